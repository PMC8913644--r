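# Training scheme: ridge regression from embedding features to rating-scale
# scores. Outer 10-fold cross-validation stratified on 4 outcome bins; within
# each outer training fold a single stratified 75/25 split selects the ridge
# penalty from a grid spanning 10^-16..10^16 (x10 steps); the model is then
# refit on the whole training fold and predicts the held-out fold. Accuracy
# is the Pearson correlation between observed scores and the assembled
# out-of-fold predictions.

#' Training configuration
#'
#' @param n_folds Outer folds (default 10).
#' @param n_strat_bins Outcome bins used to stratify folds and the inner
#'   split (default 4).
#' @param inner_analysis_fraction Fraction of the training fold used to fit
#'   candidate penalties; the rest evaluates them (default 0.75).
#' @param penalty_grid Strictly increasing positive penalties (default
#'   `10^(-16:16)`, 33 values).
#' @param standardize_features Z-score features within each training fold
#'   (default TRUE; the penalty grid spans 32 orders of magnitude, which only
#'   makes sense on a common feature scale).
#' @param selection_metric Inner assessment score: `"r"` (default) picks the
#'   penalty whose assessment-split predictions correlate most strongly with
#'   the held-out scores — the same Pearson metric used for final accuracy —
#'   with constant predictions scored as worst; `"rmse"` minimizes root mean
#'   squared error. Under pure-noise features RMSE selection always favors
#'   maximal shrinkage, making the out-of-fold predictions collapse onto
#'   fold means, whose anti-correlation with held-out scores biases the null
#'   accuracy negative; r-selection keeps the null calibrated.
#' @param seed Integer seed driving fold assignment and inner splits.
#' @return Object of class `training_config`.
#' @export
training_config <- function(n_folds = 10L, n_strat_bins = 4L,
                            inner_analysis_fraction = 0.75,
                            penalty_grid = 10^seq(-16, 16, by = 1),
                            standardize_features = TRUE,
                            selection_metric = c("r", "rmse"),
                            seed = 1L) {
  selection_metric <- match.arg(selection_metric)
  if (n_folds < 2) stop_invalid("n_folds must be at least 2")
  if (inner_analysis_fraction <= 0 || inner_analysis_fraction >= 1) {
    stop_invalid("inner_analysis_fraction must lie in (0, 1)")
  }
  if (any(penalty_grid <= 0) || is.unsorted(penalty_grid, strictly = TRUE)) {
    stop_invalid("penalty_grid must be strictly positive and increasing")
  }
  structure(list(n_folds = as.integer(n_folds),
                 n_strat_bins = as.integer(n_strat_bins),
                 inner_analysis_fraction = inner_analysis_fraction,
                 penalty_grid = penalty_grid,
                 standardize_features = isTRUE(standardize_features),
                 selection_metric = selection_metric,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Quantile-stratification bins for a continuous outcome
#'
#' Assigns near-equal-sized rank bins; ties are broken by stable rank order
#' (first occurrence first), so the result is deterministic for integer
#' scale totals.
#'
#' @param y Numeric outcome.
#' @param n_bins Number of bins.
#' @return Integer bin labels `1..n_bins` (all `1` with a warning when `y`
#'   is constant).
#' @export
#' @examples
#' stratify_bins(c(1, 2, 3, 4), 4)
stratify_bins <- function(y, n_bins) {
  n <- length(y)
  if (n < n_bins) stop_invalid("need at least n_bins observations")
  if (max(y) == min(y)) {
    warning("constant outcome: single stratification bin")
    return(rep(1L, n))
  }
  r <- rank(y, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

#' Stratified cross-validation fold assignment
#'
#' Spreads each stratification bin's members across folds as evenly as
#' possible (per-bin fold counts differ by at most 1), deterministically
#' under the seed.
#'
#' @param y Numeric outcome.
#' @param n_folds Number of folds.
#' @param n_bins Stratification bins.
#' @param seed Integer seed.
#' @return Integer fold labels `1..n_folds`.
#' @export
make_folds <- function(y, n_folds, n_bins, seed) {
  n <- length(y)
  if (n_folds > n) stop_invalid("n_folds (%d) exceeds N (%d)", n_folds, n)
  bins <- stratify_bins(y, min(n_bins, n))
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (b in sort(unique(bins))) {
      idx <- which(bins == b)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# Shrinkage filter on singular values; lambda = 0 falls back to the
# pseudo-inverse so rank-deficient OLS stays finite.
ridge_filter <- function(d, lambda) {
  if (lambda == 0) {
    tol <- if (length(d)) max(d) * 1e-12 else 0
    ifelse(d > tol, 1 / d, 0)
  } else {
    d / (d^2 + lambda)
  }
}

prep_features <- function(X, standardize) {
  center <- colMeans(X)
  scl <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = center, scale = scl,
       Xs = sweep(sweep(X, 2, center), 2, scl, "/"))
}

#' Fit a ridge regression model
#'
#' Minimizes `||y - Xb - b0||^2 + lambda * ||b||^2` on (optionally
#' standardized) features with an unpenalized intercept, solved exactly via
#' the singular-value decomposition.
#'
#' @param X Feature matrix (rows = observations).
#' @param y Numeric outcome.
#' @param lambda Non-negative penalty.
#' @param standardize Z-score features before fitting?
#' @return Object of class `ridge_model`: `coefficients` (on the
#'   standardized/internal feature scale), `intercept` (`mean(y)` on the
#'   centered parametrization), `lambda`, `center`, `scale`.
#' @export
#' @examples
#' m <- ridge_fit(cbind(1:3), c(2, 4, 6), lambda = 0, standardize = FALSE)
#' coef(m)
ridge_fit <- function(X, y, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_invalid("non-finite values in features or outcome")
  }
  if (nrow(X) != length(y)) stop_invalid("rows(X) must equal length(y)")
  if (nrow(X) < 2) stop_invalid("need at least 2 observations")
  if (lambda < 0) stop_invalid("lambda must be non-negative")
  pf <- prep_features(X, standardize)
  ybar <- mean(y)
  sv <- svd(pf$Xs)
  beta <- sv$v %*% (ridge_filter(sv$d, lambda) * crossprod(sv$u, y - ybar))
  structure(list(coefficients = drop(beta), intercept = ybar,
                 lambda = lambda, center = pf$center, scale = pf$scale,
                 standardize = standardize),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  drop(object$intercept + Xs %*% object$coefficients)
}

#' @export
coef.ridge_model <- function(object, ...) {
  beta_raw <- object$coefficients / object$scale
  c("(Intercept)" = object$intercept - sum(object$center * beta_raw),
    beta_raw)
}

# Predictions on held-out rows for every penalty in the grid from a single
# SVD of the training features.
ridge_path_predict <- function(X_train, y_train, X_test, lambdas,
                               standardize) {
  pf <- prep_features(X_train, standardize)
  ybar <- mean(y_train)
  sv <- svd(pf$Xs)
  uty <- crossprod(sv$u, y_train - ybar)
  Xs_test <- sweep(sweep(X_test, 2, pf$center), 2, pf$scale, "/")
  tv <- Xs_test %*% sv$v
  preds <- vapply(lambdas, function(l) {
    drop(ybar + tv %*% (ridge_filter(sv$d, l) * uty))
  }, numeric(nrow(X_test)))
  matrix(preds, nrow = nrow(X_test))
}

#' Select the ridge penalty on a stratified 75/25 split
#'
#' Splits the data into an analysis portion (75%, stratified on the outcome
#' bins) and an assessment portion (25%); fits every penalty in the grid on
#' the analysis portion and returns the penalty with the best assessment
#' score (smallest penalty on ties): highest Pearson correlation with the
#' assessment outcomes under the default `"r"` metric, or lowest root mean
#' squared error under `"rmse"` (see [training_config()]).
#'
#' @param X Feature matrix.
#' @param y Numeric outcome.
#' @param config A [training_config()].
#' @param seed Integer seed for the split (defaults to the config seed).
#' @return The selected penalty (numeric scalar) with the assessment score
#'   profile attached as attribute `"score"` (higher is better).
#' @export
select_penalty <- function(X, y, config = training_config(),
                           seed = config$seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop_invalid("too few observations for a 75/25 split")
  bins <- stratify_bins(y, min(config$n_strat_bins, n))
  analysis <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (b in sort(unique(bins))) {
      idx <- which(bins == b)
      idx <- idx[sample.int(length(idx))]
      k <- round(config$inner_analysis_fraction * length(idx))
      analysis <- c(analysis, idx[seq_len(k)])
    }
  })
  if (length(analysis) < 2 || length(analysis) > n - 1) {
    stop_invalid("degenerate 75/25 split (N = %d)", n)
  }
  assess <- setdiff(seq_len(n), analysis)
  preds <- ridge_path_predict(X[analysis, , drop = FALSE], y[analysis],
                              X[assess, , drop = FALSE],
                              config$penalty_grid,
                              config$standardize_features)
  y_assess <- y[assess]
  rmse <- sqrt(colMeans((y_assess - preds)^2))
  if (config$selection_metric == "rmse") {
    if (!any(is.finite(rmse))) {
      stop_invalid("penalty selection failed: no finite assessment score")
    }
    lam <- config$penalty_grid[which.min(rmse)]
    attr(lam, "score") <- -rmse
    return(lam)
  }
  if (sd(y_assess) == 0) {
    stop_invalid("penalty selection failed: constant assessment outcome")
  }
  score <- apply(preds, 2, function(p) if (sd(p) == 0) -Inf else cor(y_assess, p))
  if (!any(is.finite(score))) {
    stop_invalid("penalty selection failed: no finite assessment score")
  }
  # Correlation is scale-free: when several penalties score within numerical
  # noise of the best (e.g. low-rank signal, where shrinkage changes only the
  # prediction scale, not its direction), the tie is broken by assessment
  # RMSE — which does see scale — and then toward the smallest penalty.
  ties <- which(score >= max(score[is.finite(score)]) - 1e-3)
  lam <- config$penalty_grid[ties[which.min(rmse[ties])]]
  attr(lam, "score") <- score
  lam
}

#' Construct a prediction result
#'
#' @param y_observed,y_predicted Observed and out-of-fold predicted scores.
#' @param fold_assignment Integer outer-fold labels.
#' @param lambda_per_fold Selected penalty per outer fold.
#' @param outcome_name,model_name Labels.
#' @param smoother Optional N x N linear-smoother matrix H with
#'   `y_predicted = H %*% y_observed`, supplied by
#'   [cross_validated_predict()]. When present, `accuracy_p` is computed
#'   from the smoother-based Monte-Carlo null (see Details); otherwise the
#'   naive t transform of the pooled correlation is used.
#' @param n_null Monte-Carlo draws for the smoother-based null.
#' @param null_seed Seed for the Monte-Carlo null.
#' @details `accuracy_r` is the Pearson correlation over the pooled
#'   out-of-fold vector (computed with [pearson_r()] exactly). Pooled
#'   out-of-fold predictions are not independent across observations: fold A
#'   helps predict fold B and vice versa, which roughly doubles the variance
#'   of the pooled null correlation relative to the independent case, and
#'   heavily shrunk folds contribute training-fold means that anti-correlate
#'   with their held-out scores. The naive `N - 2` t transform is therefore
#'   anti-conservative for cross-validated accuracies. Because the whole
#'   cross-validation fit is a linear smoother `yhat = H y` once folds,
#'   penalties and scalings are fixed, the null distribution of
#'   `cor(y*, H y*)` under an outcome carrying no signal is available by
#'   Monte Carlo with H frozen; `accuracy_p` is the two-sided tail
#'   probability of the observed accuracy under that null.
#' @return Object of class `prediction_result`.
#' @export
prediction_result <- function(y_observed, y_predicted, fold_assignment,
                              lambda_per_fold, outcome_name = "y",
                              model_name = outcome_name, smoother = NULL,
                              n_null = 1000L, null_seed = 1L) {
  stopifnot(length(y_observed) == length(y_predicted),
            length(y_observed) == length(fold_assignment))
  acc <- pearson_r(y_observed, y_predicted)
  p <- if (is.null(smoother)) {
    acc$p
  } else {
    smoother_null_p(acc$r, smoother, n_null, null_seed)
  }
  structure(list(y_observed = y_observed, y_predicted = y_predicted,
                 fold_assignment = fold_assignment,
                 lambda_per_fold = lambda_per_fold,
                 accuracy_r = acc$r,
                 accuracy_p = p,
                 outcome_name = outcome_name, model_name = model_name),
            class = "prediction_result")
}

# Two-sided Monte-Carlo p-value of the pooled out-of-fold correlation under
# the no-signal null, conditioning on the fitted linear smoother H: draw
# y* ~ N(0, 1), form H y*, and compare |cor(y*, H y*)| with the observed
# accuracy. Degenerate draws (constant predictions) carry no evidence
# against the null and are counted as non-exceedances.
smoother_null_p <- function(r_obs, H, n_null = 1000L, seed = 1L) {
  n <- nrow(H)
  r_null <- withr::with_seed(as.integer(seed), {
    ystar <- matrix(rnorm(n * n_null), n, n_null)
    pstar <- H %*% ystar
    yc <- sweep(ystar, 2, colMeans(ystar))
    pc <- sweep(pstar, 2, colMeans(pstar))
    num <- colSums(yc * pc)
    den <- sqrt(colSums(yc^2) * colSums(pc^2))
    ifelse(den > 0, num / den, 0)
  })
  (1 + sum(abs(r_null) >= abs(r_obs))) / (n_null + 1)
}

# 1 / (d^2 + lambda) filter used when building the smoother; matches
# ridge_filter(d, lambda) / d with the same pseudo-inverse convention.
ridge_filter_sq <- function(d, lambda) {
  if (lambda == 0) {
    tol <- if (length(d)) max(d) * 1e-12 else 0
    ifelse(d > tol, 1 / d^2, 0)
  } else {
    1 / (d^2 + lambda)
  }
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s -> %s: r = %.3f (p = %.3g, N = %d, %s)\n",
              x$model_name, x$outcome_name, x$accuracy_r, x$accuracy_p,
              length(x$y_observed), interpret_r(x$accuracy_r)))
  invisible(x)
}

#' Cross-validated out-of-fold prediction
#'
#' For each outer fold: select the penalty on the training part (single
#' stratified 75/25 split), refit on the whole training part at the selected
#' penalty, and predict the held-out part. Every observation is predicted
#' exactly once by a model never trained on it; accuracy is the Pearson
#' correlation between the observed scores and the pooled out-of-fold
#' predictions.
#'
#' @param X Feature matrix or [embedding_matrix()].
#' @param y Numeric outcome (rating-scale totals or a difference score).
#' @param config A [training_config()].
#' @param outcome_name,model_name Labels carried into the result.
#' @return A [prediction_result()].
#' @export
#' @examples
#' lt <- generate_latents(120, 0.85, seed = 1)
#' em <- generate_response_embeddings(lt$hil_latent, 8, 1, seed = 2)
#' res <- cross_validated_predict(em, lt$hil_latent,
#'                                training_config(seed = 1))
#' res$accuracy_r
cross_validated_predict <- function(X, y, config = training_config(),
                                    outcome_name = "y",
                                    model_name = outcome_name) {
  if (inherits(X, "embedding_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop_invalid("rows(X) must equal length(y)")
  if (n < config$n_folds) stop_invalid("N < n_folds")
  if (sd(y) == 0) stop_invalid("outcome is constant; accuracy undefined")
  folds <- make_folds(y, config$n_folds, config$n_strat_bins,
                      seed_child(config$seed, "folds"))
  yhat <- rep(NA_real_, n)
  lambda_fold <- numeric(config$n_folds)
  H <- matrix(0, n, n)
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    lam <- select_penalty(X[tr, , drop = FALSE], y[tr], config,
                          seed = seed_child(config$seed, paste0("inner-", f)))
    lambda_fold[f] <- as.numeric(lam)
    # Fold block of the linear smoother: yhat_test = H[test, train] y_train,
    # built from one SVD of the (standardized) training features.
    pf <- prep_features(X[tr, , drop = FALSE], config$standardize_features)
    sv <- svd(pf$Xs)
    Xs_te <- sweep(sweep(X[!tr, , drop = FALSE], 2, pf$center), 2,
                   pf$scale, "/")
    f2 <- ridge_filter_sq(sv$d, lambda_fold[f])
    M <- sweep(Xs_te %*% sv$v, 2, f2 * sv$d, "*") %*% t(sv$u)
    n_tr <- sum(tr)
    H[!tr, tr] <- M + (1 - rowSums(M)) / n_tr
    yhat[!tr] <- H[!tr, tr, drop = FALSE] %*% y[tr]
  }
  if (anyNA(yhat)) stop_invalid("internal error: incomplete out-of-fold predictions")
  if (sd(yhat) == 0) stop_invalid("assembled predictions are constant; accuracy undefined")
  prediction_result(y, yhat, folds, lambda_fold, outcome_name, model_name,
                    smoother = H, n_null = 1000L,
                    null_seed = seed_child(config$seed, "nullmc"))
}

#' Centered difference score of two outcomes
#'
#' The discriminant-model target: each outcome is normalized by subtracting
#' its column mean, then the two are differenced. The result always has mean
#' zero.
#'
#' @param y1,y2 Numeric vectors of equal length.
#' @return `(y1 - mean(y1)) - (y2 - mean(y2))`.
#' @export
#' @examples
#' difference_target(c(1, 2, 3), c(3, 2, 1))
difference_target <- function(y1, y2) {
  if (length(y1) != length(y2)) stop_invalid("y1 and y2 differ in length")
  (y1 - mean(y1)) - (y2 - mean(y2))
}
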