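# Evaluation statistics: prediction accuracy and its significance, bespoke
# model-comparison tests (paired error t-test for models of the same outcome,
# paired bootstrap of accuracy distributions for models of different
# outcomes), rating-scale reliability as the attenuation ceiling on
# attainable accuracy, the Shannon-entropy diversity index, and the
# interpretation bands for correlation magnitudes.

#' Pearson correlation with two-sided significance
#'
#' @param a,b Numeric vectors of equal length (at least 3), both
#'   non-constant.
#' @return List with `r` (product-moment correlation) and `p` (two-sided
#'   p-value from the t transform with N - 2 df).
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("vectors differ in length")
  if (length(a) < 3) stop_invalid("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0) stop_invalid("undefined correlation: constant input")
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

comparison_result <- function(method, statistic, p_value, model_names,
                              n_boot = NA_integer_, seed = NA_integer_,
                              detail = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 model_names = model_names, n_boot = n_boot, seed = seed,
                 detail = detail),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s [%s]: statistic = %.3f, p = %.4g\n",
              x$model_names[1], x$model_names[2], x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' Paired error t-test between two models of the same outcome
#'
#' Computes each model's per-participant prediction error `y - yhat` and
#' compares the two error vectors with a paired t-test. Raw cross-validated
#' errors have near-zero mean for any competent model, so by default the
#' errors are compared in absolute value (magnitude); raw and squared errors
#' are available by flag.
#'
#' @param res_a,res_b [prediction_result()]s for the *same* observed outcome
#'   on the same participants.
#' @param error Error transform: `"absolute"` (default), `"raw"` or
#'   `"squared"`.
#' @return A `comparison_result` with method `"paired_error_t"`.
#' @export
compare_same_outcome <- function(res_a, res_b,
                                 error = c("absolute", "raw", "squared")) {
  error <- match.arg(error)
  if (length(res_a$y_observed) != length(res_b$y_observed) ||
      !isTRUE(all.equal(res_a$y_observed, res_b$y_observed))) {
    stop_invalid(paste("models predict different outcomes;",
                       "use compare_bootstrap() for cross-outcome comparison"))
  }
  per_error <- function(res) {
    d <- res$y_observed - res$y_predicted
    switch(error, absolute = abs(d), raw = d, squared = d^2)
  }
  ea <- per_error(res_a)
  eb <- per_error(res_b)
  d <- ea - eb
  if (isTRUE(all.equal(ea, eb))) {
    stat <- 0; p <- 1
  } else if (sd(d) == 0) {
    # one model's error exceeds the other's by the same amount everywhere:
    # a deterministic difference, beyond any finite t statistic
    stat <- sign(mean(d)) * Inf; p <- 0
  } else {
    tt <- t.test(ea, eb, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  comparison_result("paired_error_t", stat, p,
                    c(res_a$model_name, res_b$model_name),
                    detail = list(error_metric = error))
}

#' Bootstrap comparison of two models' accuracy distributions
#'
#' Resamples participants with replacement and recomputes each model's
#' accuracy (Pearson r between its observed and predicted scores) on every
#' replicate, building one bootstrapped accuracy distribution per model. The
#' overlap of the two distributions is summarized as a two-sided Monte-Carlo
#' p-value: `2 * min(P(dr <= 0), P(dr >= 0))` over the between-distribution
#' accuracy difference `dr = r_a - r_b`, capped at 1 (add-one convention).
#' Unlike the paired error t-test this works for models of *different*
#' outcomes.
#'
#' By default each model's distribution is built from its own independent
#' resamples. Fitted cross-validated predictions freeze the alignment
#' between the model and its training noise, so jointly resampled (paired)
#' differences hugely understate the sampling variability of an accuracy
#' difference and over-reject when two models are equally accurate;
#' comparing the two distributions independently matches the observed
#' variability. Joint resampling remains available via `resample =
#' "paired"`.
#'
#' @param res_a,res_b [prediction_result()]s over the same participants;
#'   outcomes may differ.
#' @param n_boot Bootstrap replicates (default 1000; below 100 a warning).
#' @param seed Integer seed (required for reproducibility).
#' @param resample `"independent"` (default) or `"paired"`.
#' @return A `comparison_result` with method `"bootstrap_overlap"`;
#'   `statistic` is the mean accuracy difference over replicates.
#' @export
compare_bootstrap <- function(res_a, res_b, n_boot = 1000L, seed,
                              resample = c("independent", "paired")) {
  resample <- match.arg(resample)
  n <- length(res_a$y_observed)
  if (length(res_b$y_observed) != n) {
    stop_invalid("results are not aligned: %d vs %d participants",
                 n, length(res_b$y_observed))
  }
  if (n_boot < 1) stop_invalid("n_boot must be at least 1")
  if (n_boot < 100) warning("n_boot < 100: bootstrap p-value will be coarse")
  safe_r <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  dr <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx_a <- sample.int(n, n, replace = TRUE)
      idx_b <- if (resample == "paired") idx_a else sample.int(n, n, replace = TRUE)
      safe_r(res_a$y_observed[idx_a], res_a$y_predicted[idx_a]) -
        safe_r(res_b$y_observed[idx_b], res_b$y_predicted[idx_b])
    }, numeric(1))
  })
  dr <- dr[is.finite(dr)]
  if (!length(dr)) stop_invalid("all bootstrap replicates degenerate")
  # two-sided crossing probability with the add-one Monte-Carlo convention,
  # so a finite number of replicates never reports an exact zero
  b <- length(dr)
  p <- min(1, 2 * min((1 + sum(dr <= 0)) / (b + 1),
                      (1 + sum(dr >= 0)) / (b + 1)))
  comparison_result("bootstrap_overlap", mean(dr), p,
                    c(res_a$model_name, res_b$model_name),
                    n_boot = as.integer(n_boot), seed = as.integer(seed),
                    detail = list(delta_r = dr))
}

item_matrix <- function(items) {
  if (inherits(items, "rating_scale_data")) items <- items$items
  items <- as.matrix(items)
  if (ncol(items) < 2) stop_invalid("need at least 2 items")
  csd <- apply(items, 2, sd)
  if (any(csd == 0)) {
    stop_invalid("item(s) with zero variance: %s",
                 paste(colnames(items)[csd == 0] %||% which(csd == 0),
                       collapse = ", "))
  }
  items
}

#' Mean inter-item correlation
#'
#' Mean of the `k(k-1)/2` pairwise Pearson correlations among a scale's
#' items — the weakest of the reliability summaries used as accuracy
#' ceilings.
#'
#' @param items A [rating_scale_data()] or numeric item matrix.
#' @return Numeric scalar.
#' @export
inter_item_mean <- function(items) {
  it <- item_matrix(items)
  cm <- cor(it)
  mean(cm[upper.tri(cm)])
}

#' Mean corrected item-total correlation
#'
#' Mean over items of the correlation between each item and the total of the
#' remaining items. On positively correlated scales this exceeds the mean
#' inter-item correlation, giving a higher reliability ceiling.
#'
#' @inheritParams inter_item_mean
#' @return Numeric scalar.
#' @export
corrected_item_total_mean <- function(items) {
  it <- item_matrix(items)
  if (ncol(it) < 3) stop_invalid("corrected item-total needs at least 3 items")
  total <- rowSums(it)
  mean(vapply(seq_len(ncol(it)),
              function(j) cor(it[, j], total - it[, j]), numeric(1)))
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`.
#'
#' @inheritParams inter_item_mean
#' @return Numeric scalar (at most 1).
#' @export
cronbach_alpha <- function(items) {
  it <- item_matrix(items)
  k <- ncol(it)
  vt <- var(rowSums(it))
  if (vt == 0) stop_invalid("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(it, 2, var)) / vt)
}

#' Reliability report for a rating scale
#'
#' @param items A [rating_scale_data()] or numeric item matrix.
#' @param test_retest Optional numeric vector of externally supplied
#'   test-retest reliabilities (taken as constants, not estimated).
#' @param scale_name Label.
#' @return Object of class `reliability_report` with `inter_item_mean_r`,
#'   `corrected_item_total_mean_r`, `alpha`, `test_retest` and
#'   `ceiling` (the paper-convention ceiling, see
#'   [reliability_ceiling()]).
#' @export
reliability_report <- function(items, test_retest = NULL,
                               scale_name = if (inherits(items, "rating_scale_data"))
                                 items$scale_name else "scale") {
  iim <- inter_item_mean(items)
  citm <- corrected_item_total_mean(items)
  structure(list(
    scale_name = scale_name,
    inter_item_mean_r = iim,
    corrected_item_total_mean_r = citm,
    alpha = cronbach_alpha(items),
    test_retest = test_retest,
    ceiling = reliability_ceiling(citm, convention = "paper")
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(paste0("<reliability_report> %s: inter-item r = %.3f, ",
                     "item-total r = %.3f, alpha = %.3f\n"),
              x$scale_name, x$inter_item_mean_r,
              x$corrected_item_total_mean_r, x$alpha))
  invisible(x)
}

#' Reliability ceiling on attainable prediction accuracy
#'
#' The reliability of the to-be-predicted measure bounds how strongly any
#' alternative measure can correlate with it. Convention `"paper"` compares
#' an observed accuracy directly against the reliability value itself (the
#' convention used when judging language-based accuracies against inter-item,
#' item-total and test-retest reliabilities); convention `"classical"` is the
#' attenuation formula `sqrt(rel_predicted * rel_predictor)`.
#'
#' @param rel_predicted Reliability of the predicted measure, in `(0, 1]`.
#' @param rel_predictor Reliability of the predictor measure (classical
#'   convention only; default 1).
#' @param convention `"paper"` or `"classical"`.
#' @return The ceiling correlation.
#' @export
#' @examples
#' reliability_ceiling(0.84, convention = "paper")
#' reliability_ceiling(0.81, 1, convention = "classical")
reliability_ceiling <- function(rel_predicted, rel_predictor = NULL,
                                convention = c("paper", "classical")) {
  convention <- match.arg(convention)
  rel_predictor <- rel_predictor %||% 1
  if (rel_predicted <= 0 || rel_predicted > 1 ||
      rel_predictor <= 0 || rel_predictor > 1) {
    stop_invalid("reliabilities must lie in (0, 1]")
  }
  switch(convention,
         paper = rel_predicted,
         classical = sqrt(rel_predicted * rel_predictor))
}

#' Diversity index of a token corpus
#'
#' Pools all tokens, computes the Shannon entropy H (bits) of the token
#' relative-frequency distribution, and reports the diversity index
#' `DI = 2^H`: the effective number of distinct token "types" the corpus
#' could account for. Tokens are normalized with the same rule used for
#' decontextualized embedding, so DI describes exactly the words the models
#' saw.
#'
#' @param token_lists Character vector of raw responses, or a list of token
#'   vectors.
#' @return Object of class `diversity_report` with `entropy_bits`,
#'   `diversity_index`, `token_count`, `distinct_tokens`.
#' @export
#' @examples
#' diversity_index(list(c("a", "a", "b", "b")))$diversity_index
diversity_index <- function(token_lists) {
  if (is.character(token_lists)) {
    token_lists <- tokenize_words(token_lists)
  } else {
    token_lists <- lapply(token_lists, function(t) unlist(tokenize_words(t)))
  }
  tokens <- unlist(token_lists, use.names = FALSE)
  if (!length(tokens)) stop_invalid("empty corpus")
  p <- as.numeric(table(tokens)) / length(tokens)
  h <- -sum(p * log2(p))
  structure(list(entropy_bits = h, diversity_index = 2^h,
                 token_count = length(tokens),
                 distinct_tokens = length(p)),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("<diversity_report> DI = %.1f (H = %.2f bits, %d tokens, %d types)\n",
              x$diversity_index, x$entropy_bits, x$token_count,
              x$distinct_tokens))
  invisible(x)
}

#' Interpret the magnitude of a correlation
#'
#' Bands: 0.20-0.39 weak, 0.40-0.59 moderate, 0.60-0.79 strong,
#' 0.80-1.0 very strong; magnitudes below 0.20 are labeled "negligible".
#'
#' @param r Correlation with `|r| <= 1`.
#' @return One of `"negligible"`, `"weak"`, `"moderate"`, `"strong"`,
#'   `"very strong"`.
#' @export
#' @examples
#' interpret_r(0.85)
interpret_r <- function(r) {
  if (abs(r) > 1) stop_invalid("|r| must not exceed 1")
  a <- abs(r)
  if (a >= 0.8) "very strong"
  else if (a >= 0.6) "strong"
  else if (a >= 0.4) "moderate"
  else if (a >= 0.2) "weak"
  else "negligible"
}
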