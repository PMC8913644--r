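# Orchestration: load a study from delimited files (or take a synthetic
# study), run every configured model (per construct x format plus the
# combined "all responses" model and the discriminant difference-score
# model), the model comparisons, the reliability and diversity reports, and
# bundle everything into a reproducible run report.

#' Load a study from delimited files
#'
#' Reads `responses.csv` (participant_id, construct, format, response),
#' `items_hil.csv` and `items_swl.csv` (participant_id, item_1..item_k).
#' Participants must answer all four open-ended questions (2 constructs x
#' word/text); those who do not are excluded and logged. Item values outside
#' the scale range raise a validation error.
#'
#' @param dir Directory containing the three files, or `NULL` if paths are
#'   given explicitly.
#' @param responses,items_hil,items_swl File paths (default under `dir`).
#' @param scale_range Integer pair for item validation.
#' @return Object of class `study_bundle`: `responses` ([response_set()]),
#'   `items_hil`, `items_swl` ([rating_scale_data()]), `participant_id`,
#'   and `excluded` (ids dropped with the reason).
#' @export
load_study <- function(dir = NULL,
                       responses = file.path(dir, "responses.csv"),
                       items_hil = file.path(dir, "items_hil.csv"),
                       items_swl = file.path(dir, "items_swl.csv"),
                       scale_range = c(1L, 7L)) {
  resp <- read.csv(responses, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("participant_id", "construct", "format", "response")
  for (col in need) {
    if (!col %in% names(resp)) {
      stop_invalid("responses file is missing column '%s'", col)
    }
  }
  read_items <- function(path, name) {
    it <- read.csv(path, stringsAsFactors = FALSE)
    if (!"participant_id" %in% names(it)) {
      stop_invalid("%s is missing column 'participant_id'", name)
    }
    item_cols <- grep("^item_", names(it), value = TRUE)
    if (length(item_cols) < 2) {
      stop_invalid("%s needs at least 2 item_* columns", name)
    }
    m <- as.matrix(it[item_cols])
    if (any(m < scale_range[1] | m > scale_range[2])) {
      stop_invalid("%s has item values outside [%d, %d]", name,
                   scale_range[1], scale_range[2])
    }
    list(ids = as.character(it$participant_id), items = m)
  }
  ih <- read_items(items_hil, "items_hil")
  is_ <- read_items(items_swl, "items_swl")

  # Exclude participants not answering all four open-ended questions.
  resp$participant_id <- as.character(resp$participant_id)
  answered <- !is.na(resp$response) & nzchar(trimws(resp$response))
  resp <- resp[answered, , drop = FALSE]
  cells <- paste(resp$construct, resp$format)
  tab <- table(resp$participant_id,
               factor(cells, levels = c("hil words", "hil text",
                                        "swl words", "swl text")))
  complete <- rownames(tab)[apply(tab >= 1, 1, all)]
  keep <- Reduce(intersect, list(complete, ih$ids, is_$ids))
  keep <- ih$ids[ih$ids %in% keep]  # preserve item-table order
  excluded <- setdiff(unique(c(rownames(tab), ih$ids, is_$ids)), keep)
  if (!length(keep)) stop_invalid("no participant has complete data")

  resp <- resp[resp$participant_id %in% keep, , drop = FALSE]
  rownames(resp) <- NULL
  structure(list(
    responses = response_set(resp),
    items_hil = rating_scale_data(ih$items[match(keep, ih$ids), , drop = FALSE],
                                  scale_range, "HILS"),
    items_swl = rating_scale_data(is_$items[match(keep, is_$ids), , drop = FALSE],
                                  scale_range, "SWLS"),
    participant_id = keep,
    excluded = excluded
  ), class = "study_bundle")
}

#' Word-count summary of a response set
#'
#' @param responses A [response_set()].
#' @return Data frame with one row per (construct, format): mean and SD of
#'   the number of tokens per response.
#' @export
word_count_summary <- function(responses) {
  df <- as.data.frame(responses)
  counts <- lengths(tokenize_words(df$response))
  agg <- aggregate(counts,
                   by = list(construct = df$construct, format = df$format),
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  data.frame(construct = agg$construct, format = agg$format,
             mean_words = agg$x[, "mean"], sd_words = agg$x[, "sd"])
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Trains, for each rating scale, a model per own-construct response set
#' plus the combined model using all four response sets, and the
#' discriminant model predicting the centered difference of the two scale
#' totals from all features. Adds the words-vs-text paired error t-tests per
#' scale, a bootstrap comparison of the two combined models, reliability
#' reports for both scales, and diversity/word-count summaries per response
#' set.
#'
#' @param study A [generate_study()] result (or a `study_bundle` with an
#'   `embeddings` list attached under the same names).
#' @param training A [training_config()].
#' @param n_boot Bootstrap replicates for the cross-outcome comparison.
#' @return Object of class `run_report` with elements `models` (named list
#'   of [prediction_result()]), `comparisons`, `reliability`, `diversity`,
#'   `word_counts`, `config` (echo) and `version`.
#' @export
run_pipeline <- function(study, training = training_config(),
                         n_boot = 1000L) {
  emb <- study$embeddings
  stopifnot(!is.null(emb),
            all(c("hil_words", "hil_text", "swl_words", "swl_text")
                %in% names(emb)))
  y_h <- study$items_hil$total
  y_s <- study$items_swl$total
  all_features <- combine_feature_sets(unname(emb[c("hil_words", "hil_text",
                                                    "swl_words", "swl_text")]))
  cvp <- function(X, y, outcome, model) {
    cross_validated_predict(X, y, training, outcome_name = outcome,
                            model_name = model)
  }
  models <- list(
    hils_words = cvp(emb$hil_words, y_h, "HILS", "hil_words"),
    hils_text  = cvp(emb$hil_text,  y_h, "HILS", "hil_text"),
    swls_words = cvp(emb$swl_words, y_s, "SWLS", "swl_words"),
    swls_text  = cvp(emb$swl_text,  y_s, "SWLS", "swl_text"),
    hils_all   = cvp(all_features,  y_h, "HILS", "all_responses"),
    swls_all   = cvp(all_features,  y_s, "SWLS", "all_responses"),
    difference_all = cvp(all_features, difference_target(y_h, y_s),
                         "HILS-minus-SWLS", "all_responses")
  )
  comparisons <- list(
    hils_words_vs_text = compare_same_outcome(models$hils_words,
                                              models$hils_text),
    swls_words_vs_text = compare_same_outcome(models$swls_words,
                                              models$swls_text),
    combined_hils_vs_swls = compare_bootstrap(models$hils_all,
                                              models$swls_all,
                                              n_boot = n_boot,
                                              seed = seed_child(training$seed,
                                                                "boot"))
  )
  reliability <- list(
    HILS = reliability_report(study$items_hil),
    SWLS = reliability_report(study$items_swl)
  )
  sets <- c("hil_words", "hil_text", "swl_words", "swl_text")
  diversity <- lapply(sets, function(k) {
    cf <- strsplit(k, "_")[[1]]
    sub <- response_subset(study$responses, cf[1], cf[2])
    diversity_index(sub$response)
  })
  names(diversity) <- sets
  structure(list(
    models = models,
    comparisons = comparisons,
    reliability = reliability,
    diversity = diversity,
    word_counts = word_count_summary(study$responses),
    config = list(synthetic = if (inherits(study, "synthetic_study"))
      unclass(study$config) else NULL,
      training = unclass(training), n_boot = n_boot),
    version = as.character(utils::packageVersion("lbassess"))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  Models (out-of-fold accuracy):\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("    %-16s -> %-15s r = %.3f (%s)\n", nm, m$outcome_name,
                m$accuracy_r, interpret_r(m$accuracy_r)))
  }
  cat("  Reliability ceilings:\n")
  for (nm in names(x$reliability)) {
    r <- x$reliability[[nm]]
    cat(sprintf("    %s: inter-item %.3f, item-total %.3f, alpha %.3f\n",
                nm, r$inter_item_mean_r, r$corrected_item_total_mean_r,
                r$alpha))
  }
  cat("  Diversity indices:\n")
  for (nm in names(x$diversity)) {
    cat(sprintf("    %-10s DI = %.1f\n", nm, x$diversity[[nm]]$diversity_index))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes a canonical JSON report plus a flat CSV model summary.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summarize_model <- function(m) {
    list(model = m$model_name, outcome = m$outcome_name,
         accuracy_r = m$accuracy_r, accuracy_p = m$accuracy_p,
         interpretation = interpret_r(m$accuracy_r),
         lambda_per_fold = m$lambda_per_fold)
  }
  json <- list(
    models = lapply(report$models, summarize_model),
    comparisons = lapply(report$comparisons, function(cc) {
      list(method = cc$method, models = cc$model_names,
           statistic = cc$statistic, p_value = cc$p_value)
    }),
    reliability = lapply(report$reliability, function(r) {
      list(scale = r$scale_name, inter_item_mean_r = r$inter_item_mean_r,
           corrected_item_total_mean_r = r$corrected_item_total_mean_r,
           alpha = r$alpha, ceiling = r$ceiling)
    }),
    diversity = lapply(report$diversity, unclass),
    word_counts = report$word_counts,
    config = report$config,
    version = report$version
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA)
  csv <- do.call(rbind, lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]
    data.frame(model = nm, outcome = m$outcome_name,
               accuracy_r = m$accuracy_r, accuracy_p = m$accuracy_p)
  }))
  csv_path <- file.path(dir, "models.csv")
  write.csv(csv, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
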