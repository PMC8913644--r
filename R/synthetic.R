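# Synthetic study generator: the statistical world the analysis pipeline is
# tested in. Two correlated Gaussian latent traits (harmony in life,
# satisfaction with life), parallel-indicator rating items on a 1-7 grid,
# linear-Gaussian embeddings of controllable signal strength, and multinomial
# token streams with a trait-tilted vocabulary.

#' Default construct vocabularies for the token generator
#'
#' Small weighted vocabularies per construct with a valence tag used by the
#' trait tilt: positive tokens become more likely for participants high on
#' the latent trait, negative tokens less likely, neutral tokens are
#' unaffected.
#'
#' @return Named list with elements `hil` and `swl`, each a data frame with
#'   columns `token`, `weight` (non-negative sampling weight) and `valence`
#'   (+1 positive, -1 negative, 0 neutral).
#' @export
default_vocab <- function() {
  neutral <- c("life", "days", "things", "people", "work", "time",
               "often", "maybe", "usually", "about")
  list(
    hil = data.frame(
      token = c("harmony", "peaceful", "balanced", "calm", "content",
                "serene", "stable", "whole",
                "conflicted", "stressed", "torn", "restless", "uneasy",
                "divided",
                neutral),
      weight = 1,
      valence = c(rep(1L, 8), rep(-1L, 6), rep(0L, length(neutral)))
    ),
    swl = data.frame(
      token = c("satisfied", "happy", "fulfilled", "grateful", "successful",
                "pleased", "thriving", "lucky",
                "disappointed", "regretful", "unhappy", "lacking", "failing",
                "empty",
                neutral),
      weight = 1,
      valence = c(rep(1L, 8), rep(-1L, 6), rep(0L, length(neutral)))
    )
  )
}

#' Configuration of a synthetic study
#'
#' Bundles every parameter of the generator. The defaults emulate the target
#' study design: N = 608 participants, two latent well-being traits
#' correlating 0.85, five items per scale on a 1-7 agreement range with item
#' loadings calibrated so the population inter-item correlations are 0.76
#' (harmony) and 0.73 (life satisfaction), word responses of exactly 10
#' descriptive words and text responses of about 70 words.
#'
#' @param n_participants Number of participants (default 608).
#' @param rho_latent Correlation between the two latent traits, in `[-1, 1]`.
#' @param n_items Items per rating scale (default 5).
#' @param item_loading_hil,item_loading_swl Per-item loading on the latent
#'   trait, in `[0, 1]`; population inter-item correlation is the loading
#'   squared (before grid rounding).
#' @param scale_range Integer pair giving the item response range.
#' @param embed_dim Dimensionality of synthetic embeddings.
#' @param embed_signal Proportion of embedding variance driven by the latent
#'   trait, in `[0, 1]`.
#' @param vocab Named list of per-construct weighted vocabularies, as
#'   [default_vocab()].
#' @param n_tokens_word_response Tokens per word-format response (default 10).
#' @param n_tokens_text_response Tokens per text-format response (default 70).
#' @param token_tilt Strength of the trait tilt on token sampling odds.
#' @param seed Integer seed; identical config implies bit-identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 608L,
                             rho_latent = 0.85,
                             n_items = 5L,
                             item_loading_hil = sqrt(0.76),
                             item_loading_swl = sqrt(0.73),
                             scale_range = c(1L, 7L),
                             embed_dim = 64L,
                             embed_signal = 0.5,
                             vocab = default_vocab(),
                             n_tokens_word_response = 10L,
                             n_tokens_text_response = 70L,
                             token_tilt = 1,
                             seed = 1L) {
  if (abs(rho_latent) > 1) stop_invalid("rho_latent must lie in [-1, 1]")
  for (ld in c(item_loading_hil, item_loading_swl, embed_signal)) {
    if (ld < 0 || ld > 1) stop_invalid("loadings and embed_signal must lie in [0, 1]")
  }
  if (n_participants < 3 || n_items < 2 || embed_dim < 1 ||
      n_tokens_word_response < 1 || n_tokens_text_response < 1) {
    stop_invalid("all counts must be positive (n_participants >= 3, n_items >= 2)")
  }
  stopifnot(length(scale_range) == 2L, scale_range[1] < scale_range[2])
  structure(list(
    n_participants = as.integer(n_participants),
    rho_latent = rho_latent,
    n_items = as.integer(n_items),
    item_loading_hil = item_loading_hil,
    item_loading_swl = item_loading_swl,
    scale_range = as.integer(scale_range),
    embed_dim = as.integer(embed_dim),
    embed_signal = embed_signal,
    vocab = vocab,
    n_tokens_word_response = as.integer(n_tokens_word_response),
    n_tokens_text_response = as.integer(n_tokens_text_response),
    token_tilt = token_tilt,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate two correlated standard-normal latent traits
#'
#' @param n Number of participants (at least 3).
#' @param rho Population correlation between the two traits, in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Object of class `latent_traits`: list with numeric vectors
#'   `hil_latent` and `swl_latent` of length `n`.
#' @export
#' @examples
#' lt <- generate_latents(1000, 0.85, seed = 1)
#' cor(lt$hil_latent, lt$swl_latent)
generate_latents <- function(n, rho, seed) {
  if (abs(rho) > 1) stop_invalid("rho must lie in [-1, 1]")
  if (n < 3) stop_invalid("n must be at least 3")
  z <- withr::with_seed(as.integer(seed), {
    list(z1 = rnorm(n), z2 = rnorm(n))
  })
  structure(list(
    hil_latent = z$z1,
    swl_latent = rho * z$z1 + sqrt(1 - rho^2) * z$z2
  ), class = "latent_traits")
}

#' Construct a rating-scale data object
#'
#' @param items N x k matrix of item responses within `scale_range`.
#' @param scale_range Integer pair, inclusive response range.
#' @param scale_name Label for the scale.
#' @param items_continuous Optional N x k matrix of the continuous
#'   (pre-rounding) item scores from the generator, kept for reliability
#'   calibration checks.
#' @return Object of class `rating_scale_data` with fields `items`,
#'   `scale_range`, `total` (row sums), `scale_name` and optionally
#'   `items_continuous`.
#' @export
rating_scale_data <- function(items, scale_range = c(1L, 7L),
                              scale_name = "scale",
                              items_continuous = NULL) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stop_invalid("a rating scale needs at least 2 items")
  if (any(items < scale_range[1] | items > scale_range[2])) {
    stop_invalid("item values outside scale range [%d, %d]",
                 scale_range[1], scale_range[2])
  }
  colnames(items) <- paste0("item_", seq_len(ncol(items)))
  structure(list(
    items = items,
    scale_range = as.integer(scale_range),
    total = rowSums(items),
    scale_name = scale_name,
    items_continuous = items_continuous
  ), class = "rating_scale_data")
}

#' Generate parallel rating-scale items from a latent trait
#'
#' Each item is `item_loading * latent + sqrt(1 - item_loading^2) * noise`,
#' affinely mapped onto the scale range (midpoint at the latent mean, six
#' latent standard deviations spanning the range) and rounded to the integer
#' grid. The population inter-item correlation before rounding is
#' `item_loading^2`; grid rounding attenuates it slightly (documented, not
#' compensated).
#'
#' @param latent Numeric latent-trait vector.
#' @param n_items Number of items (at least 2).
#' @param item_loading Loading in `[0, 1]`.
#' @param scale_range Integer pair.
#' @param seed Integer seed.
#' @param scale_name Label for the scale.
#' @return A [rating_scale_data()] object; `items_continuous` holds the
#'   unrounded mapped scores.
#' @export
generate_scale_items <- function(latent, n_items = 5L, item_loading,
                                 scale_range = c(1L, 7L), seed,
                                 scale_name = "scale") {
  if (!length(latent)) stop_invalid("latent vector is empty")
  if (item_loading < 0 || item_loading > 1) {
    stop_invalid("item_loading must lie in [0, 1]")
  }
  if (n_items < 2) stop_invalid("n_items must be at least 2")
  n <- length(latent)
  noise <- withr::with_seed(as.integer(seed),
                            matrix(rnorm(n * n_items), n, n_items))
  cont <- item_loading * latent + sqrt(1 - item_loading^2) * noise
  lo <- scale_range[1]; hi <- scale_range[2]
  mapped <- (lo + hi) / 2 + cont * (hi - lo) / 6
  items <- round(mapped)
  items[items < lo] <- lo
  items[items > hi] <- hi
  rating_scale_data(items, scale_range, scale_name, items_continuous = mapped)
}

#' Item loading achieving a target total-score reliability
#'
#' Inverts the Spearman-Brown relation: a k-item scale of parallel items with
#' inter-item correlation `r` has total-score reliability
#' `k r / (1 + (k - 1) r)`; the loading is `sqrt(r)`.
#'
#' @param reliability Target total-score reliability in `(0, 1)`.
#' @param n_items Number of items.
#' @return Item loading in `(0, 1)`.
#' @export
#' @examples
#' loading_for_total_reliability(0.81, 5)
loading_for_total_reliability <- function(reliability, n_items) {
  stopifnot(reliability > 0, reliability < 1, n_items >= 2)
  r <- reliability / (n_items - reliability * (n_items - 1))
  sqrt(r)
}

#' Spearman-Brown total-score reliability of parallel items
#'
#' @param inter_item_r Common inter-item correlation.
#' @param n_items Number of items.
#' @return Reliability of the sum score.
#' @export
spearman_brown <- function(inter_item_r, n_items) {
  n_items * inter_item_r / (1 + (n_items - 1) * inter_item_r)
}

#' Generate signal-bearing synthetic embeddings
#'
#' Each column is `sqrt(signal) * w_j * latent + sqrt(1 - signal) * noise`
#' with a fixed random weight `w_j`, scaled to unit population variance. At
#' `signal = 1` every column is an exact (signed) copy of the latent trait;
#' at `signal = 0` the matrix is pure noise.
#'
#' @param latent Numeric latent-trait vector.
#' @param dim Embedding dimensionality (at least 1).
#' @param signal Proportion of variance driven by the trait, in `[0, 1]`.
#' @param seed Integer seed.
#' @param row_ids Optional participant identifiers.
#' @return An [embedding_matrix()] with mode `"synthetic"`. The generating
#'   weights are attached as attribute `"gen_weights"` for oracle checks.
#' @export
generate_response_embeddings <- function(latent, dim, signal, seed,
                                         row_ids = NULL) {
  if (signal < 0 || signal > 1) stop_invalid("signal must lie in [0, 1]")
  if (dim < 1) stop_invalid("dim must be at least 1")
  n <- length(latent)
  rng <- withr::with_seed(as.integer(seed), {
    list(w = rnorm(dim), e = matrix(rnorm(n * dim), n, dim))
  })
  raw <- sqrt(signal) * outer(latent, rng$w) + sqrt(1 - signal) * rng$e
  denom <- sqrt(signal * rng$w^2 + (1 - signal))
  denom[denom == 0] <- 1
  vals <- sweep(raw, 2, denom, "/")
  em <- embedding_matrix(vals,
                         row_ids = row_ids %||% sprintf("p%04d", seq_len(n)),
                         mode = "synthetic", layer = NA_integer_,
                         source = "synthetic-linear-gaussian")
  attr(em, "gen_weights") <- rng$w
  attr(em, "gen_signal") <- signal
  em
}

#' Generate trait-tilted token responses
#'
#' Tokens are sampled with probability proportional to
#' `weight * exp(tilt * valence * latent)`: a logistic-type odds shift that
#' makes positive-valence tokens more likely for participants high on the
#' trait. Word-format responses contain exactly `n_tokens` tokens joined by
#' ", "; text-format responses are longer space-joined streams from the same
#' tilt.
#'
#' @param latent Numeric latent-trait vector.
#' @param vocab Data frame with columns `token`, `weight` (non-negative) and
#'   `valence`.
#' @param n_tokens Tokens per response (at least 1).
#' @param seed Integer seed.
#' @param tilt Tilt strength (default 1).
#' @param construct `"hil"` or `"swl"`.
#' @param format `"words"` or `"text"`.
#' @param row_ids Optional participant identifiers.
#' @return A [response_set()] with one record per participant.
#' @export
generate_token_responses <- function(latent, vocab, n_tokens, seed,
                                     tilt = 1, construct = "hil",
                                     format = "words", row_ids = NULL) {
  if (is.null(vocab) || !nrow(vocab)) stop_invalid("vocab is empty")
  if (any(vocab$weight < 0)) stop_invalid("vocab weights must be non-negative")
  if (n_tokens < 1) stop_invalid("n_tokens must be at least 1")
  n <- length(latent)
  sep <- if (format == "words") ", " else " "
  responses <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      p <- vocab$weight * exp(tilt * vocab$valence * latent[i])
      paste(sample(vocab$token, n_tokens, replace = TRUE, prob = p),
            collapse = sep)
    }, character(1))
  })
  response_set(data.frame(
    participant_id = row_ids %||% sprintf("p%04d", seq_len(n)),
    construct = construct,
    format = format,
    response = responses
  ))
}

#' Generate text whose trait signal lives in word order only
#'
#' Each response is a fixed set of token pairs whose *orientation* is
#' trait-tilted (`"calm storm"` vs `"storm calm"` with probability
#' `plogis(tilt * latent)`), interleaved with neutral filler words. Unigram
#' counts of the pair tokens are identical across participants, so
#' order-insensitive (decontextualized) features carry no trait signal while
#' order-sensitive (contextualized) features do. Used to probe the
#' contextual-vs-decontextual contrast.
#'
#' @param latent Numeric latent-trait vector.
#' @param n_pairs Number of oriented pairs per response.
#' @param tilt Tilt strength on the orientation odds.
#' @param seed Integer seed.
#' @param construct,format Metadata for the resulting response set.
#' @param row_ids Optional participant identifiers.
#' @return A [response_set()].
#' @export
generate_bigram_responses <- function(latent, n_pairs = 8L, tilt = 2, seed,
                                      construct = "hil", format = "text",
                                      row_ids = NULL) {
  n <- length(latent)
  fillers <- c("the", "day", "and", "with", "life", "time", "people", "maybe")
  responses <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      p <- plogis(tilt * latent[i])
      parts <- character(0)
      for (j in seq_len(n_pairs)) {
        pair <- if (runif(1) < p) c("calm", "storm") else c("storm", "calm")
        parts <- c(parts, pair, sample(fillers, 1))
      }
      paste(parts, collapse = " ")
    }, character(1))
  })
  response_set(data.frame(
    participant_id = row_ids %||% sprintf("p%04d", seq_len(n)),
    construct = construct,
    format = format,
    response = responses
  ))
}

#' Generate a complete synthetic study
#'
#' Draws latent traits, rating items for both scales, the four response sets
#' (2 constructs x word/text) and a signal-bearing embedding matrix per
#' response set, all sharing one participant index and all reproducible
#' bit-identically from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_study`: list with `latents`,
#'   `responses` (all four sets row-bound), `items_hil`, `items_swl`,
#'   `embeddings` (named list `hil_words`, `hil_text`, `swl_words`,
#'   `swl_text`), `participant_id` and `config`.
#' @export
#' @examples
#' study <- generate_study(synthetic_config(n_participants = 50, seed = 3))
#' names(study$embeddings)
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  ids <- sprintf("p%04d", seq_len(cf$n_participants))
  lat <- generate_latents(cf$n_participants, cf$rho_latent,
                          seed_child(cf$seed, "latents"))
  items_hil <- generate_scale_items(lat$hil_latent, cf$n_items,
                                    cf$item_loading_hil, cf$scale_range,
                                    seed_child(cf$seed, "items_hil"), "HILS")
  items_swl <- generate_scale_items(lat$swl_latent, cf$n_items,
                                    cf$item_loading_swl, cf$scale_range,
                                    seed_child(cf$seed, "items_swl"), "SWLS")
  sets <- list(
    hil_words = list(lat$hil_latent, cf$vocab$hil, cf$n_tokens_word_response, "hil", "words"),
    hil_text  = list(lat$hil_latent, cf$vocab$hil, cf$n_tokens_text_response, "hil", "text"),
    swl_words = list(lat$swl_latent, cf$vocab$swl, cf$n_tokens_word_response, "swl", "words"),
    swl_text  = list(lat$swl_latent, cf$vocab$swl, cf$n_tokens_text_response, "swl", "text")
  )
  responses <- do.call(rbind, lapply(names(sets), function(k) {
    s <- sets[[k]]
    as.data.frame(generate_token_responses(
      s[[1]], s[[2]], s[[3]], seed_child(cf$seed, paste0("tokens_", k)),
      tilt = cf$token_tilt, construct = s[[4]], format = s[[5]],
      row_ids = ids
    ))
  }))
  embeddings <- lapply(names(sets), function(k) {
    generate_response_embeddings(
      sets[[k]][[1]], cf$embed_dim, cf$embed_signal,
      seed_child(cf$seed, paste0("embed_", k)), row_ids = ids
    )
  })
  names(embeddings) <- names(sets)
  structure(list(
    latents = lat,
    responses = response_set(responses),
    items_hil = items_hil,
    items_swl = items_swl,
    embeddings = embeddings,
    participant_id = ids,
    config = cf
  ), class = "synthetic_study")
}

#' Write a synthetic study to delimited files
#'
#' Writes `responses.csv`, `items_hil.csv`, `items_swl.csv`, `latents.csv`
#' (ground truth), one `embeddings_<set>.csv` per response set and a
#' `config.json` echo, all UTF-8 plain text.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(as.data.frame(study$responses), "responses.csv")
  for (sc in c("hil", "swl")) {
    it <- study[[paste0("items_", sc)]]
    wr(data.frame(participant_id = study$participant_id, it$items,
                  check.names = FALSE),
       paste0("items_", sc, ".csv"))
  }
  wr(data.frame(participant_id = study$participant_id,
                hil_latent = study$latents$hil_latent,
                swl_latent = study$latents$swl_latent), "latents.csv")
  for (k in names(study$embeddings)) {
    em <- study$embeddings[[k]]
    df <- data.frame(participant_id = em$row_ids, em$values)
    colnames(df)[-1] <- paste0("dim_", seq_len(ncol(em$values)))
    wr(df, paste0("embeddings_", k, ".csv"))
  }
  cfg <- study$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(dir, "config.json"))
  invisible(files)
}
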