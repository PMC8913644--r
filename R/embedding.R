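# Embedding extraction: turn word/text responses into fixed-length feature
# vectors under two regimes. Contextualized: the whole token sequence passes
# through the embedder at once, so each token's vector may depend on its
# neighbours. Decontextualized: each word is embedded as its own one-word
# document, which makes the representation order-invariant. Real transformer
# backends plug in through the embedder contract; the package ships
# deterministic toy embedders sufficient for analysis development and testing.

#' Construct a response set
#'
#' @param records Data frame with columns `participant_id`, `construct`
#'   (`"hil"` or `"swl"`), `format` (`"words"` or `"text"`) and `response`
#'   (non-empty after whitespace strip).
#' @return Object of class `response_set` (a validated data frame).
#' @export
response_set <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("participant_id", "construct", "format", "response")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop_invalid("response set is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  bad <- !records$construct %in% c("hil", "swl")
  if (any(bad)) stop_invalid("unknown construct: %s",
                             paste(unique(records$construct[bad]), collapse = ", "))
  bad <- !records$format %in% c("words", "text")
  if (any(bad)) stop_invalid("unknown format: %s",
                             paste(unique(records$format[bad]), collapse = ", "))
  empty <- !nzchar(trimws(records$response))
  if (any(empty)) {
    stop_invalid("empty response for participant(s): %s",
                 paste(records$participant_id[empty], collapse = ", "))
  }
  key <- paste(records$construct, records$format, records$participant_id)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate participant within a (construct, format) cell")
  }
  class(records) <- c("response_set", "data.frame")
  records
}

#' Subset a response set to one (construct, format) cell
#'
#' @param responses A [response_set()].
#' @param construct,format Cell to keep.
#' @return A `response_set` with unique participants.
#' @export
response_subset <- function(responses, construct, format) {
  out <- responses[responses$construct == construct &
                     responses$format == format, , drop = FALSE]
  rownames(out) <- NULL
  response_set(out)
}

#' Construct an embedding matrix
#'
#' @param values N x D numeric matrix, all entries finite.
#' @param row_ids Participant identifiers, one per row.
#' @param mode `"contextual"`, `"decontextual"`, `"synthetic"` or
#'   `"combined"`.
#' @param layer Layer index the features were taken from (NA for synthetic).
#' @param source Name of the producing embedder/backend.
#' @return Object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, row_ids,
                             mode = c("contextual", "decontextual",
                                      "synthetic", "combined"),
                             layer = NA_integer_, source = "unknown") {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop_invalid("embedding matrix has non-finite entries")
  if (nrow(values) != length(row_ids)) {
    stop_invalid("row_ids length (%d) does not match rows (%d)",
                 length(row_ids), nrow(values))
  }
  structure(list(values = values, row_ids = as.character(row_ids),
                 mode = mode, layer = layer, source = source),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d x %d, mode=%s, layer=%s, source=%s\n",
              nrow(x$values), ncol(x$values), x$mode,
              ifelse(is.na(x$layer), "-", x$layer), x$source))
  invisible(x)
}

#' @export
dim.embedding_matrix <- function(x) dim(x$values)

#' Deterministic toy embedder
#'
#' A context-free or context-sensitive stand-in for a transformer backend,
#' satisfying the embedder contract: for a token sequence and a layer index
#' it returns one vector per token (plus boundary markers). Token vectors are
#' hash-seeded Gaussian draws, deterministic in (token, layer). With
#' `context_weight != 0` each token's vector additionally receives a hashed
#' vector of the (previous token, token) pair, making the representation
#' order-sensitive the way contextual language models are.
#'
#' @param dim Vector dimensionality per layer.
#' @param n_layers Number of layers.
#' @param context_weight Weight of the previous-token interaction term
#'   (0 = context-free).
#' @param name Optional embedder name.
#' @return Object of class `embedder`: list with `name`, `n_layers`, `dim`,
#'   `context_weight` and `embed_fn(tokens, layer)` returning
#'   `list(vectors = matrix, is_marker = logical)`.
#' @export
#' @examples
#' emb <- toy_embedder(dim = 8, context_weight = 1)
#' out <- emb$embed_fn(c("calm", "storm"), layer = emb$n_layers - 1)
#' dim(out$vectors)
toy_embedder <- function(dim = 16L, n_layers = 4L, context_weight = 0,
                         name = NULL) {
  stopifnot(dim >= 1, n_layers >= 2)
  name <- name %||% sprintf("toy-%dd-%dl%s", dim, n_layers,
                            if (context_weight != 0) "-ctx" else "")
  cache <- new.env(parent = emptyenv())
  token_vec <- function(key, layer) {
    id <- paste0("L", layer, "\r", key)
    v <- cache[[id]]
    if (is.null(v)) {
      v <- withr::with_seed(seed_child(1L, id), rnorm(dim))
      cache[[id]] <- v
    }
    v
  }
  embed_fn <- function(tokens, layer) {
    stopifnot(length(tokens) >= 1, layer >= 1, layer <= n_layers)
    toks <- c("[cls]", tokens, "[sep]")
    prev <- c("[bos]", toks[-length(toks)])
    vecs <- t(vapply(seq_along(toks), function(i) {
      v <- token_vec(toks[i], layer)
      if (context_weight != 0) {
        v <- v + context_weight *
          token_vec(paste(prev[i], toks[i], sep = "|"), layer)
      }
      v
    }, numeric(dim)))
    list(vectors = vecs, is_marker = toks %in% c("[cls]", "[sep]"))
  }
  structure(list(name = name, n_layers = as.integer(n_layers),
                 dim = as.integer(dim), context_weight = context_weight,
                 embed_fn = embed_fn), class = "embedder")
}

#' Pool token vectors into one response vector
#'
#' Arithmetic mean of the token vectors, excluding boundary-marker tokens by
#' default (the usual choice for person/document-level features; including
#' markers is exposed as a flag).
#'
#' @param token_vectors Matrix (tokens x dim) or list of equal-length numeric
#'   vectors.
#' @param is_marker Optional logical flagging boundary-marker rows.
#' @param include_markers Keep marker rows in the mean?
#' @return Numeric vector of length dim.
#' @export
#' @examples
#' aggregate_tokens(rbind(c(1, 2), c(3, 4)))
aggregate_tokens <- function(token_vectors, is_marker = NULL,
                             include_markers = FALSE) {
  if (is.list(token_vectors)) {
    if (!length(token_vectors)) stop_invalid("no token vectors to pool")
    dims <- lengths(token_vectors)
    if (length(unique(dims)) != 1L) stop_invalid("token vectors differ in length")
    token_vectors <- do.call(rbind, token_vectors)
  }
  token_vectors <- as.matrix(token_vectors)
  if (!nrow(token_vectors)) stop_invalid("no token vectors to pool")
  keep <- if (is.null(is_marker) || include_markers) {
    rep(TRUE, nrow(token_vectors))
  } else {
    !is_marker
  }
  if (!any(keep)) stop_invalid("no non-marker tokens to pool")
  colMeans(token_vectors[keep, , drop = FALSE])
}

default_layer <- function(embedder) embedder$n_layers - 1L

check_layer <- function(embedder, layer) {
  if (layer < 1 || layer > embedder$n_layers) {
    stop_invalid("layer %d out of range for embedder '%s' (1..%d)",
                 layer, embedder$name, embedder$n_layers)
  }
}

embed_rows <- function(responses, row_fn, mode, embedder, layer) {
  df <- as.data.frame(responses)
  if (anyDuplicated(df$participant_id)) {
    stop_invalid("response set has duplicate participants; subset to one (construct, format) first")
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    toks <- tokenize_words(df$response[i])[[1]]
    if (!length(toks)) {
      stop_invalid("response for participant %s is empty after tokenization",
                   df$participant_id[i])
    }
    row_fn(toks)
  })
  embedding_matrix(do.call(rbind, rows), row_ids = df$participant_id,
                   mode = mode, layer = layer, source = embedder$name)
}

#' Contextualized response embeddings
#'
#' Runs each response's whole token sequence through the embedder once and
#' mean-pools the chosen layer's token vectors (boundary markers excluded by
#' default). The default layer is the second-to-last one, the layer commonly
#' found most reliable for document- and person-level prediction (layer 23 of
#' a 24-layer model).
#'
#' @param responses A [response_set()] restricted to one (construct, format).
#' @param embedder An [toy_embedder()]-style embedder.
#' @param layer Layer index; defaults to `n_layers - 1`.
#' @param include_markers Pool boundary-marker vectors too?
#' @return An [embedding_matrix()] with mode `"contextual"`.
#' @export
embed_contextualized <- function(responses, embedder,
                                 layer = default_layer(embedder),
                                 include_markers = FALSE) {
  check_layer(embedder, layer)
  embed_rows(responses, function(toks) {
    out <- embedder$embed_fn(toks, layer)
    aggregate_tokens(out$vectors, out$is_marker, include_markers)
  }, "contextual", embedder, layer)
}

#' Decontextualized (one word per document) response embeddings
#'
#' Embeds every word of a response in isolation — the embedder sees one word
#' at a time — then mean-pools the word vectors. The result is invariant to
#' word order by construction, which is exactly the information a contextual
#' model can use and this ablation removes.
#'
#' @inheritParams embed_contextualized
#' @return An [embedding_matrix()] with mode `"decontextual"`.
#' @export
embed_decontextualized <- function(responses, embedder,
                                   layer = default_layer(embedder),
                                   include_markers = FALSE) {
  check_layer(embedder, layer)
  embed_rows(responses, function(toks) {
    word_vecs <- lapply(toks, function(w) {
      out <- embedder$embed_fn(w, layer)
      aggregate_tokens(out$vectors, out$is_marker, include_markers)
    })
    aggregate_tokens(word_vecs)
  }, "decontextual", embedder, layer)
}

#' Concatenate feature sets column-wise
#'
#' Combines several embedding matrices over the same participants into one
#' wide feature matrix (e.g. the "all responses" model concatenating both
#' constructs' word- and text-response features).
#'
#' @param matrices List of [embedding_matrix()] objects with identical
#'   `row_ids` in identical order.
#' @return An [embedding_matrix()] whose width is the sum of the input
#'   widths; `source` lists the provenance of each block.
#' @export
combine_feature_sets <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ids <- matrices[[1]]$row_ids
  for (m in matrices[-1]) {
    if (!identical(m$row_ids, ids)) {
      bad <- union(setdiff(m$row_ids, ids), setdiff(ids, m$row_ids))
      stop_invalid("feature sets are not aligned on the same participants%s",
                   if (length(bad)) paste0(" (e.g. ",
                                           paste(utils::head(bad, 3), collapse = ", "),
                                           ")") else " (order differs)")
    }
  }
  if (length(matrices) == 1L) return(matrices[[1]])
  modes <- unique(vapply(matrices, `[[`, "", "mode"))
  embedding_matrix(
    do.call(cbind, lapply(matrices, `[[`, "values")),
    row_ids = ids,
    mode = if (length(modes) == 1L) modes else "combined",
    layer = matrices[[1]]$layer,
    source = paste(vapply(matrices, `[[`, "", "source"), collapse = "+")
  )
}
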