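`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic substream seed
#'
#' One user-facing integer seed drives every stochastic component of a run.
#' Substream seeds are derived by hashing a component label together with the
#' parent seed, so any stage (latent traits, item noise, embedding noise, fold
#' assignment, inner splits, bootstrap) can be regenerated independently of the
#' others while everything remains reproducible from the single parent seed.
#'
#' @param seed Parent integer seed.
#' @param label Character label naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' seed_child(1, "folds")
#' seed_child(1, "folds") == seed_child(1, "folds")
seed_child <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 + 97561) %% 2147483647)
}

#' Tokenize responses into normalized words
#'
#' Lowercases, strips punctuation (keeping letters, digits and apostrophes)
#' and splits on whitespace. This is the single tokenization rule used for
#' decontextualized embedding, token-stream generation and the diversity
#' index, so information statistics are computed on exactly the words the
#' models see.
#'
#' @param x Character vector of responses.
#' @return A list of character vectors, one per element of `x`.
#' @export
#' @examples
#' tokenize_words("Calm, balanced -- at peace.")
tokenize_words <- function(x) {
  x <- gsub("[^a-z0-9' ]", " ", tolower(as.character(x)))
  lapply(strsplit(trimws(x), "\\s+"),
         function(t) t[nzchar(t)])
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
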