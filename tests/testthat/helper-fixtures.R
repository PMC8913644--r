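# Shared fixtures, all generated in code.

# A small coherent synthetic study for pipeline-level tests.
small_study <- function(n = 120, seed = 42, embed_dim = 16,
                        embed_signal = 0.5) {
  generate_study(synthetic_config(
    n_participants = n, embed_dim = embed_dim, embed_signal = embed_signal,
    n_tokens_text_response = 30, seed = seed
  ))
}

# Latents + parallel items + embeddings for prediction-level tests.
make_dataset <- function(n, signal, seed, loading = sqrt(0.76), dim = 64) {
  lt <- generate_latents(n, 0.85, seed_child(seed, "lat"))
  it <- generate_scale_items(lt$hil_latent, 5, loading, c(1, 7),
                             seed_child(seed, "items"))
  em <- generate_response_embeddings(lt$hil_latent, dim, signal,
                                     seed_child(seed, "embed"))
  list(latent = lt$hil_latent, items = it, y = it$total, X = em)
}

# Direct normal-equations ridge solution on centered/standardized data —
# the independent oracle for the SVD-based fit.
ridge_oracle_coef <- function(X, y, lambda, standardize = TRUE) {
  center <- colMeans(X)
  scl <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scl[scl < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  yc <- y - mean(y)
  drop(solve(crossprod(Xs) + diag(lambda, ncol(X)), crossprod(Xs, yc)))
}

# Brute-force Pearson correlation and t-transform p-value.
pearson_oracle <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Response set fixture written to CSV files for load_study tests.
write_study_fixture <- function(dir, drop_response_for = NULL,
                                bad_item_value = FALSE) {
  ids <- c("p1", "p2", "p3")
  grid <- expand.grid(participant_id = ids,
                      construct = c("hil", "swl"),
                      format = c("words", "text"),
                      stringsAsFactors = FALSE)
  grid$response <- paste("calm content balanced", grid$participant_id)
  if (!is.null(drop_response_for)) {
    grid <- grid[!(grid$participant_id == drop_response_for &
                     grid$construct == "swl" & grid$format == "text"), ]
  }
  write.csv(grid, file.path(dir, "responses.csv"), row.names = FALSE)
  items <- data.frame(participant_id = ids,
                      item_1 = c(3L, 4L, 5L), item_2 = c(4L, 4L, 6L),
                      item_3 = c(3L, 5L, 6L), item_4 = c(2L, 4L, 7L),
                      item_5 = c(3L, 4L, 6L))
  if (bad_item_value) items$item_2[2] <- 9L
  write.csv(items, file.path(dir, "items_hil.csv"), row.names = FALSE)
  items$item_1 <- c(2L, 3L, 6L)
  items$item_2 <- c(3L, 4L, 6L)
  write.csv(items, file.path(dir, "items_swl.csv"), row.names = FALSE)
  dir
}
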