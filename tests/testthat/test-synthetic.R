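test_that("latent traits hit the requested correlation", {
  lt <- generate_latents(1e5, 0.85, seed = 1)
  expect_equal(cor(lt$hil_latent, lt$swl_latent), 0.85, tolerance = 0.01)
  expect_equal(mean(lt$hil_latent), 0, tolerance = 0.02)
  expect_equal(sd(lt$swl_latent), 1, tolerance = 0.02)

  ident <- generate_latents(1000, 1.0, seed = 7)
  expect_equal(ident$hil_latent, ident$swl_latent)

  indep <- generate_latents(1000, 0.0, seed = 7)
  expect_lt(abs(cor(indep$hil_latent, indep$swl_latent)), 0.1)

  expect_error(generate_latents(1000, 1.2, seed = 1), "rho")
  expect_error(generate_latents(2, 0.5, seed = 1), "at least 3")
})

test_that("scale items realize the loading-squared inter-item correlation", {
  lt <- generate_latents(5000, 0.85, seed = 3)
  z <- lt$hil_latent

  pure <- generate_scale_items(z, 5, 1, c(1, 7), seed = 4)
  expect_equal(inter_item_mean(pure$items_continuous), 1, tolerance = 1e-12)
  expect_gt(inter_item_mean(pure), 0.9)

  noise <- generate_scale_items(z, 5, 0, c(1, 7), seed = 5)
  expect_lt(abs(inter_item_mean(noise$items_continuous)), 0.05)

  # calibration point: loading sqrt(0.73) -> pre-rounding inter-item r 0.73
  cal <- generate_scale_items(z, 5, sqrt(0.73), c(1, 7), seed = 6)
  expect_equal(inter_item_mean(cal$items_continuous), 0.73, tolerance = 0.03)

  expect_true(all(cal$items >= 1 & cal$items <= 7))
  expect_equal(cal$total, rowSums(cal$items))
  expect_error(generate_scale_items(numeric(0), 5, 0.5, c(1, 7), 1), "empty")
  expect_error(generate_scale_items(z, 5, 1.2, c(1, 7), 1), "item_loading")
})

test_that("loading_for_total_reliability inverts Spearman-Brown", {
  for (rel in c(0.6, 0.81, 0.95)) {
    a <- loading_for_total_reliability(rel, 5)
    expect_equal(spearman_brown(a^2, 5), rel, tolerance = 1e-12)
  }
})

test_that("synthetic embeddings carry the configured signal share", {
  lt <- generate_latents(20000, 0.85, seed = 9)
  z <- lt$hil_latent

  exact <- generate_response_embeddings(z[1:500], 8, 1, seed = 10)
  fit <- lm(z[1:500] ~ exact$values)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fit by design
  expect_equal(r2, 1, tolerance = 1e-9)

  # closed-form multiple correlation from the generating model:
  # R^2 = S / (1 + S), S = signal/(1-signal) * sum(w^2)
  em <- generate_response_embeddings(z, 50, 0.5, seed = 11)
  w <- attr(em, "gen_weights")
  S <- 0.5 / 0.5 * sum(w^2)
  R_expected <- sqrt(S / (1 + S))
  R_fit <- sqrt(summary(lm(z ~ em$values))$r.squared)
  expect_equal(R_fit, R_expected, tolerance = 0.02)

  expect_true(all(is.finite(em$values)))
  expect_equal(unname(apply(em$values, 2, sd)), rep(1, 50), tolerance = 0.05)
  expect_identical(em$mode, "synthetic")
  expect_error(generate_response_embeddings(z, 8, 1.5, seed = 1), "signal")
  expect_error(generate_response_embeddings(z, 0, 0.5, seed = 1), "dim")
})

test_that("token responses follow the format and the trait tilt", {
  lt <- generate_latents(2000, 0.85, seed = 12)
  z <- lt$hil_latent
  vocab <- default_vocab()$hil

  words <- generate_token_responses(z, vocab, 10, seed = 13, tilt = 1)
  lens <- lengths(tokenize_words(words$response))
  expect_true(all(lens == 10))
  expect_s3_class(words, "response_set")

  # degenerate vocabulary: every response is that token; corpus DI = 1
  one <- data.frame(token = "calm", weight = 1, valence = 0L)
  mono <- generate_token_responses(z[1:50], one, 10, seed = 14)
  expect_true(all(mono$response == paste(rep("calm", 10), collapse = ", ")))
  expect_equal(diversity_index(mono$response)$diversity_index, 1)

  # uniform untilted vocabulary of 8 tokens: corpus DI ~ 8
  uni <- data.frame(token = letters[1:8], weight = 1, valence = 0L)
  flat <- generate_token_responses(z, uni, 10, seed = 15, tilt = 1)
  expect_equal(diversity_index(flat$response)$diversity_index, 8,
               tolerance = 0.05)

  # positive tokens become more frequent for high-trait participants
  tilted <- generate_token_responses(z, vocab, 10, seed = 16, tilt = 1)
  pos <- vocab$token[vocab$valence == 1]
  share <- vapply(tokenize_words(tilted$response),
                  function(t) mean(t %in% pos), numeric(1))
  expect_gt(cor(share, z), 0.5)

  bad <- vocab; bad$weight[1] <- -1
  expect_error(generate_token_responses(z, bad, 10, seed = 1), "non-negative")
})

test_that("a full study is coherent and bit-reproducible", {
  cf <- synthetic_config(n_participants = 608, embed_dim = 16,
                         n_tokens_text_response = 20, seed = 99)
  s1 <- generate_study(cf)
  s2 <- generate_study(cf)
  expect_identical(s1, s2)

  expect_length(s1$latents$hil_latent, 608)
  expect_equal(nrow(s1$items_hil$items), 608)
  expect_equal(nrow(s1$responses), 4 * 608)
  for (em in s1$embeddings) expect_equal(dim(em)[1], 608)

  # totals correlate strongly under the default latent correlation
  expect_gt(cor(s1$items_hil$total, s1$items_swl$total), 0.6)
})

test_that("token responses and embeddings are independent of item noise given the latent", {
  # regenerating items with a different seed leaves responses and embeddings
  # untouched: no leakage path from item noise into the predictors
  cf1 <- synthetic_config(n_participants = 80, embed_dim = 8, seed = 5)
  s <- generate_study(cf1)
  it2 <- generate_scale_items(s$latents$hil_latent, 5,
                              cf1$item_loading_hil, c(1, 7),
                              seed = 12345)
  expect_false(identical(it2$items, s$items_hil$items))
  s_again <- generate_study(cf1)
  expect_identical(s$embeddings, s_again$embeddings)
  expect_identical(s$responses, s_again$responses)
})

test_that("write_study round-trips through load_study", {
  dir <- withr::local_tempdir()
  study <- small_study(n = 25, seed = 8)
  write_study(study, dir)
  bundle <- load_study(dir)
  expect_equal(bundle$participant_id, study$participant_id)
  expect_equal(bundle$items_hil$total, study$items_hil$total)
  expect_equal(bundle$items_swl$items, study$items_swl$items,
               ignore_attr = TRUE)
  expect_equal(nrow(bundle$responses), nrow(study$responses))
})
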