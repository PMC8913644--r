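test_that("pearson_r matches the brute-force formula", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 6)
  got <- pearson_r(a, b)
  oracle <- pearson_oracle(a, b)
  expect_equal(got$r, oracle$r, tolerance = 1e-12)
  expect_equal(got$p, oracle$p, tolerance = 1e-12)

  expect_equal(pearson_r(a, a)$r, 1)
  expect_equal(pearson_r(a, -a)$r, -1)
  expect_error(pearson_r(a, rep(1, 5)), "constant")
  expect_error(pearson_r(a, b[1:4]), "length")
})

make_result <- function(y, yhat, name = "m") {
  prediction_result(y, yhat, rep(1:5, length.out = length(y)),
                    lambda_per_fold = rep(1, 5), outcome_name = name,
                    model_name = name)
}

test_that("paired error t-test separates dominated models and respects symmetry", {
  set.seed(41)
  y <- rnorm(100, 20, 4)
  truth <- make_result(y, y + rnorm(100, 0, 0.01))
  expect_equal(compare_same_outcome(truth, truth)$statistic, 0)
  expect_equal(compare_same_outcome(truth, truth)$p_value, 1)

  # constant-magnitude perturbation: clearly dominated
  worse <- make_result(y, y + sample(c(-2, 2), 100, TRUE))
  cmp <- compare_same_outcome(truth, worse)
  expect_lt(cmp$p_value, 0.001)
  expect_lt(cmp$statistic, 0)

  # swapping models flips the sign, p unchanged
  rev <- compare_same_outcome(worse, truth)
  expect_equal(rev$statistic, -cmp$statistic)
  expect_equal(rev$p_value, cmp$p_value)

  # equal-magnitude sign flips are indistinguishable under absolute error
  e <- sample(c(-1, 1), 100, TRUE)
  ma <- make_result(y, y + e)
  mb <- make_result(y, y - e)
  expect_equal(compare_same_outcome(ma, mb)$p_value, 1)

  # opposite constant offsets: glaring to raw error, invisible to absolute
  pa <- make_result(y, y + 1 + rnorm(100, 0, 0.05))
  pb <- make_result(y, y - 1 + rnorm(100, 0, 0.05))
  expect_lt(compare_same_outcome(pa, pb, error = "raw")$p_value, 0.001)
  expect_gt(compare_same_outcome(pa, pb)$p_value, 0.01)

  other <- make_result(y + rnorm(100), y)
  expect_error(compare_same_outcome(truth, other), "compare_bootstrap")
})

test_that("bootstrap overlap is calibrated at the degenerate ends", {
  set.seed(42)
  y <- rnorm(200, 20, 4)
  good <- make_result(y, y + rnorm(200, 0, 1), "good")
  expect_gt(compare_bootstrap(good, good, n_boot = 500, seed = 1)$p_value, 0.8)
  expect_equal(compare_bootstrap(good, good, n_boot = 500, seed = 1,
                                 resample = "paired")$p_value, 1)

  bad <- make_result(y, rnorm(200), "bad")
  cmp <- compare_bootstrap(good, bad, n_boot = 500, seed = 2)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$statistic, 0)

  # deterministic under seed, in [0, 1]
  again <- compare_bootstrap(good, bad, n_boot = 500, seed = 2)
  expect_identical(cmp$p_value, again$p_value)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_warning(compare_bootstrap(good, bad, n_boot = 50, seed = 3),
                 "coarse")
  expect_error(compare_bootstrap(good, make_result(y[1:100], y[1:100])),
               "aligned")
})

test_that("inter-item and corrected item-total means match hand computation", {
  ident <- matrix(rep(c(3, 4, 5, 6), 3), ncol = 3)
  expect_equal(inter_item_mean(ident), 1)
  expect_equal(corrected_item_total_mean(ident), 1)

  two <- cbind(c(1, 2, 4, 5), c(2, 1, 5, 4))
  expect_equal(inter_item_mean(two), cor(two[, 1], two[, 2]))

  k3 <- cbind(c(1, 3, 4, 7), c(2, 2, 5, 6), c(1, 4, 4, 6))
  hand <- mean(c(cor(k3[, 1], k3[, 2] + k3[, 3]),
                 cor(k3[, 2], k3[, 1] + k3[, 3]),
                 cor(k3[, 3], k3[, 1] + k3[, 2])))
  expect_equal(corrected_item_total_mean(k3), hand, tolerance = 1e-12)
  expect_error(corrected_item_total_mean(two), "at least 3")

  set.seed(43)
  indep <- matrix(rnorm(5000 * 5), ncol = 5)
  expect_lt(abs(inter_item_mean(indep)), 0.05)

  const <- cbind(c(1, 2, 3), c(2, 2, 2))
  expect_error(inter_item_mean(const), "zero variance")
})

test_that("alpha follows its defining formula and the parallel-item closed form", {
  ident <- matrix(rep(c(3, 4, 5, 6), 3), ncol = 3)
  expect_equal(cronbach_alpha(ident), 1)

  set.seed(44)
  indep <- matrix(rnorm(4000 * 5), ncol = 5)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)

  lt <- generate_latents(4000, 0.85, seed = 45)
  par <- generate_scale_items(lt$hil_latent, 5, sqrt(0.73), c(1, 7), seed = 46)
  a <- cronbach_alpha(par$items_continuous)
  expect_equal(a, spearman_brown(inter_item_mean(par$items_continuous), 5),
               tolerance = 0.02)
})

test_that("reliability report orders its statistics as expected", {
  study <- small_study(n = 500, seed = 47)
  rep_h <- reliability_report(study$items_hil)
  expect_gt(rep_h$corrected_item_total_mean_r, rep_h$inter_item_mean_r)
  expect_true(rep_h$alpha <= 1)
  expect_equal(rep_h$ceiling, rep_h$corrected_item_total_mean_r)
})

test_that("reliability ceilings follow both conventions", {
  expect_equal(reliability_ceiling(1, convention = "paper"), 1)
  expect_equal(reliability_ceiling(1, 1, convention = "classical"), 1)
  expect_equal(reliability_ceiling(0.84, convention = "paper"), 0.84)
  expect_equal(reliability_ceiling(0.81, 1, convention = "classical"), 0.9)
  expect_equal(reliability_ceiling(0.8, 0.9, convention = "classical"),
               sqrt(0.72))
  expect_error(reliability_ceiling(0, convention = "paper"), "reliabilities")
  expect_error(reliability_ceiling(1.2, convention = "paper"), "reliabilities")
})

test_that("diversity index is exact on closed-form corpora", {
  uni <- diversity_index(list(letters[1:8]))
  expect_equal(uni$entropy_bits, 3)
  expect_equal(uni$diversity_index, 8)

  aabb <- diversity_index(list(c("a", "a", "b", "b")))
  expect_equal(aabb$diversity_index, 2)

  half <- diversity_index(list(c("a", "a", "b", "c")))
  expect_equal(half$entropy_bits, 1.5)
  expect_equal(half$diversity_index, 2^1.5)

  expect_error(diversity_index(list()), "empty")
})

test_that("diversity agrees with an independent entropy implementation", {
  skip_if_not_installed("vegan")
  set.seed(48)
  tokens <- sample(letters[1:12], 400, TRUE, prob = runif(12))
  di <- diversity_index(list(tokens))
  h_nats <- vegan::diversity(as.numeric(table(tokens)), index = "shannon")
  expect_equal(di$diversity_index, exp(h_nats), tolerance = 1e-10)
})

test_that("diversity respects bounds, normalization and self-merge invariance", {
  resp <- c("Calm, BALANCED!", "calm storm", "maybe calm")
  di <- diversity_index(resp)
  expect_gte(di$diversity_index, 1)
  expect_lte(di$diversity_index, di$distinct_tokens)
  expect_equal(di$distinct_tokens, 4)

  merged <- diversity_index(c(resp, resp))
  expect_equal(merged$diversity_index, di$diversity_index)
  expect_equal(merged$token_count, 2 * di$token_count)
})

test_that("correlation magnitudes map onto the interpretation bands", {
  expect_equal(interpret_r(0.85), "very strong")
  expect_equal(interpret_r(0.47), "moderate")
  expect_equal(interpret_r(0.10), "negligible")
  expect_equal(interpret_r(-0.65), "strong")
  expect_equal(interpret_r(0.2), "weak")
  expect_equal(interpret_r(0.39), "weak")
  expect_equal(interpret_r(0.4), "moderate")
  expect_equal(interpret_r(0.6), "strong")
  expect_equal(interpret_r(0.8), "very strong")
  expect_error(interpret_r(1.2), "exceed")
})
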