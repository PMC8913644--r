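---
title: "Predicting well-being rating scales from word and text responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting well-being rating scales from word and text responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Standard psychological assessment asks people to rate closed-ended
statements on numeric scales. Language-based assessment instead asks
open-ended questions — "describe your life in ten words", or a free-text
answer — quantifies the answers as word-embedding features from a language
model, and trains a regression from those features to the rating-scale
score. Two questions drive the analysis: how closely can language-based
scores converge with established scales such as the Harmony in Life Scale
(HILS) and the Satisfaction with Life Scale (SWLS), and how does that
convergence compare with the scales' own reliability, which bounds the
correlation any alternative measure can reach (attenuation)?

`lbassess` implements the full pipeline — simulation, embedding, training,
evaluation — so that every statistical component can be exercised and
verified end to end without access to survey data or a transformer backend.

## The synthetic world

No response-level data ships with the package. Instead, a generator
(`generate_study()`) produces studies from a known ground truth, and the
test suite asserts that the pipeline recovers that truth. The generating
model is deliberately the simplest structure that reproduces every quantity
the analysis computes:

* **Latent traits.** Two standard-normal traits (harmony, life
  satisfaction) with correlation `rho_latent` (default 0.85).
* **Rating items.** Each scale has `n_items = 5` parallel indicators:
  `loading * trait + sqrt(1 - loading^2) * noise`, mapped affinely onto the
  1–7 grid (midpoint at the trait mean, six trait SDs spanning the range)
  and rounded. The population inter-item correlation before rounding is
  `loading^2`; the default loadings `sqrt(0.76)` (HILS) and `sqrt(0.73)`
  (SWLS) target the inter-item values reported for these scales. Rounding
  to the integer grid attenuates the realized correlations slightly
  (roughly 0.72/0.67 at the defaults); this is documented rather than
  compensated, because real item responses are also discretized.
  `loading_for_total_reliability()` inverts the Spearman–Brown relation
  when a specific total-score reliability is wanted.
* **Embeddings.** Each feature is `sqrt(signal) * w_j * trait +
  sqrt(1 - signal) * noise`, scaled to unit variance, with fixed random
  weights `w_j`. `embed_signal` is the fraction of feature variance carried
  by the trait: at 0 the features are pure noise, at 1 the trait is an
  exact linear function of them, so cross-validated accuracy must approach
  the attenuation ceiling `sqrt(reliability of the total score)`. The
  default dimensionality is 64: far below transformer width, but the
  effective (trait-relevant) rank of pooled transformer features is low,
  and 64 noise dimensions at N ≈ 600 already put ridge regression in the
  regime where regularization genuinely matters. The default
  `embed_signal = 0.5` makes the default study an easy, near-ceiling
  prediction problem; weaker regimes are exercised explicitly in tests.
* **Token streams.** Responses are sampled from a small per-construct
  vocabulary whose positive/negative tokens are tilted by the trait:
  sampling odds are multiplied by `exp(tilt * valence * trait)` — a
  bounded, monotone, easily invertible tilt. Word-format responses have
  exactly 10 tokens; text-format responses default to 70, matching the
  order of magnitude of free-text answers to single questions.
  `generate_bigram_responses()` additionally produces text whose signal
  lives *only in word order* (trait-tilted orientation of fixed token
  pairs, constant unigram counts), which is what separates contextualized
  from decontextualized features.

All randomness flows from one integer seed through labelled substreams
(`seed_child()`), so identical configurations are bit-reproducible and any
component can be regenerated independently.

What the generator does **not** emulate: real English prose, response
styles (acquiescence, social desirability), length variation in text
answers, non-Gaussian trait distributions, and the heavy-tailed token
frequencies of natural vocabulary (a few dozen types versus hundreds in
real responses, so synthetic diversity indices are far smaller than
real-corpus values). Passing tests therefore demonstrate the statistical
machinery, not linguistic realism.

## Embedding extraction

Two regimes are implemented behind a pluggable embedder contract:

* **Contextualized**: the whole token sequence passes through the embedder
  once, so a token's vector depends on its neighbours; one layer is
  selected and its token vectors are pooled.
* **Decontextualized**: every word is embedded as its own one-word
  document and the word vectors are pooled — an ablation that removes all
  order information (it is permutation-invariant by construction).

Decisions the interface fixes:

* **Pooling** is the arithmetic mean over real-word tokens, excluding
  boundary markers; pooling over markers too is available by flag. Mean
  pooling is the standard choice for person- and document-level features.
* **Layer**: the default is the second-to-last layer (layer 23 of a
  24-layer model), the layer repeatedly found most reliable for
  human-level prediction.
* **Tokenization** lowercases, strips punctuation (keeping apostrophes)
  and splits on whitespace — appropriate for comma-separated word lists —
  and the *same* rule feeds the diversity index, so information statistics
  describe exactly the words the models saw.
* **Combining response sets** ("all responses" models) concatenates the
  pooled vectors column-wise rather than averaging them, preserving
  response-specific information.

The shipped `toy_embedder()` hash-seeds a deterministic Gaussian vector per
(token, layer); with `context_weight != 0` it adds a hashed vector of the
(previous token, token) pair, giving a minimal order-sensitive embedder.
Real transformer backends can be adapted to the same contract; sub-word
pieces of one word should be mean-pooled to a word vector before response
pooling.

## Training scheme

`cross_validated_predict()` implements the assessment regression:

* ridge regression (SVD-solved, intercept unpenalized, features z-scored
  within each training fold — the penalty grid spans 32 orders of
  magnitude, which is only meaningful on a common feature scale);
* 10-fold outer cross-validation, stratified on 4 quantile bins of the
  outcome (ties broken by stable rank, so integer scale totals bin
  deterministically);
* within each outer training fold, a single stratified 75/25 split
  selects the penalty from the grid `10^-16, 10^-15, …, 10^16`;
* the model is refit on the whole training fold at the selected penalty
  and predicts the held-out fold; accuracy is the Pearson correlation
  between observed scores and the pooled out-of-fold predictions.

Numerical choices worth knowing:

* **Penalty selection score.** Candidates are scored by the Pearson
  correlation between assessment-split observations and predictions — the
  same metric used for final accuracy — with constant predictions scored
  as worst. Scoring by RMSE instead (available as
  `selection_metric = "rmse"`) always favors maximal shrinkage on
  signal-free data; the resulting predictions collapse onto training-fold
  means, which anti-correlate with the held-out scores and bias the pooled
  null accuracy visibly negative. Correlation scoring avoids that but is
  scale-blind, so near-ties (within 10^-3, e.g. when shrinkage changes
  only the prediction scale because the signal is low-rank) are broken by
  assessment RMSE and then toward the smallest penalty.
* **Significance of a cross-validated accuracy.** Pooled out-of-fold
  predictions are not independent across observations: fold A's model was
  trained on fold B and vice versa, which roughly doubles the variance of
  the pooled correlation under the null, and heavily shrunk folds
  contribute fold-mean artifacts. The naive `N - 2` t transform is
  therefore anti-conservative (we measure 13–16% rejection at a nominal
  5%). Because the entire cross-validation fit is a linear smoother
  `yhat = H y` once folds, penalties and scalings are fixed, `accuracy_p`
  is computed by Monte Carlo: draw signal-free outcomes `y*`, form
  `H y*` with the fitted smoother frozen, and report the two-sided tail
  probability of the observed accuracy (1000 draws, seeded, add-one
  convention). The acceptance suite verifies 5% ± 3 rejection under the
  null. Plain correlations (`pearson_r()`) keep the classical t transform.
* **Degenerate inputs.** Constant outcomes, constant items, empty
  responses and misaligned feature sets are rejected with typed errors
  rather than propagating NaN.

## Evaluation statistics

* **Reliability as ceiling.** Mean inter-item correlation, mean corrected
  item-total correlation and Cronbach's alpha are computed from the item
  matrix; externally estimated test–retest reliabilities can be supplied
  as constants. The package follows the convention of comparing an
  observed accuracy directly against these reliability values
  (`reliability_ceiling(..., convention = "paper")`); the classical
  attenuation formula `sqrt(rel_y * rel_x)` is also available.
* **Same-outcome model comparison** uses a paired t-test on per-participant
  errors. Raw cross-validated errors are near-zero-mean for any competent
  model, so the default compares absolute errors; raw and squared are
  available by flag.
* **Cross-outcome comparison** bootstraps each model's accuracy
  distribution by resampling participants and summarizes the overlap of
  the two distributions as a two-sided crossing probability. The two
  distributions are resampled *independently* by default: the fitted
  predictions freeze each model's alignment with its training noise, so
  jointly resampled (paired) differences understate the variability of an
  accuracy difference several-fold and declare equal models different;
  independent resampling matches the observed variability of accuracy
  differences between refitted models of genuinely equal strength far
  better. Paired resampling remains available. Even so, this comparison
  tests a *conditional* question — are these two fitted models equally
  accurate on new participants — not the unconditional one — would two
  freshly trained models of this kind differ. Fit-level noise (fold
  assignment, penalty selection, training-noise alignment) is invisible to
  any resampling of fixed predictions, so in simulation studies that refit
  models on every replicate the comparison over-rejects the unconditional
  null; this is a known limitation, shared by every procedure that
  bootstraps fixed predictions.
* **Diversity index.** Shannon entropy (bits) of the pooled token
  frequencies, reported as `2^H` — the effective number of distinct token
  types. Log base 2 is forced by that definition.
* **Interpretation bands.** |r| of 0.20–0.39 weak, 0.40–0.59 moderate,
  0.60–0.79 strong, 0.80–1.00 very strong; below 0.20 the package says
  "negligible" rather than erroring.

## Problem sizes used by the test suite

Simulation-backed properties are asserted at sizes chosen to make the
asserted quantity stable while keeping the default run quick: ridge/oracle
equivalence on 100 random instances up to 50 × 10; null calibration and
bootstrap calibration on 200 generated datasets of N = 300; attenuation
ceiling recovery on 10 studies of N = 608 (the design size) across five
signal levels with latents and items held fixed per seed so signal levels
are compared paired; reliability recovery at N = 5000. The full suite runs
in a few minutes on one CPU.

## Known limitations

* The generator's linearity means ridge regression is the correctly
  specified model; the pipeline's behaviour under non-linear
  trait–language relations is not exercised.
* The unconditional calibration of the bootstrap overlap comparison is
  unattainable from fixed predictions (see above); treat its p-values as
  conditional statements about the fitted models at hand.
* Diversity indices on synthetic vocabularies are orders of magnitude
  smaller than real-corpus values; only their exact information-theoretic
  properties (bounds, merge invariance, closed-form cases) are
  meaningful, not their magnitudes.
* Test–retest reliability is accepted as user-supplied constants; the
  package does not model measurement across time.
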