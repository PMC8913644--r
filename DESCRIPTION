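Package: lbassess
Title: Language-Based Assessment of Subjective Well-Being from Word and
    Text Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts rating-scale measures of subjective well-being
    (Harmony in Life, Satisfaction with Life) from open-ended word- and
    text-responses quantified as word-embedding features. Implements the
    full analysis pipeline: a synthetic study generator with known ground
    truth (correlated latent traits, parallel-indicator rating items,
    signal-bearing embeddings, trait-tilted token streams), contextualized
    and decontextualized embedding extraction behind a pluggable embedder
    contract, ridge regression trained with stratified ten-fold
    cross-validation and inner 75/25 penalty selection over a wide
    penalty grid, and evaluation statistics: Pearson accuracy with
    significance, paired error t-tests and bootstrap comparison of
    correlated prediction accuracies, scale reliability (inter-item mean,
    corrected item-total mean, Cronbach's alpha) as attenuation ceilings,
    a Shannon-entropy diversity index, and correlation interpretation
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
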