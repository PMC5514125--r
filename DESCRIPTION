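Package: finchplayback
Title: Playback Analysis of Individual Vocal Recognition in Zebra Finch Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design, simulate and analyse playback experiments on
    individual vocal recognition in zebra finches. Covers amplitude-threshold
    call segmentation, spectral feature extraction (sorting features and a
    14-feature sonogram set), k-means call-type clustering, generation of
    block/series playback schedules with stimulus preprocessing, answer-window
    scoring of vocal exchanges, linear mixed models with posterior-simulation
    credible intervals and exceedance probabilities for familiarity contrasts,
    habituation and repeatability checks, and a PCA-LDA index of individual
    call distinctiveness. A seeded synthetic-data generator produces call
    waveforms, pair exchange streams and playback response logs with planted
    effects so every pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    yaml
Config/testthat/edition: 3
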