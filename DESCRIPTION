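Package: popnoise
Title: Population Coding and Noise-Correlation Analysis for Trial-Structured
    Visual Cortex Recordings
Version: 0.1.0
Authors@R:
    person("V1 Population", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for trial-structured extracellular recordings
    from primary visual cortex under drifting-grating protocols: double von
    Mises orientation-tuning fits with orientation selectivity index, ROC
    (AUC) based signal-to-noise ratio, single-unit and multi-unit Fano
    factors, pairwise noise correlation and covariance with evoked versus
    spontaneous decorrelation of fast-spiking/regular-spiking pairs,
    Panzeri-Treves bias-corrected mutual information as a function of
    population size, waveform-based fast-spiking classification, and a
    nonparametric group-comparison layer. Includes a doubly-stochastic
    (shared-gain Poisson) synthetic recording generator with analytic
    oracles for implanted correlations, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
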