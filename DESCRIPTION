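Package: remslope
Title: Aperiodic Spectral Dynamics of Phasic and Tonic REM Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the heterogeneity of rapid eye movement (REM)
    sleep through the aperiodic (1/f-like) component of the EEG power
    spectrum. Implements IRASA (irregularly resampled auto-spectral
    analysis) decomposition of 4-s epochs into fractal and oscillatory
    power with log-log slope fitting in configurable bands, rule-based
    phasic/tonic microstate segmentation from electrooculogram deflections,
    amplitude-based rapid eye movement detection, within-episode lagged
    rank cross-correlation between eye-movement amplitude and aperiodic
    slope time series with Fisher-z inference and Bayesian population
    prevalence, and cohort-level paired contrasts with ROC/AUC and
    false-discovery-rate control. A synthetic polysomnography generator
    with known ground truth (state-dependent spectral exponents, scripted
    eye-movement bursts) makes every stage testable without clinical
    recordings; recordings round-trip through a minimal EDF writer/reader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
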