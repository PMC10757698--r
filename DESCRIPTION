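Package: eodassay
Title: Neuro-Behavioral Assay Analysis of Electric Organ Discharge Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a neuro-behavioral anesthesia assay based on
    the electric organ discharge (EOD) of the weakly electric fish Apteronotus
    leptorhynchus. Provides a ground-truth-annotated synthetic EOD generator
    (frequency profiles, sech-shaped type-2 chirps, amplitude collapse episodes,
    multi-fish randomized block experiments), adaptive dominant-frequency
    tracking with a sliding search band, chirp detection and shape fitting,
    temperature (Q10) adjustment, a four-parameter frequency-recovery model,
    and the assay's statistical procedures: the exact two-tailed sign test with
    its minimal-sample-size design rule, a split-plot linear mixed model for
    dose-dependent recovery, and a Bonferroni-corrected sliding-window
    estimator of recovery time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
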