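Package: pfcplast
Title: Longitudinal Analysis of Prefrontal Population Plasticity During Task Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chronic multielectrode-array recordings from
    prefrontal cortex across staged training of a delayed match-to-sample task.
    Provides a synthetic-experiment generator with planted plasticity effects
    (inhomogeneous-Poisson spiking with shared multiplicative gains, band-limited
    LFP), responsiveness screening, population PSTHs, fixation-period noise
    correlation versus electrode distance with ANCOVA phase comparison,
    multitaper LFP band-power time courses, pseudo-population decoding with
    cross-validated shuffle nulls, demixed principal component analysis, and a
    sliding-window three-way ANOVA of task-variable selectivity, orchestrated by
    an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
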