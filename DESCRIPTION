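Package: sfauc
Title: Analytic Quantification of Sympathetic Arousal from Spontaneous
    Skin Conductance Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing tonic electrodermal activity under a
    linear time-invariant (LTI) convolution model of sudomotor nerve
    activity. Implements the skin-conductance-level corrected
    time-integral (AUC) arousal statistic, deterministic detection of
    spontaneous fluctuations, least-squares finite impulse response
    (FIR) deconvolution of overlapping responses, the spectral-domain
    formulation of the model (convolution theorem, pulse-train Fourier
    coefficients, naive inverse-filter deconvolution), a synthetic
    sudomotor-burst study simulator with ground truth, and the
    validation statistics (regression, two-factor repeated-measures
    ANOVA, point-biserial classification, explained-variance F test)
    used to assess the measure. Includes delimited-text readers and
    writers and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
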