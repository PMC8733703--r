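Package: hybridoe
Title: Hybrid Modeling of Fed-Batch CHO Bioprocesses Across Scales and
    Intensified Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Serial hybrid (grey-box) modeling of fed-batch Chinese hamster
    ovary cell cultivations: a small feed-forward neural network estimates the
    specific growth and product formation rates as functions of process inputs
    (cultivation temperature, feed glucose level, amino acid concentrations),
    and those rates drive mechanistic viable-cell and titer mass balances with
    dilution by bolus or continuous feeding.  Includes a calibrated ground-truth
    simulator for shake-flask full-factorial and 15 L static/intensified
    design-of-experiments campaigns, Levenberg-Marquardt training through the
    integrated states with weight decay, repeated random-split and
    leave-one-run-out cross-validation, ensemble model averaging with SD and
    confidence bands, NRMSE evaluation, smoothing-spline specific-rate
    estimation, and a PCA / correlation / backward-elimination input-selection
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
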