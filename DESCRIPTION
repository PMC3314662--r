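Package: tlr4scen
Title: Paired-Design Expression Analysis and Scenario Simulation of TLR4 Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain from paired uterine-horn microarray intensities to a
    simulated maternal innate-immune response. Provides lowess normalization and a
    per-probe-set linear mixed model for paired two-condition designs with
    Bonferroni control; construction of minimum-, average- and maximum-response
    protein-abundance scenarios from probe-level expression ratios (including a
    constituent-product rule for protein complexes); a deterministic mass-action
    ODE model of LPS-stimulated TLR4 signalling with a TNF readout; finite
    difference sensitivity coefficients on the TNF peak; and scenario comparison
    of peak height and peak interval. A synthetic-data generator emulates the
    paired 3-animal, 2-condition array design so the whole chain is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
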