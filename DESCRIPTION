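Package: lrsam
Title: Logistic-Regression Significance Analysis of Multiple Reaction
    Monitoring Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protein-level significance tests for targeted (multiple
    reaction monitoring, MRM) proteomics experiments that compare two
    groups of subjects. Group membership is modelled by logistic
    regression on a protein's peptide log2 relative intensities, giving
    a likelihood-ratio test, full and pooled Wald tests, a
    summed-covariate Wald test, and a variance-component score test
    whose null is a mixture of chi-square distributions. The four
    MSstats-style linear mixed model variants (fixed or random subject
    and run effects, with AIC-based selection) are provided as
    baselines, together with a generative simulator for spike-in MRM
    designs and a Monte-Carlo harness estimating type I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    limma,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
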