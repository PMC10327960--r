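Package: frpdeconv
Title: Deconvolution of Fixation-Related Potentials with Refixation
    Scanpath Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electroencephalography (EEG) co-registered
    with eye movements in free viewing. Categorizes fixations in scanpaths
    into precursor fixations, refixations, ordinary and leftover fixations
    using a revisit-radius rule; builds mass-univariate regression designs
    with treatment-coded categories and quantile-knotted B-spline bases for
    oculomotor covariates; time-expands them into a sparse design over the
    continuous EEG recording and estimates overlap-corrected fixation-related
    potentials (FRPs) by iterative sparse least squares (LSMR); reconstructs
    marginal per-category waveforms at mean covariate levels; and runs
    region-of-interest window statistics with repeated-measures ANOVA
    (Huynh-Feldt sphericity correction) and Newman-Keuls post hoc tests.
    Includes a synthetic scanpath and forward EEG simulator with full ground
    truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
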