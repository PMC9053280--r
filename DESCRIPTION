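Package: breathtdm
Title: Real-Time Breath Metabolomics for Therapeutic Drug Monitoring of
    Valproic Acid
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A reusable analysis pipeline for real-time exhaled-breath
    metabolomics acquired by secondary electrospray ionisation
    high-resolution mass spectrometry (SESI-HRMS). Turns time-resolved
    centroided spectra into a measurements-by-features matrix of
    exhalation-normalised areas (nAUC) via exhalation detection, spectral
    alignment, kernel-density feature consolidation and breath-correlation
    filtering; predicts total and free serum valproic-acid concentration
    with dual RReliefF/random-forest predictor selection, empirical-Bayes
    batch adjustment and exponential-kernel Gaussian-process regression
    evaluated by Lin's concordance correlation coefficient; and derives
    side-effect and drug-response risk scores through Welch differential
    testing, accurate-mass (mummichog-style) and GSEA pathway enrichment,
    and a first-principal-component score thresholded at Youden's index.
    A seeded synthetic-cohort generator with full ground truth makes every
    stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    kernlab,
    mzR,
    optparse,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
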