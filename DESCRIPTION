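Package: wesconcord
Title: Multi-Institution Concordance Analysis for Clinical Whole-Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between somatic variant call sets, copy-number
    segmentations, and complex biomarker scores (HRD, TMB, MSI) produced by
    multiple laboratories or pipelines for the same tumor cases. Builds
    consensus variant references and computes positive percentage agreement
    (PPA) and positive predictive value (PPV) with exact Clopper-Pearson
    intervals; performs base-resolution pairwise copy-number comparison with
    correction for discordant whole-genome-duplication calls; estimates
    pairwise Pearson correlations and systematic deviations of biomarker
    scores via zero-intercept regression; and separates wet-lab from
    bioinformatic variability through per-sample standard deviations of
    replicate measurements. A seeded synthetic-cohort generator reproduces
    the statistical structure of multi-center discordance so every stage can
    be validated against a known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
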