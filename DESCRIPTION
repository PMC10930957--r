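Package: mitocirc
Title: Circular Mitochondrial Reference Rotation and D-Loop lncRNA Biomarker
    Analysis
Version: 0.1.0
Authors@R:
    person("Mitocirc", "Developers", email = "mitocirc@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying transcripts that span the linearization
    junction of a circular genome, motivated by the mitochondrial D-loop long
    non-coding RNAs MDL1 and MDL1AS. Provides circular coordinate algebra
    (rotation of the reference origin, annotation liftover, junction-padded
    linear references), a strand-aware short-read simulator for circular
    transcript models, a desk-scale seed-and-extend read mapper with
    featureCounts-style overlap counting and RPKM normalization, synthetic
    patient-cohort generation with expression-dependent survival, group
    comparison statistics (ANOVA, Sidak, Welch, chi-square, Benjamini-Hochberg
    FDR), and survival-biomarker evaluation from first principles (empirical
    ROC with DeLong confidence intervals, Youden-index cutoffs, Kaplan-Meier
    curves, log-rank test, and univariate Cox regression with Efron ties).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
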