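Package: OncoCompare
Title: COMPARE-Style Mode-of-Action Inference and Target-Validation
    Statistics for Phytochemical Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and statistical validation chain for
    phytochemical anticancer screens run against the NCI-60 tumor cell
    line panel. Converts docking free energies to predicted inhibition
    constants and runs correlation quality control; infers mode of
    action by COMPARE-style correlation of cytotoxicity profiles against
    annotated agent libraries (oncobiograms); selects proteomic
    correlates of drug response, clusters them with Ward's method, and
    tests cluster-response association by chi-squared; fits microscale
    thermophoresis titrations with the quadratic law-of-mass-action
    isotherm to estimate dissociation constants; quantifies relative
    expression by the delta-delta-Ct method and summarizes dose-response
    curves; and screens survival cohorts with Kaplan-Meier/log-rank
    statistics under Benjamini-Hochberg FDR control. Seeded synthetic
    generators emulate every input so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
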