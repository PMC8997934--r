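Package: editome
Title: RNA Editing Profiles as Sex-Dependent Prognostic Markers in Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing A-to-I RNA editing in tumour cohorts: loading
    and validating site-level editing matrices (editing level, edited-G reads,
    A+G coverage), filtering sites against sequencing error with an exact
    binomial test and selecting discriminative sites, stratifying patients by
    editing profile with UMAP embedding and HDBSCAN density clustering tuned
    by a survival (log-rank) objective, detecting differentially edited sites
    between risk groups with a variance/median-difference filter cascade and
    Mann-Whitney tests, comparing ranked gene lists by rank-rank hypergeometric
    overlap, inferring editing-regulated genes from editing-expression
    regression combined with ADAR1 knockdown response, screening sites for
    sex-specific prognostic value with age-adjusted Cox models, and
    transferring sex-specific random-forest subtype classifiers across
    cohorts. Includes a synthetic-cohort generator with planted cluster,
    survival, and regulatory structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    uwot,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
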