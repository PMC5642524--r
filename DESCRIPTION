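Package: gastrosubtype
Title: Molecular Subtyping and Mutation Profiling of Gastric Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for TCGA-style molecular classification of
    gastric cancer from targeted tumor/normal panel sequencing. Implements
    somatic and germline variant post-filtering with a panel of normals,
    microsatellite instability calling from mononucleotide marker allele
    profiles (BAT-25, BAT-26, NR-21, NR-24, NR-27), gene-level copy-number
    calling from coverage ratios with a three-state Gaussian hidden Markov
    model, serial EBV/MSI/CIN/GS subtype assignment, per-subtype mutation
    profiling with exact Fisher-Freeman-Halton association tests and exact
    binomial confidence intervals, Kaplan-Meier/log-rank/Cox survival
    analysis, and a seeded synthetic cohort generator that emulates the
    assay bundles the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
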