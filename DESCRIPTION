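Package: polyprofile
Title: Polygenic Profiling and Epistasis Search for Candidate-SNP Case-Control Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of small candidate-SNP panels:
    an additive Total Genotype Score (TGS) engine with configurable per-locus
    scoring schemes, APOE epsilon2/epsilon3/epsilon4 diplotype derivation from
    rs429358 and rs7412, Hardy-Weinberg quality control, chi-square effect-size
    power planning, odds ratios, ROC/AUC discrimination, a from-scratch
    multifactor dimensionality reduction (MDR) search for SNP-SNP epistasis
    with cross-validation consistency, and a seeded synthetic-cohort generator
    driven by published genotype frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), pROC, jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
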