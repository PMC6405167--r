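Package: hlascan
Title: Case-Control HLA Allele and Amino-Acid Epitope Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Case-control association analysis for HLA genotyping studies:
    per-allele carrier-frequency tests with automatic chi-square/Fisher
    selection and Benjamini-Hochberg false-discovery-rate correction, an
    exhaustive scan of 1-4 amino-acid motifs ("epitopes") over aligned
    allele protein sequences, two-one-sided-tests (TOST) equivalence
    testing of carrier proportions, imputation of DRB3/DRB4/DRB5 locus
    presence from DRB1 haplotype families, a subsampling detection-limit
    harness for small case cohorts, and a synthetic cohort generator with
    Hardy-Weinberg genotype sampling and configurable embedded motif
    effects so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
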