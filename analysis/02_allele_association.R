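#!/usr/bin/env Rscript
# Per-allele carrier association on the null study cohort: carrier 2x2
# tables, chi-square/Fisher selection, per-locus BH adjustment, odds ratios,
# and TOST equivalence at a 0.2 proportion-difference margin.  Mirrors the
# per-locus allele frequency tables of an HLA case-control study.

suppressPackageStartupMessages(library(hlascan))
dir.create("results", showWarnings = FALSE)

cohort <- read_genotypes("results/data/null_study_genotypes.csv")
res <- run_allele_association(cohort, tost_margin = 0.2)
utils::write.table(res, "results/allele_association.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Allele association on", n_cases(cohort), "cases /",
    n_controls(cohort), "controls:\n")
cat(" -", nrow(res), "alleles tested across",
    length(unique(res$locus)), "loci\n")
cat(" - minimum adjusted p:", signif(min(res$p_adjusted), 3),
    "(no allele-level association expected under the null)\n")
cat(" - maximum TOST equivalence p at margin 0.2:",
    signif(max(res$p_equiv), 3), "\n")
cat("Table written to results/allele_association.tsv\n")
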