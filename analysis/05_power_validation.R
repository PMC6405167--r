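#!/usr/bin/env Rscript
# Detection-limit experiment: can the motif scan recover a strong embedded
# single-residue association from as few as 20 cases?  Subsamples of
# 20/30/40/50 cases (10 replicates each) against 1000 controls, scanning
# the full motif family each time.

suppressPackageStartupMessages(library(hlascan))
dir.create("results", showWarnings = FALSE)

cases <- read_genotypes("results/data/effect_cases_genotypes.csv")
controls <- read_genotypes("results/data/control_pool_genotypes.csv")
catalog <- read_catalog("results/data/effect_cases_catalog.tsv")
meta <- read.table("results/data/embedded_motif.txt", row.names = 1)
m <- motif(meta["embedded_motif_locus", 1],
           as.integer(meta["embedded_motif_position", 1]),
           meta["embedded_motif_residue", 1])

design <- subsample_design(sample_sizes = c(20, 30, 40, 50), replicates = 10,
                           n_controls = 1000, seed = 1)
curve <- subsample_and_scan(cases, controls, catalog, design, true_motif = m)
rep <- detection_report(curve)

utils::write.table(curve$cells, "results/power_cells.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(rep, "results/power_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Detection-limit experiment (embedded OR = 8, carriers ~59% vs 15%):\n")
print(rep[, c("size", "detection_frequency", "detection_frequency_true",
              "median_neglog10_p_raw")])
cat("Per-replicate cells in results/power_cells.tsv\n")
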