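# hlascan

Case-control HLA association analysis for small cohorts: per-allele
carrier tests, an exhaustive amino-acid epitope scan, equivalence testing,
DRB3/4/5 linkage imputation, and a subsampling detection-limit harness —
with a synthetic cohort generator so the whole pipeline runs and is tested
without subject-level data.

## The problem and who this is for

Autoimmune diseases are usually HLA-linked, but testing for an HLA
association in a *rare* disease means working with 20–50 cases against a
reference panel of ~1000 typed controls. At that size, individually rare
alleles cannot reach significance, while a causal amino acid shared by
several alleles can. `hlascan` is for immunogenetics analysts who need,
from a table of two-field HLA genotypes:

* **Carrier association per allele.** A subject carries allele *X* if at
  least one of its two alleles at the locus is *X* (homozygotes count
  once). Each allele yields a 2×2 table (a, n₁−a; c, n₀−c); Cochran's
  rule picks Pearson chi-square (all expected cells ≥ 5) or Fisher's
  exact test; p-values are Benjamini–Hochberg adjusted per locus; the
  effect measure is the sample odds ratio ad/bc.
* **Epitope scan.** Every combination of 1–4 residues at polymorphic
  positions of the aligned allele proteins (positions 2–192 for class I,
  8–93 for class II) that is realised on an observed allele is tested as
  a carrier trait, so residue-level sharing across disparate alleles
  becomes detectable in small cohorts.
* **Equivalence (TOST).** For a negative study, two one-sided z-tests
  against a ±δ carrier-proportion margin turn "not significant" into
  "demonstrably equivalent at margin δ".
* **DRB3/4/5 presence.** Imputed from DRB1 haplotype families
  (DR52/DR53/DR51 groups) and tested as a carrier trait.
* **Detection limits.** Repeated case subsamples (20/30/40/50 × 10) with
  a known embedded effect measure how few cases the scan needs.

## Worked example

Simulate a cohort of 40 cases and 1000 controls over a six-allele DRB1
catalog, embedding a carrier effect (odds ratio 8) on the minority residue
asparagine at position 13, then analyse it:

```r
library(hlascan)

ct <- generate_catalog("DRB1", n_alleles = 6, seq_length = 80,
                       n_polymorphic = 3, seed = 101,
                       positions = c(13, 26, 37))
rownames(ct$DRB1) <- c("01:01", "03:01", "04:01", "07:01", "15:01", "16:01")
m <- motif("DRB1", 13, "N")                 # carried only by 01:01 here
fr <- c("01:01" = 0.0777, "03:01" = 0.1845, "04:01" = 0.1845,
        "07:01" = 0.1845, "15:01" = 0.1845, "16:01" = 0.1845)
co <- simulate_cohort(list(DRB1 = fr), ct, n_cases = 40, n_controls = 1000,
                      effect = list(motif = m, target_or = 8), seed = 2)

run_allele_association(co)
scan_locus(co, ct, "DRB1")
```

The allele table shows the carrier allele 01:01 at 25/40 cases vs
150/1000 controls:

```
  allele case_carriers control_carriers       test    p_raw p_adjusted odds_ratio
1  01:01            25              150 chi_square 3.43e-15   2.06e-14      9.444
2  03:01            13              318 chi_square 9.26e-01   9.26e-01      1.033
...
```

and the scan recovers the embedded residue as the top motif:

```
epitope scan: 28 motifs tested (k=1: 8, k=2: 14, k=3: 6, k=4: 0)
top motif: DRB1 13/N p_raw=3.43e-15 p_adj=2.4e-14
```

The estimated odds ratio 9.44 is the sample estimate of the embedded
target 8; the motif's adjusted p is the raw p scaled by its BH factor
within the 28-motif locus family. Ties at (13;26 N;P) and (13;37 N;W)
are motifs perfectly correlated with N13 on this catalog — expected, since
allele 01:01 alone carries all three.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # catalog + cohorts (+ embedded effect)
Rscript analysis/02_allele_association.R # per-allele carrier tables + TOST
Rscript analysis/03_epitope_scan.R       # exhaustive 1-4 residue motif scan
Rscript analysis/04_drb_linkage.R        # DRB3/4/5 presence (incl. published tables)
Rscript analysis/05_power_validation.R   # detection-limit experiment
```

## Documentation

The methods vignette (`vignettes/hla-epitope-association.Rmd`) describes
the carrier model, test selection, the motif-scan counting rules, the
TOST formulation, the linkage map, the synthetic-data generator and its
limits, and all numerical design choices.
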