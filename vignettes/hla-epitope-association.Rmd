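---
title: "Carrier-model HLA association and the amino-acid epitope scan"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlascan)
```

## The problem

Most autoimmune diseases show a genetic association to the HLA region:
particular class I or class II alleles — or, more sharply, particular amino
acids in the peptide-binding groove shared across several alleles — are
enriched in patients.  Testing for such an association in a rare disease is
statistically awkward: case cohorts of 20–50 subjects are common, the
allele spectrum at each locus is long-tailed, and a truly causal residue
may be spread across several individually rare alleles, none of which
reaches significance on its own.

`hlascan` implements the analysis pipeline for this setting:

1. **Per-allele carrier association** between cases and controls, with
   automatic chi-square/Fisher selection and false-discovery-rate
   correction.
2. An **exhaustive amino-acid motif ("epitope") scan** that tests every
   combination of 1–4 residues at polymorphic positions of the aligned
   allele proteins, so that residue-level sharing between disparate
   alleles becomes testable.
3. **TOST equivalence testing**, so that a negative finding can be
   reported as evidence of equivalence rather than mere absence of
   significance.
4. **DRB3/DRB4/DRB5 presence imputation** from DRB1 haplotype families.
5. A **subsampling detection-limit harness** that measures, on cohorts
   with a known embedded effect, how few cases suffice to recover it.
6. A **synthetic cohort generator** so every stage is testable without
   access to subject-level data.

## The carrier model

Every test in the pipeline is built on the same 2×2 table.  For an allele
(or motif) $X$ at locus $L$, a subject is a *carrier* when at least one of
its two alleles at $L$ is (or matches) $X$; homozygotes count once.  With
$a$ case carriers out of $n_1$ typed cases and $c$ control carriers out of
$n_0$ typed controls, the table is $(a, n_1 - a, c, n_0 - c)$ and the
association measure is the sample odds ratio $\mathrm{OR} = ad/bc$.

Denominators are **per locus**, not cohort-wide: subjects with a missing
genotype at $L$ drop out of both margins for that locus only.  This
reproduces the situation in real typing data where dropout differs by
locus.

### Test selection

The choice between the Pearson chi-square test and Fisher's exact test
follows Cochran's rule: if any expected cell count under the table margins
is below 5, the exact test is used.  Both branches are two-sided; the
chi-square branch is uncorrected Pearson by default (the Yates correction
is switchable via `correct = TRUE`), and the Fisher branch uses the
minimum-likelihood two-sided rule, i.e. it sums the probabilities of all
tables no more likely than the observed one, matching mainstream exact-test
implementations.  A caller can force either branch through
`test_rule = "chi_square"` or `"fisher"`.

### Multiple testing

Raw p-values are adjusted by the Benjamini–Hochberg step-up procedure.
The default family is **per locus** — each locus's alleles (or motifs, all
sizes $k = 1..4$ jointly) form one family, matching the per-locus layout
of conventional HLA report tables — and `fdr_scope = "global"` pools all
loci into a single family instead.  The family size is always reported
(`n_motifs_tested`), so every FDR denominator is auditable.

### Equivalence testing

A non-significant difference does not demonstrate similarity.  The TOST
(two one-sided tests) procedure reverses the burden of proof: for a margin
$\delta > 0$ the null hypothesis is that the carrier proportions differ by
more than $\delta$, and a *small* $p_{\mathrm{equiv}}$ supports
equivalence.  The implementation uses the normal approximation with
unpooled variance:

$$ z_\pm = \frac{(\hat p_1 - \hat p_0) \pm \delta}
   {\sqrt{\hat p_1(1-\hat p_1)/n_1 + \hat p_0(1-\hat p_0)/n_0}}, $$

with $p_{\mathrm{equiv}} = \max\{P(Z > z_+^{lower}), P(Z < z_-^{upper})\}$.
The margin has no natural default in the literature for this design; the
pipeline requires it explicitly and uses $\delta = 0.2$ (absolute carrier
proportion difference) when unstated.  Two properties anchor the
implementation and are enforced by the test suite: $p_{\mathrm{equiv}}$ is
non-increasing in $\delta$ on fixed data, and as $\delta \to 0^+$ it
cannot drop below $0.5$.

## The epitope scan

Alleles are represented by their aligned mature-protein sequences
(1-based IMGT-style numbering, per-locus `start_position`).  The scan
window is positions 2–192 for class I (A, B, C) and 8–93 for class II
(DRB1, DQB1, DPB1) — the peptide-binding domains.  Within the window:

* A position is **polymorphic** when ≥ 2 distinct known residues occur
  among the alleles *observed in the cohort* (not the whole catalog): the
  test family is data-determined.
* For every subset of 1–4 polymorphic positions, the **realised motifs**
  are the distinct residue tuples read off the observed alleles.  Abstract
  residue combinations never realised on an allele would have zero
  carriers and are not counted as tests; the counting unit is the realised
  (position-set, residue-tuple) pair.
* An unknown residue (`'*'`, or a position outside a truncated sequence)
  never matches a motif and never generates one — conservative, so no
  sequence is fabricated.

Each motif's carrier table is then tested exactly like an allele.  When an
allele is uniquely identified by its residue tuple, the motif test
coincides with the allele test — a consistency property the test suite
checks.

Carrier counting is aggregated over *distinct genotypes* (unordered allele
pairs) rather than subjects, so scan cost scales with the number of
distinct genotypes; with 1000 controls drawn from a handful of alleles
this is a large constant-factor saving, and the per-subject brute-force
oracle in the tests confirms identical results.

## DRB3/4/5 linkage imputation

The secondary DR loci exist only on some haplotypes and travel in tight
linkage with the DRB1 family (first name field): DR3/11/12/13/14
haplotypes carry DRB3 (DR52 group), DR4/7/9 carry DRB4 (DR53), DR15/16
carry DRB5 (DR51), and DR1/8/10 carry none.  `impute_secondary_drb()`
applies this family-level map to each subject's DRB1 pair; presence is
then tested as a carrier trait with an uncorrected chi-square (three raw
tests, no adjustment — the conventional presentation for this small,
pre-specified family).  Known haplotype-level exceptions (e.g. rare
DRB4-null haplotypes) are not modelled by default because they are
unobservable without genomic typing, but the map is overridable from a
two-column TSV.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth:

* `generate_catalog()` builds aligned sequences sharing a consensus and
  differing at a chosen number of positions, each carrying 2–3 residues —
  the minimal structure the scan needs.
* `sample_genotypes_hwe()` draws two independent alleles per subject from
  a frequency vector (Hardy–Weinberg), stored unordered.
* `sample_cases_with_effect()` injects a disease effect **at the carrier
  level**: given baseline carrier probability $q$ and target odds ratio
  $\psi$, cases are carriers with probability
  $q' = \psi q / (1 - q + \psi q)$, and a genotype is drawn conditional on
  carrier status by rejection from the HWE sampler.  The target OR is thus
  exactly the estimand of the downstream carrier test, which is what makes
  parameter-recovery checks sharp.

All generators are pure functions of their arguments and a seed.

What the generator does **not** emulate: linkage disequilibrium between
loci, population admixture, realistic long-tailed allele frequency
spectra (hundreds of rare alleles), typing ambiguity, or allele-specific
missingness.  A pipeline that passes its tests here is therefore verified
for *correctness of counting and testing*, not for robustness to every
property of real typing data.

## The detection-limit experiment

The harness asks: with a strong, known residue association, how few cases
does the scan need?  The default design draws case subsamples of 20, 30,
40 and 50 (10 replicates each, without replacement, subjects keyed by id)
against 1000 controls, scans the full motif family each time, and records
the family-minimum raw and adjusted p-values plus the embedded motif's own
rank and adjusted p.  Two detection criteria are reported side by side —
family-minimum adjusted $p < \alpha$, and the embedded motif itself
reaching adjusted $p < \alpha$ — since a "detection" claim can reasonably
mean either.

The packaged study conditions embed a single-residue effect of carrier
OR 8 with control-side carrier probability 0.15 (case-side ≈ 0.59), on a
compact two-locus catalog with three polymorphic positions per locus
(motif family of a few dozen tests).  The problem size keeps the analysis
focused on *sample-size* power rather than family-size correction; with
millions of motifs the same effect would need a correspondingly smaller
p to survive adjustment, so detection frequencies here are an upper bound
relative to very large catalogs.

Reproducibility: replicate $r$ at size index $s$ runs on an independent
substream seeded as $(\mathrm{seed}\cdot 131 + 17 s + r) \bmod (2^{31}-1)$,
so results are independent of loop order and stable under re-runs.

## Numerical and design choices

* **Two-field resolution** is the working resolution; higher-resolution
  calls are truncated at load.  All printed HLA report tables use
  two-field names.
* **Null-expression suffixes** (e.g. `N`) are parsed and preserved but
  treated as ordinary alleles — excluding them is a typing-interpretation
  decision left to the user.
* **Degenerate tables**: an all-zero table is an error; a zero-margin
  table yields Fisher $p = 1$ by convention and an error for the
  chi-square branch; odds ratios are flagged `Inf` ($bc = 0 < ad$) or
  `NaN` (both products zero).
* **TOST with degenerate proportions** (both $\hat p \in \{0, 1\}$):
  the zero standard error is replaced by machine epsilon rather than
  erroring, which makes $p_{\mathrm{equiv}}$ collapse to 0 or 1 according
  to the point difference.
* **FDR ties and ordering** follow the standard step-up definition; the
  test suite pins the implementation to a literal quadratic-time
  transcription of it.
* **Problem sizes in the checks**: calibration uses 1000 null cohorts of
  40 cases / 200 controls over two 4-allele loci (common alleles, so the
  chi-square branch is exercised at near-nominal type-I rates);
  parameter recovery uses 200 cases / 1000 controls over 20 seeds per
  target OR ∈ {2, 5, 8}.  These sizes make the binomial error bars small
  enough for 3-standard-error assertions while keeping the whole suite
  fast.

## Limitations

* The scan tests marginal carrier association per motif; it does not
  condition on a top hit, so a block of correlated positions yields a
  block of correlated tests (the per-locus FDR family handles the
  multiplicity, not the correlation structure).
* Imputed DRB3/4/5 presence is family-level and ignores rare exception
  haplotypes.
* The equivalence test is a normal-approximation TOST; exact TOST for
  very small cohorts is not implemented.
* Haplotype-level (multi-locus) motifs and covariate adjustment are out
  of scope.

## A worked micro-example

```{r example}
# four DRB1 alleles differing at positions 9, 13 and 57
base <- paste(rep("A", 60), collapse = "")
put <- function(s, pos, res) {
  v <- strsplit(s, "")[[1]]; v[pos] <- res; paste(v, collapse = "")
}
catalog <- hla_catalog(list(DRB1 = list(start = 1, seqs = c(
  "01:01" = put(put(base, 13, "H"), 57, "D"),
  "02:01" = put(put(base, 13, "R"), 57, "D"),
  "03:01" = put(put(put(base, 9, "W"), 13, "H"), 57, "S"),
  "04:01" = put(put(base, 13, "R"), 57, "S")))))

cohort <- simulate_cohort(
  list(DRB1 = c("01:01" = 0.4, "02:01" = 0.3, "03:01" = 0.2, "04:01" = 0.1)),
  catalog, n_cases = 30, n_controls = 200, seed = 1)

run_allele_association(cohort)[, c("allele", "case_freq", "control_freq",
                                   "test", "p_raw", "p_adjusted")]
scan_all(cohort, catalog)
```
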