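#' Count distinct alleles observed in a cohort
#'
#' Number of distinct (locus, allele) pairs seen in either group across the
#' listed loci.
#'
#' @param cohort An [hla_cohort()].
#' @param loci Loci to include; default: all typed loci.
#' @return Integer count.
#' @export
count_distinct_alleles <- function(cohort, loci = NULL) {
  stopifnot(inherits(cohort, "hla_cohort"))
  loci <- loci %||% cohort$loci
  sum(vapply(intersect(loci, cohort$loci), function(loc) {
    length(observed_alleles_at(cohort, loc))
  }, integer(1L)))
}

fmt_pct <- function(x) sprintf("%.1f", 100 * x)
fmt_p <- function(x) sprintf("%.2f", x)

# human-readable mirror of one per-locus allele table (counts, percentages
# to 1 dp, p-values to 2 dp); machine outputs keep full precision
format_allele_report <- function(res) {
  data.frame(
    allele = res$allele,
    patients = sprintf("%d (%s)", res$case_carriers, fmt_pct(res$case_freq)),
    controls = sprintf("%d (%s)", res$control_carriers, fmt_pct(res$control_freq)),
    p_value = fmt_p(res$p_raw), p_adjusted = fmt_p(res$p_adjusted),
    stringsAsFactors = FALSE)
}

#' Run the full association pipeline
#'
#' Reads the genotype table and allele catalog, then runs, in order: the
#' per-allele carrier association analysis (with TOST equivalence), the
#' exhaustive amino-acid motif scan, the DRB3/4/5 linkage-presence analysis
#' (when DRB1 is typed), and optionally the subsampling detection-limit
#' experiment.  Writes one allele report per locus (machine TSV plus a
#' human-readable mirror), the scan report, the linkage report, and a
#' machine-readable `summary.json`.
#'
#' @param genotypes Path to the genotype CSV (see [read_genotypes()]).
#' @param catalog Path to the catalog TSV (see [read_catalog()]).
#' @param out_dir Output directory (created if needed).
#' @param linkage_map Optional path to a linkage-map override TSV.
#' @param loci Loci to analyse; default: all typed loci present in the
#'   catalog (allele association runs on all typed loci regardless).
#' @param config A [scan_config()].
#' @param tost_margin Equivalence margin on the carrier-proportion
#'   difference (default 0.2).
#' @param design Optional [subsample_design()]; when supplied the
#'   detection-limit experiment runs on the cohort itself.
#' @param seed Master seed for the optional subsampling stage.
#' @return Invisibly, a list with elements `cohort`, `alleles`, `scan`,
#'   `linkage`, `power` (NULL unless `design` given) and `summary`.
#' @export
run_pipeline <- function(genotypes, catalog, out_dir,
                         linkage_map = NULL, loci = NULL,
                         config = scan_config(), tost_margin = 0.2,
                         design = NULL, seed = 1L) {
  for (f in c(genotypes, catalog, linkage_map)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_genotypes(genotypes)
  cat_obj <- read_catalog(catalog)
  map <- if (is.null(linkage_map)) default_linkage_map() else {
    read_linkage_map(linkage_map)
  }

  alleles <- run_allele_association(cohort, fdr_scope = config$fdr_scope,
                                    tost_margin = tost_margin)
  for (loc in unique(alleles$locus)) {
    d <- alleles[alleles$locus == loc, ]
    utils::write.table(d, file.path(out_dir, paste0("alleles_", loc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_allele_report(d),
                       file.path(out_dir, paste0("alleles_", loc, "_printed.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  scan_loci <- loci %||% intersect(cohort$loci, names(cat_obj))
  scan <- scan_all(cohort, cat_obj, loci = scan_loci, config = config)
  utils::write.table(scan$results, file.path(out_dir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  linkage <- NULL
  if ("DRB1" %in% cohort$loci) {
    linkage <- secondary_drb_association(cohort, map)
    utils::write.table(linkage, file.path(out_dir, "linkage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  power <- NULL
  if (!is.null(design)) {
    design$seed <- as.integer(seed)
    power <- subsample_and_scan(cohort, cohort, cat_obj, design,
                                config = config)
    utils::write.table(power$cells, file.path(out_dir, "power_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(detection_report(power),
                       file.path(out_dir, "power_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  min_adj <- stats::aggregate(p_adjusted ~ locus, alleles, min)
  summary <- list(
    n_cases = n_cases(cohort), n_controls = n_controls(cohort),
    loci = cohort$loci,
    n_distinct_alleles = count_distinct_alleles(cohort),
    n_motifs_tested = as.list(scan$n_motifs_tested),
    n_motifs_total = scan$n_motifs_total,
    min_adjusted_p_alleles = stats::setNames(
      as.list(min_adj$p_adjusted), min_adj$locus),
    min_adjusted_p_scan = if (nrow(scan$results) > 0L) {
      min(scan$results$p_adjusted)
    } else NA_real_)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, alleles = alleles, scan = scan,
                 linkage = linkage, power = power, summary = summary))
}
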