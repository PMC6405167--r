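#' Canonical DRB1-family to secondary-DR-locus linkage map
#'
#' DRB3 (DR52 group), DRB4 (DR53) and DRB5 (DR51) are secondary DR-beta loci
#' present only on some DR haplotypes, in tight linkage disequilibrium with
#' the DRB1 family (first allele field).  This map encodes the canonical
#' haplotype families: DR1/DR8/DR10 carry none, DR3/11/12/13/14 carry DRB3,
#' DR4/7/9 carry DRB4, DR15/16 carry DRB5.
#'
#' @return Named character vector: DRB1 family -> `"DRB3"`, `"DRB4"`,
#'   `"DRB5"` or `"none"`.
#' @export
default_linkage_map <- function() {
  c("01" = "none", "08" = "none", "10" = "none",
    "03" = "DRB3", "11" = "DRB3", "12" = "DRB3", "13" = "DRB3", "14" = "DRB3",
    "04" = "DRB4", "07" = "DRB4", "09" = "DRB4",
    "15" = "DRB5", "16" = "DRB5")
}

#' Read a linkage-map override
#'
#' TSV with columns `drb1_family` and `secondary_locus`; rows replace or
#' extend the [default_linkage_map()].
#'
#' @param path Path to the TSV file.
#' @return Named character vector as in [default_linkage_map()].
#' @export
read_linkage_map <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  if (!all(c("drb1_family", "secondary_locus") %in% names(raw))) {
    stop("linkage map needs columns drb1_family, secondary_locus", call. = FALSE)
  }
  ok <- raw$secondary_locus %in% c("DRB3", "DRB4", "DRB5", "none")
  if (!all(ok)) {
    stop("invalid secondary_locus: ",
         paste(unique(raw$secondary_locus[!ok]), collapse = ", "), call. = FALSE)
  }
  map <- default_linkage_map()
  map[raw$drb1_family] <- raw$secondary_locus
  map
}

drb1_family <- function(call) sub(":.*$", "", call)

#' Impute DRB3/DRB4/DRB5 locus presence from a DRB1 genotype
#'
#' A secondary locus is present when at least one of the two DRB1 alleles
#' belongs to a family mapped to it (a homozygous family counts once).
#'
#' @param drb1_pair Character vector of the two DRB1 calls (two-field, no
#'   locus prefix).
#' @param map Linkage map, see [default_linkage_map()].
#' @return Named logical vector over `c(DRB3, DRB4, DRB5)`.
#' @export
impute_secondary_drb <- function(drb1_pair, map = default_linkage_map()) {
  stopifnot(length(drb1_pair) == 2L, !any(is.na(drb1_pair)))
  fams <- drb1_family(drb1_pair)
  unknown <- setdiff(fams, names(map))
  if (length(unknown) > 0L) {
    stop("DRB1 family not in linkage map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hit <- map[fams]
  stats::setNames(c("DRB3", "DRB4", "DRB5") %in% hit, c("DRB3", "DRB4", "DRB5"))
}

#' Association of imputed secondary DR locus presence
#'
#' Imputes DRB3/4/5 presence for every subject typed at DRB1, builds the
#' carrier-style 2x2 presence table per secondary locus and reports the
#' uncorrected chi-square p-value and sample odds ratio.  No multiple-testing
#' adjustment is applied across the three loci (raw presentation).
#'
#' @param cohort An [hla_cohort()] typed at DRB1.
#' @param map Linkage map, see [default_linkage_map()].
#' @return Data frame with one row per secondary locus: carrier counts and
#'   totals, `case_freq`, `control_freq`, `p_chi` (NA when a margin is
#'   degenerate), `odds_ratio`.
#' @export
secondary_drb_association <- function(cohort, map = default_linkage_map()) {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (!"DRB1" %in% cohort$loci) stop("cohort not typed at DRB1", call. = FALSE)
  g <- cohort$genotypes
  a1 <- g$DRB1_1; a2 <- g$DRB1_2
  typed <- !is.na(a1)
  pres <- t(mapply(function(x, y) impute_secondary_drb(c(x, y), map),
                   a1[typed], a2[typed]))
  is_case <- g$group[typed] == "case"
  rows <- lapply(c("DRB3", "DRB4", "DRB5"), function(loc) {
    hit <- pres[, loc]
    t <- c(sum(hit & is_case), sum(!hit & is_case),
           sum(hit & !is_case), sum(!hit & !is_case))
    p <- tryCatch(chi_square_p(t), error = function(e) NA_real_)
    data.frame(locus = loc,
               case_carriers = t[[1L]], case_total = sum(is_case),
               control_carriers = t[[3L]], control_total = sum(!is_case),
               case_freq = t[[1L]] / sum(is_case),
               control_freq = t[[3L]] / sum(!is_case),
               p_chi = p, odds_ratio = odds_ratio(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
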