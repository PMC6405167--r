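#' Configuration of the amino-acid motif scan
#'
#' @param k_max Largest motif size (number of position/residue pairs per
#'   motif), default 4.  Values above 4 are allowed with a warning: the
#'   enumeration grows combinatorially.
#' @param class_i_range Inclusive mature-protein position window scanned for
#'   the class I loci (A, B, C); default `c(2, 192)`.
#' @param class_ii_range Window for the class II loci (DRB1, DQB1, DPB1);
#'   default `c(8, 93)`.
#' @param fdr_scope `"per_locus"` (default) or `"global"`: the family within
#'   which motif p-values are BH-adjusted.
#' @param min_carriers Optional pruning threshold: motifs with fewer total
#'   carriers (cases + controls) are dropped before testing, shrinking the
#'   FDR family.  Default 0 = test everything.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(k_max = 4L, class_i_range = c(2L, 192L),
                        class_ii_range = c(8L, 93L),
                        fdr_scope = c("per_locus", "global"),
                        min_carriers = 0L) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(k_max >= 1L, length(class_i_range) == 2L,
            length(class_ii_range) == 2L, min_carriers >= 0L)
  if (k_max > 4L) {
    warning("k_max > 4: motif enumeration grows combinatorially", call. = FALSE)
  }
  structure(list(k_max = as.integer(k_max),
                 class_i_range = as.integer(class_i_range),
                 class_ii_range = as.integer(class_ii_range),
                 fdr_scope = fdr_scope,
                 min_carriers = as.integer(min_carriers)),
            class = "scan_config")
}

scan_range_for <- function(config, locus) {
  if (locus %in% CLASS_I_LOCI) config$class_i_range else config$class_ii_range
}

#' An amino-acid motif
#'
#' A motif ("epitope") is a set of 1-4 (position, residue) pairs on one
#' locus's aligned mature protein; a subject carries it when at least one of
#' its two alleles matches every pair.
#'
#' @param locus Locus symbol.
#' @param positions Strictly increasing integer positions.
#' @param residues One-letter residues, one per position.
#' @return List of class `hla_motif`.
#' @export
motif <- function(locus, positions, residues) {
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(residues), length(positions) >= 1L,
            all(diff(positions) > 0))
  if (!all(residues %in% setdiff(CATALOG_ALPHABET, c("-", "*")))) {
    stop("motif residues must be amino-acid letters", call. = FALSE)
  }
  structure(list(locus = locus, positions = positions,
                 residues = as.character(residues)), class = "hla_motif")
}

#' @export
print.hla_motif <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$locus,
              paste0(x$residues, x$positions, collapse = " ")))
  invisible(x)
}

observed_alleles_at <- function(cohort, locus) {
  g <- cohort$genotypes
  a1 <- g[[paste0(locus, "_1")]]
  a2 <- g[[paste0(locus, "_2")]]
  sort(unique(stats::na.omit(c(a1, a2))))
}

# residue matrix restricted to the observed alleles, erroring on alleles
# absent from the catalog
catalog_matrix <- function(catalog, locus, observed_alleles) {
  if (!locus %in% names(catalog)) {
    stop("locus ", locus, " absent from catalog", call. = FALSE)
  }
  mat <- catalog[[locus]]
  missing <- setdiff(observed_alleles, rownames(mat))
  if (length(missing) > 0L) {
    stop("allele(s) observed in cohort but absent from catalog at ", locus,
         ": ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mat[observed_alleles, , drop = FALSE]
}

#' Polymorphic positions of a locus among observed alleles
#'
#' A position is polymorphic when at least two distinct *known* residues
#' (i.e. not `'*'`) occur among the observed alleles.  Positions where some
#' observed allele is unknown remain eligible; the unknown residue itself
#' never becomes a motif residue.
#'
#' @param catalog An [hla_catalog()].
#' @param locus Locus symbol.
#' @param range Inclusive position window `c(lo, hi)`; intersected with the
#'   catalog's aligned frame.
#' @param observed_alleles Allele names restricting the comparison (normally
#'   the alleles seen in the cohort).
#' @return Sorted integer vector of polymorphic positions.
#' @export
polymorphic_positions <- function(catalog, locus, range, observed_alleles) {
  mat <- catalog_matrix(catalog, locus, observed_alleles)
  pos <- as.integer(colnames(mat))
  keep <- pos >= range[[1L]] & pos <= range[[2L]]
  mat <- mat[, keep, drop = FALSE]
  pos <- pos[keep]
  n_known <- apply(mat, 2L, function(col) length(unique(col[col != "*"])))
  sort(pos[n_known >= 2L])
}

#' Motifs realised by observed alleles at a position set
#'
#' Reads the residue tuple of every observed allele at the given positions
#' and returns the distinct tuples; tuples containing an unknown residue are
#' excluded.  Every returned motif is therefore carried by at least one
#' allele.
#'
#' @inheritParams polymorphic_positions
#' @param positions Integer positions (strictly increasing).
#' @return List of [motif()] objects.
#' @export
realized_motifs <- function(catalog, locus, positions, observed_alleles) {
  mat <- catalog_matrix(catalog, locus, observed_alleles)
  sub <- mat[, as.character(positions), drop = FALSE]
  tuples <- apply(sub, 1L, paste, collapse = "")
  tuples <- unique(tuples[!grepl("*", tuples, fixed = TRUE)])
  lapply(tuples, function(tp) {
    motif(locus, positions, strsplit(tp, "")[[1L]])
  })
}

#' Carrier 2x2 table of a motif
#'
#' A subject carries the motif when at least one of its two alleles at the
#' locus has the motif's residue at every motif position; an allele with an
#' unknown residue at any needed position does not match.  Denominators are
#' the per-group counts of subjects typed at the locus.
#'
#' @param cohort An [hla_cohort()].
#' @param catalog An [hla_catalog()] covering the cohort's alleles.
#' @param m A [motif()].
#' @return `c(a, b, c, d)` as in [two_by_two()].
#' @export
motif_carriers <- function(cohort, catalog, m) {
  stopifnot(inherits(m, "hla_motif"))
  obs <- observed_alleles_at(cohort, m$locus)
  mat <- catalog_matrix(catalog, m$locus, obs)
  sub <- mat[, as.character(m$positions), drop = FALSE]
  match_allele <- apply(sub, 1L, function(r) all(r == m$residues))
  g <- cohort$genotypes
  a1 <- g[[paste0(m$locus, "_1")]]
  a2 <- g[[paste0(m$locus, "_2")]]
  typed <- !is.na(a1)
  hit <- match_allele[a1[typed]] | match_allele[a2[typed]]
  is_case <- g$group[typed] == "case"
  two_by_two(sum(hit & is_case), sum(!hit & is_case),
             sum(hit & !is_case), sum(!hit & !is_case))
}

# Genotype aggregation: distinct unordered allele-index pairs with per-group
# multiplicities.  Carrier counting then scales with distinct genotypes, not
# subjects.
aggregate_genotypes <- function(cohort, locus, allele_names) {
  g <- cohort$genotypes
  a1 <- g[[paste0(locus, "_1")]]
  a2 <- g[[paste0(locus, "_2")]]
  typed <- !is.na(a1)
  i1 <- match(a1[typed], allele_names)
  i2 <- match(a2[typed], allele_names)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  key <- paste(lo, hi)
  is_case <- g$group[typed] == "case"
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  n_case <- tabulate(idx[is_case], nbins = sum(uk))
  n_ctrl <- tabulate(idx[!is_case], nbins = sum(uk))
  list(i1 = lo[uk], i2 = hi[uk], n_case = n_case, n_ctrl = n_ctrl,
       case_total = sum(is_case), control_total = sum(!is_case))
}

#' Exhaustive motif scan of one locus
#'
#' Enumerates every subset of 1..`k_max` polymorphic positions within the
#' locus's scan window, every residue tuple realised on an observed allele
#' at that subset, counts motif carriers, tests each resulting 2x2 table
#' (chi-square/Fisher via [select_test()]), and BH-adjusts over the whole
#' per-locus motif family (all sizes jointly) unless `scan_all()` later
#' re-adjusts globally.
#'
#' @inheritParams motif_carriers
#' @param locus Locus symbol.
#' @param config A [scan_config()].
#' @param test_rule Passed to [select_test()].
#' @return List of class `epitope_scan`: `results` (data frame with columns
#'   `locus`, `k`, `positions`, `residues` (semicolon-joined), `a`,`b`,`c`,`d`,
#'   `test`, `p_raw`, `p_adjusted`, `odds_ratio`), `n_positions_polymorphic`,
#'   `n_motifs_tested` (named by k) and `n_motifs_total`.
#' @export
scan_locus <- function(cohort, catalog, locus, config = scan_config(),
                       test_rule = "auto") {
  stopifnot(inherits(cohort, "hla_cohort"), inherits(config, "scan_config"))
  obs <- observed_alleles_at(cohort, locus)
  if (length(obs) == 0L) stop("locus ", locus, " not typed in cohort", call. = FALSE)
  mat <- catalog_matrix(catalog, locus, obs)
  range <- scan_range_for(config, locus)
  poly <- polymorphic_positions(catalog, locus, range, obs)
  geno <- aggregate_genotypes(cohort, locus, rownames(mat))

  res_list <- list()
  n_by_k <- integer(config$k_max)
  if (length(poly) > 0L) {
    for (k in seq_len(min(config$k_max, length(poly)))) {
      subsets <- utils::combn(poly, k, simplify = FALSE)
      for (ps in subsets) {
        sub <- mat[, as.character(ps), drop = FALSE]
        tuples <- apply(sub, 1L, paste, collapse = "\x01")
        known <- !vapply(strsplit(tuples, "\x01", fixed = TRUE),
                         function(x) any(x == "*"), logical(1L))
        levs <- unique(tuples[known])
        if (length(levs) == 0L) next
        # alleles x motifs match matrix; '*' alleles match nothing
        match_mat <- outer(tuples, levs, "==") & known
        carrier <- match_mat[geno$i1, , drop = FALSE] |
          match_mat[geno$i2, , drop = FALSE]
        a <- as.integer(colSums(carrier * geno$n_case))
        cc <- as.integer(colSums(carrier * geno$n_ctrl))
        keep <- (a + cc) >= config$min_carriers
        if (!any(keep)) next
        n_by_k[k] <- n_by_k[k] + sum(keep)
        res_list[[length(res_list) + 1L]] <- data.frame(
          locus = locus, k = k,
          positions = paste(ps, collapse = ";"),
          residues = vapply(strsplit(levs[keep], "\x01", fixed = TRUE),
                            paste, character(1L), collapse = ";"),
          a = a[keep], b = geno$case_total - a[keep],
          c = cc[keep], d = geno$control_total - cc[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res_list) == 0L) {
    results <- data.frame(locus = character(), k = integer(),
                          positions = character(), residues = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), test = character(),
                          p_raw = numeric(), p_adjusted = numeric(),
                          odds_ratio = numeric(), stringsAsFactors = FALSE)
  } else {
    results <- do.call(rbind, res_list)
    tabs <- lapply(seq_len(nrow(results)), function(i) {
      c(results$a[i], results$b[i], results$c[i], results$d[i])
    })
    results$test <- vapply(tabs, select_test, character(1L), rule = test_rule)
    results$p_raw <- mapply(function(t, tst) {
      if (tst == "chi_square") chi_square_p(t) else fisher_exact_p(t)
    }, tabs, results$test)
    results$p_adjusted <- bh_adjust(results$p_raw)
    results$odds_ratio <- vapply(tabs, odds_ratio, numeric(1L))
    rownames(results) <- NULL
  }
  structure(list(results = results,
                 n_positions_polymorphic = stats::setNames(length(poly), locus),
                 n_motifs_tested = stats::setNames(n_by_k, seq_along(n_by_k)),
                 n_motifs_total = sum(n_by_k)),
            class = "epitope_scan")
}

#' Motif scan across loci
#'
#' Runs [scan_locus()] on each requested locus and combines the results.
#' With `fdr_scope = "global"` the BH adjustment is recomputed over the
#' pooled motif family; with `"per_locus"` (default) each locus keeps its own
#' family, matching per-locus reporting.
#'
#' @inheritParams scan_locus
#' @param loci Loci to scan; default: loci both typed in the cohort and
#'   present in the catalog.
#' @return An `epitope_scan` list as in [scan_locus()], with per-locus
#'   polymorphic-position counts and a per-(locus-summed) `n_motifs_tested`.
#' @export
scan_all <- function(cohort, catalog, loci = NULL, config = scan_config(),
                     test_rule = "auto") {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (nrow(cohort$genotypes) == 0L) stop("empty cohort", call. = FALSE)
  loci <- loci %||% intersect(cohort$loci, names(catalog))
  if (length(loci) == 0L) stop("no loci shared by cohort and catalog", call. = FALSE)
  scans <- lapply(loci, function(loc) {
    scan_locus(cohort, catalog, loc, config = config, test_rule = test_rule)
  })
  results <- do.call(rbind, lapply(scans, `[[`, "results"))
  rownames(results) <- NULL
  if (config$fdr_scope == "global" && nrow(results) > 0L) {
    results$p_adjusted <- bh_adjust(results$p_raw)
  }
  n_by_k <- Reduce(`+`, lapply(scans, `[[`, "n_motifs_tested"))
  structure(list(results = results,
                 n_positions_polymorphic =
                   do.call(c, lapply(scans, `[[`, "n_positions_polymorphic")),
                 n_motifs_tested = n_by_k,
                 n_motifs_total = sum(n_by_k)),
            class = "epitope_scan")
}

#' @export
print.epitope_scan <- function(x, ...) {
  cat(sprintf("epitope scan: %d motifs tested (%s)\n", x$n_motifs_total,
              paste(sprintf("k=%s: %d", names(x$n_motifs_tested),
                            x$n_motifs_tested), collapse = ", ")))
  if (nrow(x$results) > 0L) {
    top <- x$results[order(x$results$p_raw), ][1L, ]
    cat(sprintf("top motif: %s %s/%s p_raw=%.3g p_adj=%.3g\n", top$locus,
                top$positions, top$residues, top$p_raw, top$p_adjusted))
  }
  invisible(x)
}
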