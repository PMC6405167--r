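#' Carrier contingency table
#'
#' Builds the 2x2 table underlying every carrier test: `a` case carriers,
#' `b` case non-carriers, `c` control carriers, `d` control non-carriers.
#'
#' @param a,b,c,d Nonnegative counts.
#' @return Named numeric vector of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  t <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(t)) || any(t < 0) || any(t != floor(t))) {
    stop("two_by_two cells must be nonnegative integers", call. = FALSE)
  }
  structure(as.numeric(t), names = names(t), class = "two_by_two")
}

as_2x2_matrix <- function(t) {
  matrix(as.numeric(t), nrow = 2L, byrow = TRUE,
         dimnames = list(c("case", "control"), c("carrier", "non_carrier")))
}

check_2x2 <- function(t) {
  if (length(t) != 4L || any(is.na(t)) || any(t < 0)) {
    stop("expected a valid 2x2 table (a, b, c, d)", call. = FALSE)
  }
  as.numeric(t)
}

#' Choose chi-square or Fisher's exact test for a 2x2 table
#'
#' Cochran's rule: Fisher's exact test whenever any expected cell count under
#' the table margins is below 5, otherwise the Pearson chi-square test.
#'
#' @param t 2x2 table as `c(a, b, c, d)` (see [two_by_two()]).
#' @param rule `"auto"` (Cochran), or force `"chi_square"` / `"fisher"`.
#' @return `"chi_square"` or `"fisher"`.
#' @export
select_test <- function(t, rule = c("auto", "chi_square", "fisher")) {
  rule <- match.arg(rule)
  t <- check_2x2(t)
  if (sum(t) == 0) stop("degenerate table: all cells zero", call. = FALSE)
  if (rule != "auto") return(rule)
  m <- as_2x2_matrix(t)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) "fisher" else "chi_square"
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' One degree of freedom, two-sided, without Yates continuity correction by
#' default (the correction is switchable).
#'
#' @inheritParams select_test
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return Two-sided p-value.
#' @export
chi_square_p <- function(t, correct = FALSE) {
  t <- check_2x2(t)
  m <- as_2x2_matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square undefined: zero margin", call. = FALSE)
  }
  suppressWarnings(stats::chisq.test(m, correct = correct)$p.value)
}

#' Fisher's exact two-sided p-value for a 2x2 table
#'
#' Conditional on the margins; the two-sided p sums the probabilities of all
#' tables no more likely than the observed one (minimum-likelihood rule).
#' A table with a zero margin carries no information and returns 1.
#'
#' @inheritParams select_test
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(t) {
  t <- check_2x2(t)
  m <- as_2x2_matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`.  Returns `Inf` when `b*c == 0` with `a*d > 0`, and `NaN`
#' (undefined) when both products are zero.
#'
#' @inheritParams select_test
#' @return Numeric odds ratio (possibly `Inf` or `NaN`).
#' @export
odds_ratio <- function(t) {
  t <- check_2x2(t)
  num <- t[[1L]] * t[[4L]]
  den <- t[[2L]] * t[[3L]]
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' TOST equivalence test for two carrier proportions
#'
#' Two one-sided z-tests of the case-minus-control carrier proportion
#' difference against the margins -delta and +delta, using the normal
#' approximation with unpooled variance.  The reported `p_equiv` is the
#' larger of the two one-sided p-values; a small `p_equiv` rejects the null
#' of a difference larger than `delta` in absolute value, i.e. supports
#' equivalence.
#'
#' @inheritParams select_test
#' @param delta Equivalence margin: half-width of the allowed absolute
#'   proportion difference (must be > 0).  There is no natural default; the
#'   pipeline uses 0.2 unless told otherwise.
#' @return List with `estimate` (proportion difference), `margin`, `se`, and
#'   `p_equiv`.
#' @export
tost_equivalence <- function(t, delta) {
  t <- check_2x2(t)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0) {
    stop("equivalence margin delta must be a positive number", call. = FALSE)
  }
  n1 <- t[[1L]] + t[[2L]]
  n0 <- t[[3L]] + t[[4L]]
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty", call. = FALSE)
  p1 <- t[[1L]] / n1
  p0 <- t[[3L]] / n0
  diff <- p1 - p0
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  se <- max(se, .Machine$double.eps)  # degenerate all-0/all-1 proportions
  p_lower <- stats::pnorm((diff + delta) / se, lower.tail = FALSE)
  p_upper <- stats::pnorm((diff - delta) / se, lower.tail = TRUE)
  list(estimate = diff, margin = delta, se = se,
       p_equiv = max(p_lower, p_upper))
}

#' Per-allele carrier association analysis
#'
#' For every allele observed at the requested loci, builds the carrier 2x2
#' table, picks the test ([select_test()]), computes the two-sided p-value
#' and sample odds ratio, and adjusts p-values by Benjamini-Hochberg within
#' the configured family (per locus by default, mirroring per-locus report
#' tables; or globally across all loci).
#'
#' @param cohort An [hla_cohort()] with both cases and controls.
#' @param loci Loci to analyse; default: all loci typed in the cohort.
#' @param test_rule `"auto"` (Cochran's rule), `"chi_square"`, or `"fisher"`.
#' @param correct Yates correction for the chi-square branch (default `FALSE`).
#' @param fdr_scope `"per_locus"` or `"global"`.
#' @param tost_margin Optional equivalence margin; when supplied, a TOST
#'   equivalence p-value column `p_equiv` is added (see [tost_equivalence()]).
#' @return Data frame with one row per (locus, allele): carrier counts and
#'   totals, carrier frequencies, `test`, `p_raw`, `p_adjusted`,
#'   `odds_ratio`, and optionally `p_equiv`; sorted by locus then allele.
#' @export
run_allele_association <- function(cohort, loci = NULL,
                                   test_rule = c("auto", "chi_square", "fisher"),
                                   correct = FALSE,
                                   fdr_scope = c("per_locus", "global"),
                                   tost_margin = NULL) {
  stopifnot(inherits(cohort, "hla_cohort"))
  test_rule <- match.arg(test_rule)
  fdr_scope <- match.arg(fdr_scope)
  if (n_cases(cohort) == 0L || n_controls(cohort) == 0L) {
    stop("both groups required: cohort must contain cases and controls",
         call. = FALSE)
  }
  loci <- loci %||% cohort$loci
  missing_loci <- setdiff(loci, cohort$loci)
  if (length(missing_loci) > 0L) {
    stop("locus not typed in cohort: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  }
  per_locus <- lapply(loci, function(loc) {
    cc <- carrier_counts(cohort, loc)
    if (nrow(cc) == 0L) return(NULL)
    tabs <- lapply(seq_len(nrow(cc)), function(i) {
      c(cc$case_carriers[i], cc$case_total[i] - cc$case_carriers[i],
        cc$control_carriers[i], cc$control_total[i] - cc$control_carriers[i])
    })
    test <- vapply(tabs, select_test, character(1L), rule = test_rule)
    p_raw <- mapply(function(t, tst) {
      if (tst == "chi_square") chi_square_p(t, correct = correct)
      else fisher_exact_p(t)
    }, tabs, test)
    res <- cbind(cc, data.frame(
      case_freq = cc$case_carriers / cc$case_total,
      control_freq = cc$control_carriers / cc$control_total,
      test = test, p_raw = as.numeric(p_raw),
      odds_ratio = vapply(tabs, odds_ratio, numeric(1L)),
      stringsAsFactors = FALSE))
    if (!is.null(tost_margin)) {
      res$p_equiv <- vapply(tabs, function(t) {
        tost_equivalence(t, tost_margin)$p_equiv
      }, numeric(1L))
    }
    res
  })
  res <- do.call(rbind, per_locus)
  if (is.null(res) || nrow(res) == 0L) {
    stop("no typed loci among: ", paste(loci, collapse = ", "), call. = FALSE)
  }
  if (fdr_scope == "per_locus") {
    res$p_adjusted <- stats::ave(res$p_raw, res$locus, FUN = bh_adjust)
  } else {
    res$p_adjusted <- bh_adjust(res$p_raw)
  }
  res <- res[order(match(res$locus, HLA_LOCI), res$allele), ]
  rownames(res) <- NULL
  # stable column order
  cols <- c("locus", "allele", "case_carriers", "case_total",
            "control_carriers", "control_total", "case_freq", "control_freq",
            "test", "p_raw", "p_adjusted", "odds_ratio")
  if ("p_equiv" %in% names(res)) cols <- c(cols, "p_equiv")
  res[, cols]
}
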