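# Synthetic cohorts and catalogs.  All generators are pure functions of
# (arguments, seed): randomness runs inside withr::with_seed and leaves the
# caller's RNG untouched.

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate a synthetic aligned allele catalog for one locus
#'
#' Builds `n_alleles` aligned sequences sharing a random consensus and
#' differing only at `n_polymorphic` positions; each polymorphic position
#' carries 2-3 distinct residues, and every variant residue is realised by
#' at least one allele.
#'
#' @param locus Locus symbol.
#' @param n_alleles Number of alleles (>= 2 when `n_polymorphic` > 0).
#' @param seq_length Aligned sequence length.
#' @param n_polymorphic Number of polymorphic positions (<= `seq_length`).
#' @param seed Integer seed; the catalog is a pure function of the arguments.
#' @param positions Optional explicit polymorphic positions (1-based within
#'   the aligned frame); default: sampled uniformly.
#' @param start_position First aligned position (mature-protein numbering).
#' @return An [hla_catalog()] with this single locus; allele names are
#'   `"01:01"`, `"02:01"`, ...
#' @export
generate_catalog <- function(locus, n_alleles, seq_length, n_polymorphic,
                             seed = NULL, positions = NULL,
                             start_position = 1L) {
  stopifnot(n_polymorphic <= seq_length, n_alleles >= 1L)
  if (n_polymorphic > 0L && n_alleles < 2L) {
    stop("need >= 2 alleles to realise polymorphism", call. = FALSE)
  }
  aa <- setdiff(CATALOG_ALPHABET, c("-", "*"))
  with_opt_seed(seed, {
    cons <- sample(aa, seq_length, replace = TRUE)
    if (is.null(positions)) {
      positions <- sort(sample.int(seq_length, n_polymorphic))
    } else {
      positions <- sort(as.integer(positions))
      stopifnot(length(positions) == n_polymorphic,
                all(positions >= 1L), all(positions <= seq_length))
    }
    mat <- matrix(rep(cons, each = n_alleles), nrow = n_alleles)
    for (p in positions) {
      n_res <- min(sample(2:3, 1L), n_alleles)
      res <- sample(aa, n_res)
      assign_res <- c(res, sample(res, n_alleles - n_res, replace = TRUE))
      mat[, p] <- sample(assign_res)  # every residue realised at least once
    }
    names_ <- sprintf("%02d:01", seq_len(n_alleles))
    seqs <- stats::setNames(apply(mat, 1L, paste, collapse = ""), names_)
    hla_catalog(stats::setNames(
      list(list(start = start_position, seqs = seqs)), locus))
  })
}

#' Merge single-locus catalogs
#'
#' @param ... `hla_catalog` objects with disjoint loci.
#' @return Combined `hla_catalog`.
#' @export
catalog_bind <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1L), "hla_catalog")))
  loci <- unlist(lapply(parts, names))
  if (anyDuplicated(loci)) stop("duplicate loci across catalogs", call. = FALSE)
  structure(stats::setNames(do.call(c, lapply(parts, unclass)), loci),
            class = "hla_catalog")
}

check_freqs <- function(freqs) {
  if (is.null(names(freqs)) || any(names(freqs) == "")) {
    stop("allele frequencies must be a named vector", call. = FALSE)
  }
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must be nonnegative and sum to 1", call. = FALSE)
  }
  freqs
}

#' Sample unordered genotypes under Hardy-Weinberg equilibrium
#'
#' Each subject's two alleles are independent draws from the population
#' frequency vector; the pair is stored unordered (sorted).
#'
#' @param freqs Named numeric vector of allele frequencies (sums to 1).
#' @param n Number of subjects.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Data frame with character columns `a1`, `a2`.
#' @export
sample_genotypes_hwe <- function(freqs, n, seed = NULL) {
  freqs <- check_freqs(freqs)
  with_opt_seed(seed, {
    al <- names(freqs)
    a1 <- sample(al, n, replace = TRUE, prob = freqs)
    a2 <- sample(al, n, replace = TRUE, prob = freqs)
    data.frame(a1 = pmin(a1, a2), a2 = pmax(a1, a2), stringsAsFactors = FALSE)
  })
}

# carrier probability of an allele subset under HWE
hwe_carrier_prob <- function(freqs, matching) {
  p <- sum(freqs[matching])
  1 - (1 - p)^2
}

motif_matching_alleles <- function(catalog, m) {
  mat <- catalog[[m$locus]]
  if (is.null(mat)) stop("locus ", m$locus, " absent from catalog", call. = FALSE)
  sub <- mat[, as.character(m$positions), drop = FALSE]
  rownames(mat)[apply(sub, 1L, function(r) all(r == m$residues))]
}

#' Sample case genotypes with an embedded motif effect
#'
#' Disease effects are injected at the carrier level: with baseline motif
#' carrier probability `q` under Hardy-Weinberg, cases carry the motif with
#' probability `q' = OR*q / (1 - q + OR*q)`, so the target odds ratio is
#' exactly the estimand of the downstream carrier test.  Carrier status is
#' drawn first; the genotype is then drawn from the HWE sampler by rejection
#' conditional on carrier status.
#'
#' @inheritParams sample_genotypes_hwe
#' @param catalog An [hla_catalog()] used to resolve which alleles carry the
#'   motif.
#' @param effect List with elements `motif` (a [motif()]) and `target_or`
#'   (carrier odds ratio > 0).
#' @return Data frame with columns `a1`, `a2`.
#' @export
sample_cases_with_effect <- function(freqs, catalog, effect, n, seed = NULL) {
  freqs <- check_freqs(freqs)
  stopifnot(is.list(effect), inherits(effect$motif, "hla_motif"),
            effect$target_or > 0)
  matching <- motif_matching_alleles(catalog, effect$motif)
  q <- hwe_carrier_prob(freqs, names(freqs) %in% matching)
  if (q <= 0 || q >= 1) {
    stop("effect unidentifiable: baseline carrier probability is ", q,
         call. = FALSE)
  }
  or <- effect$target_or
  q_case <- (or * q) / (1 - q + or * q)
  with_opt_seed(seed, {
    is_carrier <- stats::runif(n) < q_case
    al <- names(freqs)
    out1 <- character(n); out2 <- character(n)
    todo <- seq_len(n)
    while (length(todo) > 0L) {
      # oversample; rejection by carrier status
      m_draw <- max(64L, ceiling(2.5 * length(todo) / min(q, 1 - q)))
      b1 <- sample(al, m_draw, replace = TRUE, prob = freqs)
      b2 <- sample(al, m_draw, replace = TRUE, prob = freqs)
      carr <- (b1 %in% matching) | (b2 %in% matching)
      for (want in c(TRUE, FALSE)) {
        need <- todo[is_carrier[todo] == want]
        pool <- which(carr == want)
        take <- seq_len(min(length(need), length(pool)))
        if (length(take) > 0L) {
          out1[need[take]] <- b1[pool[take]]
          out2[need[take]] <- b2[pool[take]]
          todo <- setdiff(todo, need[take])
        }
      }
    }
    data.frame(a1 = pmin(out1, out2), a2 = pmax(out1, out2),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete case-control cohort
#'
#' Controls are sampled under Hardy-Weinberg at every locus; cases likewise,
#' except at the locus of an optional embedded motif effect, where
#' [sample_cases_with_effect()] is used.  Per-locus missingness blanks a
#' subject's pair with the given probability.
#'
#' @param freq_spec Named list: locus -> named allele frequency vector.
#' @param catalog An [hla_catalog()] (needed when `effect` is given).
#' @param n_cases,n_controls Group sizes (>= 1).
#' @param effect Optional effect list as in [sample_cases_with_effect()].
#' @param missingness Per-locus probability of a missing genotype, in
#'   \[0, 1); default 0.
#' @param seed Integer seed.
#' @return An [hla_cohort()]; subject ids `case_0001`, ..., `ctrl_0001`, ...
#' @export
simulate_cohort <- function(freq_spec, catalog = NULL, n_cases, n_controls,
                            effect = NULL, missingness = 0, seed = NULL) {
  stopifnot(n_cases >= 1L, n_controls >= 1L,
            missingness >= 0, missingness < 1)
  loci <- names(freq_spec)
  stopifnot(all(loci %in% HLA_LOCI))
  with_opt_seed(seed, {
    g <- data.frame(
      subject_id = c(sprintf("case_%04d", seq_len(n_cases)),
                     sprintf("ctrl_%04d", seq_len(n_controls))),
      group = rep(c("case", "control"), c(n_cases, n_controls)),
      stringsAsFactors = FALSE)
    for (loc in loci) {
      fr <- check_freqs(freq_spec[[loc]])
      if (!is.null(effect) && effect$motif$locus == loc) {
        cas <- sample_cases_with_effect(fr, catalog, effect, n_cases)
      } else {
        cas <- sample_genotypes_hwe(fr, n_cases)
      }
      ctl <- sample_genotypes_hwe(fr, n_controls)
      a1 <- c(cas$a1, ctl$a1); a2 <- c(cas$a2, ctl$a2)
      if (missingness > 0) {
        drop <- stats::runif(length(a1)) < missingness
        a1[drop] <- NA_character_; a2[drop] <- NA_character_
      }
      g[[paste0(loc, "_1")]] <- a1
      g[[paste0(loc, "_2")]] <- a2
    }
    hla_cohort(g)
  })
}

#' Write a cohort + catalog fixture pair
#'
#' Emits `<root>_genotypes.csv` and `<root>_catalog.tsv` in the package's
#' file dialects; the files round-trip exactly through [read_genotypes()]
#' and [read_catalog()].
#'
#' @param cohort An [hla_cohort()] (non-empty).
#' @param catalog An [hla_catalog()].
#' @param root Path prefix for the two files.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_fixture <- function(cohort, catalog, root) {
  stopifnot(inherits(cohort, "hla_cohort"), inherits(catalog, "hla_catalog"))
  if (nrow(cohort$genotypes) == 0L) stop("empty cohort", call. = FALSE)
  paths <- c(genotypes = paste0(root, "_genotypes.csv"),
             catalog = paste0(root, "_catalog.tsv"))
  write_genotypes(cohort, paths[["genotypes"]])
  write_catalog(catalog, paths[["catalog"]])
  invisible(paths)
}
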