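# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive (per-subject / per-column loops, literal definitions)
# and share no code with the implementation paths they check.

# two-sided Fisher p by explicit enumeration of the hypergeometric support,
# using the standard minimum-likelihood rule with the customary relative
# tolerance on ties
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b            # cases
  n <- c + d            # controls
  k <- a + c            # carriers
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# literal quadratic-time Benjamini-Hochberg step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    adj[i] <- min(1, min(m / seq(r, m) * p[ord][seq(r, m)]))
  }
  adj
}

# per-subject carrier counting
oracle_carrier_counts <- function(cohort, locus) {
  g <- cohort$genotypes
  a1 <- g[[paste0(locus, "_1")]]
  a2 <- g[[paste0(locus, "_2")]]
  typed <- which(!is.na(a1))
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  out <- data.frame(allele = alleles, case_carriers = 0L, control_carriers = 0L,
                    stringsAsFactors = FALSE)
  for (i in typed) {
    mine <- unique(c(a1[i], a2[i]))
    col <- if (g$group[i] == "case") "case_carriers" else "control_carriers"
    for (al in mine) out[out$allele == al, col] <- out[out$allele == al, col] + 1L
  }
  out$case_total <- sum(g$group[typed] == "case")
  out$control_total <- sum(g$group[typed] == "control")
  out
}

# per-column polymorphic-position detection
oracle_polymorphic <- function(catalog, locus, range, observed) {
  mat <- catalog[[locus]][observed, , drop = FALSE]
  pos <- as.integer(colnames(mat))
  keep <- integer(0)
  for (j in seq_along(pos)) {
    if (pos[j] < range[1] || pos[j] > range[2]) next
    res <- unique(mat[, j])
    res <- res[res != "*"]
    if (length(res) >= 2) keep <- c(keep, pos[j])
  }
  sort(keep)
}

# per-allele tuple read-off
oracle_realized_tuples <- function(catalog, locus, positions, observed) {
  mat <- catalog[[locus]][observed, , drop = FALSE]
  tuples <- character(0)
  for (al in observed) {
    tp <- mat[al, as.character(positions)]
    if (any(tp == "*")) next
    tuples <- c(tuples, paste(tp, collapse = ";"))
  }
  sort(unique(tuples))
}

# per-subject motif carrier counting
oracle_motif_carriers <- function(cohort, catalog, m) {
  g <- cohort$genotypes
  mat <- catalog[[m$locus]]
  matches <- function(al) {
    r <- mat[al, as.character(m$positions)]
    all(r == m$residues)
  }
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(g))) {
    x <- g[[paste0(m$locus, "_1")]][i]
    y <- g[[paste0(m$locus, "_2")]][i]
    if (is.na(x)) next
    hit <- matches(x) || matches(y)
    if (g$group[i] == "case") {
      if (hit) a <- a + 1L else b <- b + 1L
    } else {
      if (hit) cc <- cc + 1L else d <- d + 1L
    }
  }
  c(a, b, cc, d)
}

# per-subject DRB presence proportions
oracle_drb_presence <- function(cohort, map) {
  g <- cohort$genotypes
  typed <- which(!is.na(g$DRB1_1))
  out <- matrix(0L, nrow = 2, ncol = 3,
                dimnames = list(c("case", "control"), c("DRB3", "DRB4", "DRB5")))
  for (i in typed) {
    fams <- sub(":.*", "", c(g$DRB1_1[i], g$DRB1_2[i]))
    for (loc in colnames(out)) {
      if (any(map[fams] == loc)) out[g$group[i], loc] <- out[g$group[i], loc] + 1L
    }
  }
  out
}

# a deterministic hand-built cohort/catalog pair used across tests:
# DRB1 with 4 alleles differing at positions 9, 13, 57 (frame 1..60)
toy_catalog <- function() {
  base <- paste(rep("A", 60), collapse = "")
  put <- function(s, pos, res) {
    v <- strsplit(s, "")[[1]]; v[pos] <- res; paste(v, collapse = "")
  }
  s1 <- put(put(base, 13, "H"), 57, "D")         # 01:01 H13 D57
  s2 <- put(put(base, 13, "R"), 57, "D")         # 02:01 R13 D57
  s3 <- put(put(put(base, 9, "W"), 13, "H"), 57, "S")  # 03:01 W9 H13 S57
  s4 <- put(put(base, 13, "R"), 57, "S")         # 04:01 R13 S57
  hla_catalog(list(DRB1 = list(start = 1, seqs = c(
    "01:01" = s1, "02:01" = s2, "03:01" = s3, "04:01" = s4))))
}

toy_cohort <- function() {
  g <- data.frame(
    subject_id = sprintf("s%02d", 1:10),
    group = rep(c("case", "control"), each = 5),
    DRB1_1 = c("01:01", "01:01", "03:01", "02:01", "04:01",
               "02:01", "01:01", "04:01", "02:01", "04:01"),
    DRB1_2 = c("01:01", "03:01", "04:01", "02:01", "04:01",
               "04:01", "02:01", "04:01", "02:01", "04:01"),
    stringsAsFactors = FALSE)
  hla_cohort(g)
}

# random toy generators for property-style loops (plain base R, independent
# of the package's synthetic_data generators)
random_toy_catalog <- function(locus = "DRB1", n_alleles = 5, len = 20,
                               star_rate = 0.03) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cons <- sample(aa, len, replace = TRUE)
  seqs <- character(n_alleles)
  for (i in seq_len(n_alleles)) {
    v <- cons
    nmut <- sample(0:4, 1)
    if (nmut > 0) {
      at <- sample.int(len, nmut)
      v[at] <- sample(aa, nmut, replace = TRUE)
    }
    star <- runif(len) < star_rate
    v[star] <- "*"
    seqs[i] <- paste(v, collapse = "")
  }
  names(seqs) <- sprintf("%02d:01", seq_len(n_alleles))
  hla_catalog(stats::setNames(list(list(start = 1, seqs = seqs)), locus))
}

random_toy_cohort <- function(alleles, locus = "DRB1", n_case = 8,
                              n_ctrl = 12, miss = 0.1) {
  n <- n_case + n_ctrl
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- sample(alleles, n, replace = TRUE)
  drop <- runif(n) < miss
  a1[drop] <- NA; a2[drop] <- NA
  g <- data.frame(subject_id = sprintf("r%03d", 1:n),
                  group = rep(c("case", "control"), c(n_case, n_ctrl)),
                  stringsAsFactors = FALSE)
  g[[paste0(locus, "_1")]] <- a1
  g[[paste0(locus, "_2")]] <- a2
  hla_cohort(g)
}
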