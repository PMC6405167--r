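test_that("polymorphic positions are found per column among observed alleles", {
  ct <- toy_catalog()
  obs <- rownames(ct$DRB1)
  expect_equal(polymorphic_positions(ct, "DRB1", c(8, 93), obs), c(9, 13, 57))
  # restricting to observed alleles changes the answer
  expect_equal(polymorphic_positions(ct, "DRB1", c(8, 93), c("01:01", "02:01")),
               13)
  # monomorphic subset
  expect_equal(length(polymorphic_positions(ct, "DRB1", c(8, 93), "01:01")), 0L)
  # window filter
  expect_equal(polymorphic_positions(ct, "DRB1", c(10, 20), obs), 13)
  expect_error(polymorphic_positions(ct, "DQB1", c(8, 93), obs), "absent")

  set.seed(41)
  for (i in 1:30) {
    rc <- random_toy_catalog()
    obs <- sample(rownames(rc$DRB1), sample(2:5, 1))
    expect_equal(polymorphic_positions(rc, "DRB1", c(2, 18), obs),
                 oracle_polymorphic(rc, "DRB1", c(2, 18), obs))
  }
})

test_that("realised motifs are exactly the tuples read off observed alleles", {
  ct <- toy_catalog()
  obs <- rownames(ct$DRB1)
  ms <- realized_motifs(ct, "DRB1", c(13, 57), obs)
  tuples <- sort(vapply(ms, function(m) paste(m$residues, collapse = ";"),
                        character(1)))
  expect_equal(tuples, c("H;D", "H;S", "R;D", "R;S")[order(c("H;D", "H;S", "R;D", "R;S"))])
  # one allele -> exactly one motif per position set
  expect_length(realized_motifs(ct, "DRB1", c(9, 13), "03:01"), 1L)

  set.seed(42)
  for (i in 1:30) {
    rc <- random_toy_catalog()
    obs <- sample(rownames(rc$DRB1), sample(2:5, 1))
    poly <- polymorphic_positions(rc, "DRB1", c(1, 20), obs)
    if (length(poly) < 2) next
    ps <- sort(sample(poly, 2))
    got <- sort(vapply(realized_motifs(rc, "DRB1", ps, obs),
                       function(m) paste(m$residues, collapse = ";"),
                       character(1)))
    expect_equal(got, oracle_realized_tuples(rc, "DRB1", ps, obs))
  }
})

test_that("motif carrier tables match the per-subject oracle", {
  ct <- toy_catalog()
  co <- toy_cohort()
  # H13 alleles are 01:01 and 03:01: cases s1,s2,s3 carry one, controls s7
  m13 <- motif("DRB1", 13, "H")
  expect_equal(as.numeric(motif_carriers(co, ct, m13)), c(3, 2, 1, 4))
  # homozygote for a matching allele counts once (s1 is 01:01/01:01)
  m57d <- motif("DRB1", 57, "D")
  tab <- motif_carriers(co, ct, m57d)
  expect_equal(sum(tab[1:2]), 5)  # case denominators intact

  bad <- toy_cohort()
  bad$genotypes$DRB1_1[1] <- "09:01"
  expect_error(motif_carriers(bad, ct, m13), "09:01")

  set.seed(43)
  for (i in 1:30) {
    rc <- random_toy_catalog()
    co2 <- random_toy_cohort(rownames(rc$DRB1))
    poly <- polymorphic_positions(rc, "DRB1", c(1, 20), rownames(rc$DRB1))
    if (length(poly) == 0) next
    ps <- sort(sample(poly, min(length(poly), sample(1:3, 1))))
    ms <- realized_motifs(rc, "DRB1", ps, rownames(rc$DRB1))
    m <- ms[[sample(length(ms), 1)]]
    expect_equal(as.numeric(motif_carriers(co2, rc, m)),
                 oracle_motif_carriers(co2, rc, m))
  }
})

test_that("the locus scan enumerates every realised motif exactly once", {
  ct <- toy_catalog()
  co <- toy_cohort()
  cfg <- scan_config(k_max = 4)
  sc <- scan_locus(co, ct, "DRB1", config = cfg)

  # brute-force enumeration over position subsets of the 3 polymorphic
  # positions: realised tuples per subset, summed
  poly <- c(9, 13, 57)
  n_expected <- 0L
  for (k in 1:3) {
    for (ps in combn(poly, k, simplify = FALSE)) {
      n_expected <- n_expected +
        length(oracle_realized_tuples(ct, "DRB1", ps, rownames(ct$DRB1)))
    }
  }
  expect_equal(sc$n_motifs_total, n_expected)
  expect_equal(nrow(sc$results), n_expected)
  # k=1 count equals the sum of distinct known residues per position
  n1 <- sum(vapply(poly, function(p) {
    length(unique(ct$DRB1[, as.character(p)]))
  }, integer(1)))
  expect_equal(unname(sc$n_motifs_tested["1"]), n1)
  # every table is tested and adjusted within the locus family
  expect_equal(sc$results$p_adjusted, bh_adjust(sc$results$p_raw))

  # scanned carrier tables agree with direct motif counting
  i <- which(sc$results$positions == "13" & sc$results$residues == "H")
  expect_equal(as.numeric(unlist(sc$results[i, c("a", "b", "c", "d")])),
               as.numeric(motif_carriers(co, ct, motif("DRB1", 13, "H"))))
})

test_that("an allele uniquely identified by its tuple reproduces carrier_counts", {
  ct <- toy_catalog()
  co <- toy_cohort()
  # 03:01 is the only allele with W at 9
  tab <- motif_carriers(co, ct, motif("DRB1", 9, "W"))
  cc <- carrier_counts(co, "DRB1")
  r <- cc[cc$allele == "03:01", ]
  expect_equal(as.numeric(tab),
               c(r$case_carriers, r$case_total - r$case_carriers,
                 r$control_carriers, r$control_total - r$control_carriers))
})

test_that("scan results are invariant to subject and within-pair order", {
  ct <- toy_catalog()
  co <- toy_cohort()
  sc <- scan_locus(co, ct, "DRB1")
  g <- co$genotypes[sample(10), ]
  swap <- c(1, 4, 7)
  tmp <- g$DRB1_1[swap]; g$DRB1_1[swap] <- g$DRB1_2[swap]; g$DRB1_2[swap] <- tmp
  sc2 <- scan_locus(hla_cohort(g), ct, "DRB1")
  expect_equal(sc2$results, sc$results)
  expect_equal(sc2$n_motifs_tested, sc$n_motifs_tested)
})

test_that("a monomorphic locus yields zero motifs and scan_all adds counts", {
  mono <- hla_catalog(list(A = list(start = 1, seqs = c(
    "01:01" = "ACDEFGHIKL", "02:01" = "ACDEFGHIKL"))))
  g <- data.frame(subject_id = c("p1", "c1"), group = c("case", "control"),
                  A_1 = c("01:01", "02:01"), A_2 = c("02:01", "02:01"),
                  stringsAsFactors = FALSE)
  sc <- scan_locus(hla_cohort(g), mono, "A")
  expect_equal(sc$n_motifs_total, 0L)
  expect_equal(nrow(sc$results), 0L)

  # additivity across loci, and invariance of the family size to group labels
  ct <- toy_catalog()
  co <- toy_cohort()
  both_cat <- catalog_bind(ct, generate_catalog("DQB1", 3, 20, 2, seed = 9,
                                                positions = c(9, 12)))
  g2 <- co$genotypes
  set.seed(7)
  g2$DQB1_1 <- sample(c("01:01", "02:01", "03:01"), 10, replace = TRUE)
  g2$DQB1_2 <- sample(c("01:01", "02:01", "03:01"), 10, replace = TRUE)
  co2 <- hla_cohort(g2)
  sall <- scan_all(co2, both_cat)
  s1 <- scan_locus(co2, both_cat, "DRB1")
  s2 <- scan_locus(co2, both_cat, "DQB1")
  expect_equal(sall$n_motifs_total, s1$n_motifs_total + s2$n_motifs_total)

  flipped <- g2
  flipped$group <- rev(flipped$group)
  expect_equal(scan_all(hla_cohort(flipped), both_cat)$n_motifs_total,
               sall$n_motifs_total)

  empty <- hla_cohort(g2[0, ])
  expect_error(scan_all(empty, both_cat), "empty")
})

test_that("an embedded single-residue effect attains the locus-minimum raw p", {
  ct <- generate_catalog("DRB1", n_alleles = 8, seq_length = 40,
                         n_polymorphic = 4, seed = 21,
                         positions = c(11, 13, 26, 30))
  # embed the effect on the minority residue at position 13, so the baseline
  # carrier probability leaves room for enrichment
  res13 <- table(ct$DRB1[, "13"])
  m <- motif("DRB1", 13, names(res13)[which.min(res13)])
  fr <- stats::setNames(rep(1 / 8, 8), rownames(ct$DRB1))
  co <- simulate_cohort(list(DRB1 = fr), ct, n_cases = 40, n_controls = 1000,
                        effect = list(motif = m, target_or = 8), seed = 22)
  sc <- scan_locus(co, ct, "DRB1")
  best <- sc$results[which.min(sc$results$p_raw), ]
  hit <- sc$results$positions == "13" &
    sc$results$residues == m$residues
  expect_equal(sc$results$p_raw[hit], min(sc$results$p_raw))
})

test_that("min_carriers pruning shrinks the tested family", {
  ct <- toy_catalog()
  co <- toy_cohort()
  full <- scan_locus(co, ct, "DRB1")
  pruned <- scan_locus(co, ct, "DRB1", config = scan_config(min_carriers = 3))
  expect_lt(pruned$n_motifs_total, full$n_motifs_total)
  expect_true(all(pruned$results$a + pruned$results$c >= 3))
})
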