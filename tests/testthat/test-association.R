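test_that("Cochran's rule selects the exact test for sparse tables", {
  # expected case-carrier count 30*65/1030 = 1.9 < 5
  expect_equal(select_test(c(5, 25, 60, 940)), "fisher")
  # all expected counts >= 5
  expect_equal(select_test(c(25, 16, 632, 368)), "chi_square")
  expect_error(select_test(c(0, 0, 0, 0)), "degenerate")
  # caller can force either branch
  expect_equal(select_test(c(5, 25, 60, 940), rule = "chi_square"), "chi_square")
})

test_that("chi-square p-values behave as uncorrected Pearson", {
  expect_equal(chi_square_p(c(10, 10, 500, 500)), 1)
  expect_equal(chi_square_p(c(25, 16, 632, 368)), 0.772, tolerance = 0.01)
  # doubling all cells of a non-null table strictly decreases p
  t0 <- c(12, 28, 90, 110)
  expect_lt(chi_square_p(t0 * 2), chi_square_p(t0))
  expect_error(chi_square_p(c(0, 0, 5, 5)), "zero margin")
})

test_that("Fisher p-values match printed table values and conventions", {
  expect_lt(abs(fisher_exact_p(c(5, 25, 60, 940)) - 0.04), 0.01)
  expect_lt(fisher_exact_p(c(4, 35, 12, 988)), 0.005)
  expect_equal(fisher_exact_p(c(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_p(c(0, 5, 0, 10)), 1)  # zero margin convention
})

test_that("odds ratios reproduce published values and algebraic identities", {
  expect_equal(round(odds_ratio(c(25, 16, 632, 368)), 2), 0.91)
  expect_equal(round(odds_ratio(c(10, 31, 324, 676)), 2), 0.67)
  expect_equal(odds_ratio(c(7, 7, 13, 13)), 1)
  expect_identical(odds_ratio(c(3, 0, 5, 2)), Inf)
  expect_true(is.nan(odds_ratio(c(0, 5, 0, 7))))
  set.seed(2)
  for (i in 1:20) {
    t <- rpois(4, 20) + 1
    expect_equal(odds_ratio(t) * odds_ratio(t[c(3, 4, 1, 2)]), 1)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_gte(min(adj), min(p))
    expect_lte(max(adj), 1)
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("TOST equivalence p has the right limits and monotonicity", {
  t <- c(12, 29, 300, 700)  # 0.293 vs 0.3
  # shrinking the margin towards zero forces p_equiv >= 0.5
  expect_gte(tost_equivalence(t, 1e-9)$p_equiv, 0.5)
  # p_equiv non-increasing in the margin on fixed data
  deltas <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  ps <- vapply(deltas, function(d) tost_equivalence(t, d)$p_equiv, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(tost_equivalence(t, 0), "positive")
  expect_error(tost_equivalence(t, -0.1), "positive")
})

test_that("TOST matches a direct evaluation of the two z-statistics", {
  # equal proportions 0.3 vs 0.3 at the study's group sizes, margin 0.2
  t <- c(12, 29, 300, 700)
  got <- tost_equivalence(t, 0.2)
  p1 <- 12 / 41; p0 <- 0.3
  se <- sqrt(p1 * (1 - p1) / 41 + p0 * (1 - p0) / 1000)
  d <- p1 - p0
  p_expected <- max(pnorm((d + 0.2) / se, lower.tail = FALSE),
                    pnorm((d - 0.2) / se))
  expect_equal(got$p_equiv, p_expected)
  expect_lt(got$p_equiv, 1e-2)
})

test_that("per-allele association assembles tables, tests and FDR correctly", {
  g <- data.frame(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("case", "control"), each = 10),
    A_1 = c(rep("01:01", 7), rep("02:01", 3), rep("01:01", 3), rep("02:01", 7)),
    A_2 = c(rep("01:01", 7), rep("02:01", 3), rep("01:01", 3), rep("02:01", 7)),
    stringsAsFactors = FALSE)
  co <- hla_cohort(g)
  res <- run_allele_association(co)
  expect_equal(nrow(res), 2L)
  expect_equal(res$p_adjusted, bh_adjust(res$p_raw))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_equal(res$case_freq, res$case_carriers / res$case_total)

  only_cases <- hla_cohort(g[g$group == "case", ])
  expect_error(run_allele_association(only_cases), "both groups required")
})

test_that("global FDR scope pools allele families across loci", {
  co <- simulate_cohort(
    list(A = c("01:01" = 0.6, "02:01" = 0.4),
         B = c("07:02" = 0.5, "08:01" = 0.5)),
    n_cases = 15, n_controls = 30, seed = 10)
  glob <- run_allele_association(co, fdr_scope = "global")
  expect_equal(glob$p_adjusted, bh_adjust(glob$p_raw))
  per <- run_allele_association(co, fdr_scope = "per_locus")
  for (loc in c("A", "B")) {
    i <- per$locus == loc
    expect_equal(per$p_adjusted[i], bh_adjust(per$p_raw[i]))
  }
})
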