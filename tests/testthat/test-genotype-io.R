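write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("genotype tables read with normalisation, missingness and errors", {
  f <- write_lines_tmp(c(
    "subject_id,group,A_1,A_2,DRB1_1,DRB1_2",
    "p1,case,A*02:01:01,02:05,04:01,07:01",
    "c1,control,,,15:01,15:01"))
  co <- read_genotypes(f)
  expect_equal(n_cases(co), 1L)
  expect_equal(n_controls(co), 1L)
  expect_equal(co$loci, c("A", "DRB1"))
  # prefix stripped, three-field call truncated
  expect_equal(co$genotypes$A_1[1], "02:01")
  # both cells blank: subject retained with a missing pair
  expect_true(is.na(co$genotypes$A_1[2]) && is.na(co$genotypes$A_2[2]))

  half <- write_lines_tmp(c(
    "subject_id,group,A_1,A_2",
    "p1,case,02:01,"))
  expect_error(read_genotypes(half), "one of the two allele cells")

  dup <- write_lines_tmp(c(
    "subject_id,group,A_1,A_2",
    "p1,case,02:01,03:01",
    "p1,control,02:01,03:01"))
  expect_error(read_genotypes(dup), "duplicate subject_id")
})

test_that("cohort and catalog round-trip through write/read exactly", {
  co <- simulate_cohort(
    list(A = c("01:01" = 0.5, "02:01" = 0.3, "03:01" = 0.2)),
    n_cases = 6, n_controls = 9, missingness = 0.2, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(co, f)
  expect_equal(read_genotypes(f), co)

  cat1 <- generate_catalog("B", n_alleles = 4, seq_length = 12,
                           n_polymorphic = 3, seed = 8)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, g)
  expect_equal(read_catalog(g), cat1)
})

test_that("catalog loading enforces the alignment frame and alphabet", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tallele\tstart_position\tsequence",
               "DRB1\t01:01\t1\tACDEFGHIKL",
               "DRB1\t02:01\t1\tACDEF-HIK*",
               "DRB1\t03:01\t1\tACWEFGHIKL"), f)
  ct <- read_catalog(f)
  expect_equal(as.integer(colnames(ct$DRB1)), 1:10)
  # '-' resolved to the reference residue; '*' kept as unknown
  expect_equal(unname(ct$DRB1["02:01", "6"]), "G")
  expect_equal(unname(ct$DRB1["02:01", "10"]), "*")

  writeLines(c("locus\tallele\tstart_position\tsequence",
               "DRB1\t01:01\t1\tACDEF",
               "DRB1\t02:01\t1\tACDEFGH"), f)
  expect_error(read_catalog(f), "unequal")

  writeLines(c("locus\tallele\tstart_position\tsequence",
               "DRB1\t01:01\t1\tACDEZ"), f)
  expect_error(read_catalog(f), "alphabet")
})

test_that("carrier counting matches the per-subject oracle and its invariants", {
  # homozygote counts once; zero controls typed at the locus
  g <- data.frame(subject_id = c("p1", "p2", "c1"),
                  group = c("case", "case", "control"),
                  A_1 = c("02:01", "02:01", NA),
                  A_2 = c("02:01", "03:01", NA),
                  stringsAsFactors = FALSE)
  cc <- carrier_counts(hla_cohort(g), "A")
  r <- cc[cc$allele == "02:01", ]
  expect_equal(r$case_carriers, 2L)
  expect_equal(r$case_total, 2L)
  expect_equal(r$control_total, 0L)

  # untyped locus: empty result
  expect_equal(nrow(carrier_counts(hla_cohort(g), "B")), 0L)

  set.seed(31)
  for (i in 1:25) {
    ct <- random_toy_catalog()
    co <- random_toy_cohort(rownames(ct$DRB1))
    got <- carrier_counts(co, "DRB1")
    exp <- oracle_carrier_counts(co, "DRB1")
    expect_equal(got$allele, exp$allele)
    expect_equal(got$case_carriers, exp$case_carriers)
    expect_equal(got$control_carriers, exp$control_carriers)
    expect_equal(got$case_total[1], exp$case_total[1])
    # per-subject carrier indicators sum to 1 or 2 at every typed locus
    g2 <- co$genotypes
    typed <- !is.na(g2$DRB1_1)
    n_carried <- mapply(function(x, y) length(unique(c(x, y))),
                        g2$DRB1_1[typed], g2$DRB1_2[typed])
    expect_true(all(n_carried >= 1 & n_carried <= 2))

    # invariance to subject order and within-pair allele order
    perm <- sample(nrow(g2))
    g3 <- g2[perm, ]
    swap <- seq_len(nrow(g3)) %% 2 == 0
    tmp <- g3$DRB1_1[swap]
    g3$DRB1_1[swap] <- g3$DRB1_2[swap]
    g3$DRB1_2[swap] <- tmp
    expect_equal(carrier_counts(hla_cohort(g3), "DRB1"), got)
  }
})

test_that("published carrier percentages reconstruct from per-locus denominators", {
  # 30 typed cases of which 9 carry A*01:01 -> 30.0%
  g <- data.frame(
    subject_id = sprintf("p%02d", 1:30), group = "case",
    A_1 = c(rep("01:01", 9), rep("02:01", 21)),
    A_2 = rep("24:02", 30), stringsAsFactors = FALSE)
  g <- rbind(g, data.frame(subject_id = "c1", group = "control",
                           A_1 = "01:01", A_2 = "01:01"))
  cc <- carrier_counts(hla_cohort(g), "A")
  r <- cc[cc$allele == "01:01", ]
  expect_equal(r$case_carriers / r$case_total, 0.300)
})
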