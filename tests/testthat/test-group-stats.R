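test_that("rater averaging collapses to one row per patient and timepoint", {
  feat <- cached_cohort_features()
  av <- average_raters(feat)
  expect_equal(nrow(av), 118)
  expect_true(all(av$rater == "mean"))

  # arithmetic-mean check on one cell
  one <- feat[feat$patient_id == "P001" & feat$timepoint == "pre", ]
  got <- av[av$patient_id == "P001" & av$timepoint == "pre", ]
  expect_equal(got$uniformity, mean(one$uniformity))
  expect_equal(got$entropy, mean(one$entropy))

  # identical raters: averaging is the identity on features
  dup <- feat[feat$rater == "R1", ]
  dup2 <- dup; dup2$rater <- "R2"
  av2 <- average_raters(rbind(dup, dup2))
  expect_equal(av2$energy, dup$energy[order(dup$patient_id, dup$timepoint)])

  # a missing rater row is a hard error naming the slot
  broken <- feat[-1, ]
  expect_error(average_raters(broken), "missing")
})

test_that("signed-rank test matches exact enumeration and handles the null identity", {
  expect_warning(r0 <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(r0$p_value, 1)

  # six all-positive differences: exact two-sided p = 2/64
  r6 <- paired_wilcoxon(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(r6$p_value, 2 / 64)

  set.seed(55)
  for (i in 1:5) {
    pre <- rnorm(7)
    early <- pre + rnorm(7)
    got <- paired_wilcoxon(pre, early)$p_value
    expect_equal(got, enum_sr_p(early - pre), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney matches exact enumeration and is rank-invariant", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)

  set.seed(66)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(mann_whitney(a, b)$p_value, enum_mw_p(a, b),
                 tolerance = 1e-12)
  }

  # identical groups are null
  x <- c(1, 5, 9, 13)
  expect_gte(mann_whitney(x, x)$p_value, 0.99)

  # invariance under a strictly monotone transform of the pooled values
  a <- rnorm(20); b <- rnorm(25) + 0.5
  p1 <- mann_whitney(a, b)$p_value
  p2 <- mann_whitney(exp(a), exp(b))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("median and IQR use linear interpolation", {
  s <- summarize_median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(unname(s["median"]), 3)
  s2 <- summarize_median_iqr(rep(4.2, 9))
  expect_equal(unname(s2["median"]), unname(s2["q1"]))
  expect_equal(unname(s2["q1"]), unname(s2["q3"]))
  set.seed(3)
  s3 <- summarize_median_iqr(runif(1000))
  expect_equal(unname(s3), c(0.5, 0.25, 0.75), tolerance = 0.05)
})

test_that("group tables report both standards with correct group sizes", {
  feat <- cached_cohort_features()
  av <- average_raters(feat)
  gt <- run_group_tables(av)
  expect_equal(nrow(gt$paired), 7)
  expect_equal(nrow(gt$trg), 14)
  expect_equal(nrow(gt$pcr), 14)
  expect_true(all(gt$trg$n1 == 30 & gt$trg$n2 == 29))
  expect_true(all(gt$pcr$n1 == 15 & gt$pcr$n2 == 44))
  expect_true(all(gt$paired$p_value >= 0 & gt$paired$p_value <= 1))

  # Holm correction is available and never smaller than the raw p
  gth <- run_group_tables(av, p_adjust = "holm")
  expect_true(all(gth$pcr$p_adjusted >= gth$pcr$p_value))

  one <- av[av$patient_id == "P001", ]
  expect_error(run_group_tables(one), "at least 2")
})
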