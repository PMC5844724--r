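test_that("phantom generation is deterministic and honors point-mass targets", {
  sp <- phantom_spec(seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)

  spc <- phantom_spec(target_marginal = marginal_point(7), seed = 3)
  suppressWarnings(f <- extract_features(generate_phantom(spc)))
  expect_equal(f$entropy, 0)
  expect_equal(f$uniformity, 1)
  expect_equal(f$mean, 7)
})

test_that("histogram matching recovers a uniform 32-level target on a large ROI", {
  sp <- phantom_spec(image_size = 160, roi_axes = c(62, 55),
                     target_marginal = marginal_levels(rep(1, 32), 0, 32),
                     seed = 8)
  f <- extract_features(generate_phantom(sp), n_bins = 32)
  expect_gte(f$n_pixels, 1e4)
  expect_lt(abs(f$entropy - 5), 0.02)
  expect_lt(abs(f$uniformity - 1 / 32), 0.005)
})

test_that("marginal quantiles and standardization are exact", {
  m <- marginal_histogram(c(0, 1, 3, 10), c(0.2, 0.5, 0.3))
  # CDF round trip on a grid
  p <- seq(0.001, 0.999, length.out = 200)
  q <- marginal_quantile(m, p)
  cdf <- vapply(q, function(x) {
    0.2 * min(1, max(0, x / 1)) +
      0.5 * min(1, max(0, (x - 1) / 2)) +
      0.3 * min(1, max(0, (x - 3) / 7))
  }, 0)
  expect_equal(cdf, p, tolerance = 1e-10)

  ms <- marginal_standardize(m, mean = 200, sd = 30)
  n <- 2e5
  x <- marginal_quantile(ms, (seq_len(n) - 0.5) / n)
  expect_equal(mean(x), 200, tolerance = 0.01)
  expect_equal(sd(x), 30, tolerance = 0.01)
  expect_error(marginal_standardize(marginal_point(3), 0, 1), "support points")
})

test_that("mask perturbation is bounded by a one-pixel boundary band", {
  m <- rectexture:::ellipse_mask(64, c(20, 20))
  expect_identical(perturb_mask(m, 0, 1), m)
  p1 <- perturb_mask(m, 1, seed = 9)
  expect_identical(p1, perturb_mask(m, 1, seed = 9))
  expect_true(any(p1))

  # counting oracle: pixels within Euclidean distance 1.5 of the other
  # side, via 8-neighborhood shifts
  shift <- function(mat, di, dj) {
    out <- matrix(FALSE, nrow(mat), ncol(mat))
    ri <- seq_len(nrow(mat)); rj <- seq_len(ncol(mat))
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= nrow(mat); ok_j <- sj >= 1 & sj <= ncol(mat)
    out[ri[ok_i], rj[ok_j]] <- mat[si[ok_i], sj[ok_j]]
    out
  }
  near_other <- function(mat) {
    acc <- matrix(FALSE, nrow(mat), ncol(mat))
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      acc <- acc | shift(mat, di, dj)
    }
    acc
  }
  ring_out <- sum(!m & near_other(m))   # background touching the mask
  ring_in <- sum(m & near_other(!m))    # mask touching the background
  added <- sum(p1 & !m)
  removed <- sum(m & !p1)
  expect_lte(added, ring_out)
  expect_lte(removed, ring_in)
  expect_lte(abs(sum(p1) - sum(m)), max(ring_in, ring_out))
})

test_that("cohort generation yields 236 labeled feature rows, deterministically", {
  feat <- cached_cohort_features()
  expect_equal(nrow(feat), 59 * 2 * 2)
  expect_equal(length(unique(feat$patient_id)), 59)
  expect_equal(sum(feat$pcr) / 4, 15)
  expect_equal(sum(feat$responder_trg) / 4, 30)
  expect_true(all(feat$responder_trg == (feat$trg <= 2)))

  co2 <- generate_cohort(cohort_spec(seed = 101))
  feat2 <- extract_cohort_features(co2)
  expect_equal(feat, feat2)

  expect_error(cohort_spec(n_pcr = 40, n_nonpcr = 19), "n_pcr")
  expect_error(cohort_spec(n_pcr = 10, n_nonpcr = 10), "inconsistent")
})

test_that("two-rater ICC decreases with rater jitter and is 1 at zero jitter", {
  iccs <- vapply(c(0, 1.5, 4), function(j) {
    co <- generate_cohort(cohort_spec(seed = 17, rater_jitter = j))
    tab <- icc_table(extract_cohort_features(co))
    mean(tab$icc[tab$parameter == "entropy"])
  }, 0)
  expect_equal(iccs[1], 1)
  expect_true(all(diff(iccs) < 0))
})

test_that("a zero-effect cohort gives uniform responder-test p-values", {
  ps <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_spec(seed = 4000 + s, effect_scale = 0,
                                      image_size = 48, roi_axes = c(18, 13)))
    av <- average_raters(extract_cohort_features(co))
    pre <- av[av$timepoint == "pre", ]
    mann_whitney(pre$uniformity[pre$pcr], pre$uniformity[!pre$pcr])$p_value
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.005)
  expect_lt(mean(ps < 0.05), 0.2)
})
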