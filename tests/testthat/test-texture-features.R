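test_that("discretization handles the uniform identity and degenerate cases", {
  h <- discretize(0:31, n_bins = 32)
  expect_equal(h$probabilities, rep(1 / 32, 32))
  expect_equal(sum(h$counts), 32)
  expect_true(all(diff(h$bin_edges) > 0))

  h7 <- discretize(rep(7, 50), n_bins = 32)
  expect_equal(sum(h7$probabilities == 1), 1)
  expect_equal(sum(h7$counts), 50)
  expect_equal(histogram_stats(h7)$entropy, 0)
  expect_equal(histogram_stats(h7)$uniformity, 1)

  expect_error(discretize(numeric(0)), "empty ROI")
  expect_error(discretize(c(1, NA)), "finite")
  expect_error(discretize(1:10, n_bins = 1), "n_bins")
})

test_that("discretization matches a naive per-value binning loop", {
  set.seed(31)
  for (rep in 1:5) {
    x <- runif(1000)
    h <- discretize(x, n_bins = 16)
    lo <- min(x); width <- (max(x) - lo) / 16
    naive <- rep(0L, 16)
    for (v in x) {
      b <- min(floor((v - lo) / width) + 1, 16)
      naive[b] <- naive[b] + 1L
    }
    expect_identical(h$counts, naive)
  }
})

test_that("first-order moments match hand evaluation and flag zero variance", {
  fo <- first_order_stats(c(1, 2, 3, 4))
  expect_equal(fo$mean, 2.5)
  expect_equal(fo$sd, sqrt(5 / 3), tolerance = 1e-12)  # 1.29099...

  expect_warning(fo0 <- first_order_stats(rep(3, 10)), "undefined")
  expect_equal(fo0$sd, 0)
  expect_true(is.na(fo0$skewness) && is.na(fo0$kurtosis))
})

test_that("histogram features reproduce closed forms", {
  hs <- histogram_stats(c(0.5, 0.5))
  expect_equal(hs$entropy, 1)
  expect_equal(hs$uniformity, 0.5)

  hs1 <- histogram_stats(1)
  expect_equal(hs1$entropy, 0)
  expect_equal(hs1$uniformity, 1)

  hs8 <- histogram_stats(rep(1 / 8, 8))
  expect_equal(hs8$entropy, 3)
  expect_equal(hs8$uniformity, 0.125)

  # weighted variant keeps the printed definition available
  expect_equal(histogram_stats(c(0.5, 0.5), "weighted")$uniformity,
               1 * 0.25 + 2 * 0.25)
})

test_that("entropy and uniformity are anti-monotone over two-bin histograms", {
  ps <- seq(0.01, 0.5, by = 0.01)
  ent <- vapply(ps, function(p) histogram_stats(c(p, 1 - p))$entropy, 0)
  uni <- vapply(ps, function(p) histogram_stats(c(p, 1 - p))$uniformity, 0)
  expect_true(all(diff(ent) > 0))
  expect_true(all(diff(uni) < 0))
  expect_true(all(ent >= 0 & ent <= 1))
  expect_true(all(uni >= 0.5 & uni <= 1))
})

test_that("extracted features agree with the naive loop oracle, ties included", {
  set.seed(77)
  for (i in 1:15) {
    img <- random_masked_image()
    f <- extract_features(img, n_bins = 32)
    o <- naive_features(img$pixels, img$mask, 32)
    for (nm in c("mean", "sd", "skewness", "kurtosis", "uniformity",
                 "energy", "entropy")) {
      expect_equal(f[[nm]], o[[nm]], tolerance = 1e-10, label = nm)
    }
  }
})

test_that("constant ROI yields the degenerate feature vector", {
  img <- masked_image(matrix(7, 12, 12), matrix(TRUE, 12, 12))
  expect_warning(f <- extract_features(img), "undefined")
  expect_equal(f$mean, 7)
  expect_equal(f$sd, 0)
  expect_equal(f$entropy, 0)
  expect_equal(f$uniformity, 1)
  expect_true(is.na(f$skewness) && is.na(f$kurtosis))
})

test_that("features ignore pixel order and mask-external values", {
  set.seed(12)
  img <- random_masked_image(20, 20)
  f1 <- extract_features(img)

  # permute masked values among masked positions
  px <- img$pixels
  idx <- which(img$mask)
  px[idx] <- px[sample(idx)]
  f2 <- extract_features(masked_image(px, img$mask))

  # scramble everything outside the mask
  px2 <- img$pixels
  px2[!img$mask] <- rnorm(sum(!img$mask), 1e6, 100)
  f3 <- extract_features(masked_image(px2, img$mask))

  drop_id <- function(f) f[!(names(f) %in% c("patient_id", "timepoint", "rater"))]
  expect_equal(drop_id(f1), drop_id(f2), tolerance = 1e-12)
  expect_equal(drop_id(f1), drop_id(f3), tolerance = 1e-12)
})

test_that("an intensity shift moves the mean and nothing else", {
  set.seed(5)
  img <- random_masked_image(25, 25)
  f1 <- extract_features(img)
  f2 <- extract_features(masked_image(img$pixels + 123.45, img$mask))
  expect_equal(f2$mean, f1$mean + 123.45, tolerance = 1e-9)
  for (nm in c("sd", "skewness", "kurtosis", "uniformity", "entropy")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-9, label = nm)
  }
})

test_that("feature bounds hold on random inputs", {
  set.seed(99)
  for (i in 1:20) {
    img <- random_masked_image()
    f <- extract_features(img, n_bins = 32)
    expect_gte(f$sd, 0)
    expect_true(f$uniformity > 0 && f$uniformity <= 1)
    expect_true(f$entropy >= 0 && f$entropy <= log2(32) + 1e-12)
    expect_true(f$energy >= 0 && f$energy <= 1)
    if (!is.na(f$kurtosis)) expect_gte(f$kurtosis, 1)
  }
})
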