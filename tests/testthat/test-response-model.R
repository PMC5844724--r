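test_that("ROC analysis handles separation, the worked pair count, and reversal", {
  r <- roc_analysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_true(r$cutoff >= 2 && r$cutoff < 3)

  r2 <- roc_analysis(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r2$auc, 0.75)

  # anti-predictive scores: direction flips, AUC re-oriented to 1
  r3 <- roc_analysis(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r3$auc, 1)
  expect_equal(r3$direction, "<=")

  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("empirical AUC equals pair enumeration on random data with ties", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(8:50, 1)
    scores <- sample(1:12, n, replace = TRUE) + rbinom(n, 1, 0.5) * 0.5
    labels <- rbinom(n, 1, 0.4) == 1
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, max(pair_auc(scores, labels),
                            1 - pair_auc(scores, labels)),
                 tolerance = 1e-12)
  }
})

test_that("the Youden cutoff reproduces its reported sensitivity and specificity", {
  set.seed(21)
  for (i in 1:10) {
    n <- 40
    labels <- rbinom(n, 1, 0.4) == 1
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    scores <- rnorm(n) + labels
    r <- roc_analysis(scores, labels)
    called_pos <- if (r$direction == ">") scores > r$cutoff else scores <= r$cutoff
    expect_equal(100 * mean(called_pos[labels]), r$sensitivity)
    expect_equal(100 * mean(!called_pos[!labels]), r$specificity)
  }
})

test_that("AUC is invariant to strictly increasing score transforms", {
  set.seed(13)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5) == 1
  labels[1:2] <- c(TRUE, FALSE)
  a1 <- roc_analysis(scores, labels)$auc
  a2 <- roc_analysis(qlogis(plogis(scores * 3 + 2)), labels)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("backward elimination keeps signal, drops noise, and flags null fits", {
  set.seed(31)
  keep_signal <- 0
  for (i in 1:20) {
    n <- 500
    x_sig <- rnorm(n)
    x_noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * x_sig)) == 1
    m <- select_features_backward(data.frame(sig = x_sig, noise = x_noise),
                                  y, c("sig", "noise"))
    if (identical(m$retained, "sig") && m$coefficients[["sig"]] > 0) {
      keep_signal <- keep_signal + 1
      expect_equal(m$trace$removed, "noise")
    }
  }
  expect_gte(keep_signal, 18)

  intercept_only <- 0
  for (i in 1:20) {
    n <- 500
    y <- rbinom(n, 1, 0.4) == 1
    m <- select_features_backward(
      data.frame(a = rnorm(n), b = rnorm(n)), y, c("a", "b"))
    if (m$intercept_only) intercept_only <- intercept_only + 1
  }
  expect_gte(intercept_only, 15)
})

test_that("perfect separation on a tiny sample raises the separation warning", {
  warns <- character()
  withCallingHandlers(
    m <- select_features_backward(data.frame(x = c(1, 2, 9, 10)),
                                  c(FALSE, FALSE, TRUE, TRUE), "x"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("separation", warns)))
  expect_true(m$separation)
})

test_that("predicted probabilities invert the logit and respect monotonicity", {
  m0 <- structure(list(coefficients = c("(Intercept)" = 0, f = 0),
                       retained = "f"), class = "texture_logistic")
  expect_equal(predict_probabilities(m0, data.frame(f = c(-5, 0, 7))),
               rep(0.5, 3))

  m1 <- structure(list(coefficients = c("(Intercept)" = log(3)),
                       retained = character(0)), class = "texture_logistic")
  expect_equal(predict_probabilities(m1, data.frame(x = 1:4)), rep(0.75, 4))

  m2 <- structure(list(coefficients = c("(Intercept)" = -1, f = 2),
                       retained = "f"), class = "texture_logistic")
  p <- predict_probabilities(m2, data.frame(f = c(0, 1, 2)))
  expect_true(all(diff(p) > 0))
  expect_error(predict_probabilities(m2, data.frame(g = 1)), "lacks")
})

test_that("DeLong comparison is null on identical scores and powered on signal", {
  set.seed(17)
  labels <- rbinom(60, 1, 0.4) == 1
  labels[1:2] <- c(TRUE, FALSE)
  s <- rnorm(60) + labels
  cmp <- compare_auc_delong(s, s, labels)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)

  hits <- 0
  for (i in 1:5) {
    n <- 400
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * x)) == 1
    cmp <- compare_auc_delong(x, rnorm(n), y)
    if (cmp$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("response analysis gates candidates and reports apparent performance", {
  feat <- cached_cohort_features()
  av <- average_raters(feat)
  ra <- response_analysis(av, "pcr")
  expect_true(all(ra$candidates %in% feature_names()))
  expect_true(all(ra$gate_p[ra$candidates] < 0.05))
  expect_true(all(ra$table$performance == "apparent"))

  # alpha = 1 admits every feature
  ra_all <- response_analysis(av, "pcr", alpha = 1)
  expect_setequal(ra_all$candidates, feature_names())

  # combined model, when present, is ROC-analyzed on predicted probabilities
  if (!is.null(ra$roc_combined)) {
    expect_true(ra$roc_combined$auc >= 0.5 && ra$roc_combined$auc <= 1)
    probs <- predict_probabilities(ra$model,
                                   av[av$timepoint == "pre", ])
    expect_true(all(probs > 0 & probs < 1))
  }
})
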