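#' Interobserver agreement via the intraclass correlation coefficient
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC —
#' ICC(A,1) in McGraw & Wong's taxonomy, ICC(2,1) in Shrout & Fleiss's —
#' between two raters' per-subject feature values. Raters are modeled as
#' a random sample of interchangeable readers, and systematic offsets
#' between raters count against agreement (absolute agreement, not mere
#' consistency). The 95% confidence interval uses the F-distribution
#' construction with Satterthwaite degrees of freedom.
#'
#' If all values are identical across subjects and raters the ICC is
#' defined as 1 with a degenerate interval and a warning.
#'
#' @param rater_a,rater_b Numeric vectors of the same length (>= 3),
#'   paired by subject.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `icc_result`: list with `estimate`,
#'   `ci_low`, `ci_high`, `model` (`"ICC(A,1)"`), `n_subjects`, `band`
#'   (agreement label from [classify_agreement()]).
#' @examples
#' set.seed(1)
#' x <- rnorm(30)
#' icc_agreement(x, x + rnorm(30, sd = 0.3))
#' @export
icc_agreement <- function(rater_a, rater_b, conf_level = 0.95) {
  if (length(rater_a) != length(rater_b)) stop("rater vectors must be paired")
  n <- length(rater_a)
  if (n < 3L) stop("need at least 3 subjects")
  x <- cbind(rater_a, rater_b)
  if (!all(is.finite(x))) stop("values must be finite")
  k <- 2L

  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && mse == 0)) {
    warning("no variance in either raters or subjects; ICC degenerate, returning 1")
    est <- 1
    lo <- hi <- 1
  } else {
    est <- (msr - mse) / denom
    alpha <- 1 - conf_level
    r <- max(est, .Machine$double.eps)
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    lo <- min(lo, est)
    hi <- max(hi, est)
  }
  structure(list(estimate = est, ci_low = lo, ci_high = hi,
                 model = "ICC(A,1)", n_subjects = n,
                 band = classify_agreement(est)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI %.3f-%.3f), n = %d subjects: %s agreement\n",
              x$model, x$estimate, x$ci_low, x$ci_high, x$n_subjects, x$band))
  invisible(x)
}

#' Label an ICC estimate with its agreement band
#'
#' Conventional interpretation bands: 0-0.20 poor, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00 excellent. Boundaries
#' are half-open on the left (an estimate of exactly 0.60 is moderate,
#' 0.61 good) so the printed ranges are exhaustive. Negative estimates
#' are bucketed as poor, with a warning.
#'
#' @param estimate Finite ICC estimate.
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`,
#'   `"excellent"`.
#' @export
classify_agreement <- function(estimate) {
  stopifnot(is.finite(estimate))
  if (estimate < 0) {
    warning("negative ICC estimate classified as poor agreement")
    return("poor")
  }
  if (estimate <= 0.20) "poor"
  else if (estimate <= 0.40) "fair"
  else if (estimate <= 0.60) "moderate"
  else if (estimate <= 0.80) "good"
  else "excellent"
}

#' Interobserver agreement table for a cohort
#'
#' Computes the two-rater ICC of every texture feature at each timepoint
#' from a long-format cohort feature table (one row per patient,
#' timepoint and rater), the per-feature analogue of a standard
#' interobserver-agreement reporting table.
#'
#' @param cohort_table Data frame from [extract_cohort_features()].
#' @param raters Length-2 character: the two rater identifiers to compare.
#' @param conf_level Confidence level for the ICC intervals.
#' @return Data frame with columns `timepoint`, `parameter`, `icc`,
#'   `ci_low`, `ci_high`, `band`, `n_subjects`, `model`.
#' @export
icc_table <- function(cohort_table, raters = c("R1", "R2"),
                      conf_level = 0.95) {
  stopifnot(length(raters) == 2L)
  out <- list()
  for (tp in unique(cohort_table$timepoint)) {
    sub <- cohort_table[cohort_table$timepoint == tp, , drop = FALSE]
    a <- sub[sub$rater == raters[1L], , drop = FALSE]
    b <- sub[sub$rater == raters[2L], , drop = FALSE]
    a <- a[order(a$patient_id), , drop = FALSE]
    b <- b[order(b$patient_id), , drop = FALSE]
    if (!identical(a$patient_id, b$patient_id)) {
      stop(sprintf("raters disagree on patient set at timepoint %s", tp))
    }
    for (f in feature_names()) {
      r <- icc_agreement(a[[f]], b[[f]], conf_level = conf_level)
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, parameter = f, icc = r$estimate,
        ci_low = r$ci_low, ci_high = r$ci_high, band = r$band,
        n_subjects = r$n_subjects, model = r$model,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
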