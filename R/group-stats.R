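#' Average the two raters' feature values
#'
#' Collapses the long-format cohort table to one row per (patient,
#' timepoint), replacing each feature by the across-rater arithmetic
#' mean. All group comparisons and models downstream operate on these
#' rater-averaged values, so neither reader's delineation dominates.
#'
#' @param cohort_table Data frame from [extract_cohort_features()].
#' @param raters Rater identifiers that must all be present for every
#'   (patient, timepoint).
#' @return Data frame with one row per (patient, timepoint), `rater`
#'   column set to `"mean"`.
#' @export
average_raters <- function(cohort_table, raters = c("R1", "R2")) {
  missing_r <- setdiff(raters, unique(cohort_table$rater))
  if (length(missing_r)) {
    stop(sprintf("rater(s) %s absent from the table",
                 paste(missing_r, collapse = ", ")))
  }
  key <- interaction(cohort_table$patient_id, cohort_table$timepoint,
                     drop = TRUE)
  tab <- table(key, cohort_table$rater)
  bad <- which(apply(tab[, raters, drop = FALSE], 1, function(z) any(z != 1L)))
  if (length(bad)) {
    stop(sprintf("missing or duplicated rater rows for %s",
                 paste(rownames(tab)[bad[1L]], collapse = "")))
  }
  sub <- cohort_table[cohort_table$rater %in% raters, , drop = FALSE]
  feats <- intersect(c(feature_names(), "n_pixels"), names(sub))
  agg <- stats::aggregate(sub[feats],
                          by = list(patient_id = sub$patient_id,
                                    timepoint = sub$timepoint),
                          FUN = mean)
  meta_cols <- intersect(c("trg", "responder_trg", "pcr", "n_bins_used"),
                         names(sub))
  meta <- unique(sub[c("patient_id", "timepoint", meta_cols)])
  out <- merge(agg, meta, by = c("patient_id", "timepoint"), sort = FALSE)
  out$rater <- "mean"
  out[order(out$patient_id, out$timepoint), , drop = FALSE]
}

#' Paired pre- vs early-treatment comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on per-patient paired values.
#' Zero differences are dropped (the classical Wilcoxon convention); the
#' exact null distribution is used when at most 25 nonzero differences
#' remain and their absolute values are untied, otherwise the normal
#' approximation with tie correction and continuity correction. If every
#' difference is zero the test is vacuous: p = 1 with a warning.
#'
#' @param pre,early Numeric vectors paired by patient.
#' @param parameter Feature name for the output row.
#' @return A one-row `group_comparison` data frame: parameter, per-group
#'   median and quartiles, test statistic, two-sided p, test label, n.
#' @export
paired_wilcoxon <- function(pre, early, parameter = "feature") {
  if (length(pre) != length(early)) stop("pre/early must be paired")
  d <- early - pre
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; p = 1")
    stat <- 0
    p <- 1
  } else {
    exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
    ht <- suppressWarnings(
      stats::wilcox.test(early, pre, paired = TRUE, exact = exact,
                         correct = TRUE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  s1 <- summarize_median_iqr(pre)
  s2 <- summarize_median_iqr(early)
  group_comparison_row(parameter, "pre", s1, length(pre), "early", s2,
                       length(early), stat, p, "Wilcoxon signed-rank")
}

#' Unpaired responder vs nonresponder comparison (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U test. The exact null distribution is used
#' when the smaller group has at most 8 observations and the pooled
#' values are untied; otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param group_a,group_b Numeric vectors, both nonempty.
#' @param parameter Feature name for the output row.
#' @param names_ab Length-2 character naming the groups.
#' @return A one-row `group_comparison` data frame (see
#'   [paired_wilcoxon()]).
#' @export
mann_whitney <- function(group_a, group_b, parameter = "feature",
                         names_ab = c("A", "B")) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty")
  }
  pooled <- c(group_a, group_b)
  exact <- min(length(group_a), length(group_b)) <= 8L &&
    !anyDuplicated(pooled)
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  group_comparison_row(parameter,
                       names_ab[1L], summarize_median_iqr(group_a),
                       length(group_a),
                       names_ab[2L], summarize_median_iqr(group_b),
                       length(group_b),
                       unname(ht$statistic), ht$p.value, "Mann-Whitney U")
}

group_comparison_row <- function(parameter, name1, s1, n1, name2, s2, n2,
                                 stat, p, test) {
  out <- data.frame(parameter = parameter,
                    group1 = name1, median1 = s1[["median"]],
                    q1_1 = s1[["q1"]], q3_1 = s1[["q3"]], n1 = n1,
                    group2 = name2, median2 = s2[["median"]],
                    q1_2 = s2[["q1"]], q3_2 = s2[["q3"]], n2 = n2,
                    statistic = stat, p_value = p, test = test,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Median and interquartile range
#'
#' Median with 25th and 75th percentiles by linear interpolation
#' (`stats::quantile` type 7), the `median (Q1-Q3)` presentation used in
#' the summary tables.
#'
#' @param values Nonempty numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
summarize_median_iqr <- function(values) {
  if (length(values) == 0L) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' All group-comparison tables for a rater-averaged cohort
#'
#' Produces the three analysis tables of the study design:
#' `paired`: per-feature pre- vs early-treatment signed-rank comparison
#' (all patients); `trg` and `pcr`: per-feature, per-timepoint
#' responder-vs-nonresponder Mann-Whitney comparisons under the
#' tumor-regression-grade (TRG 1-2) and complete-response (ypT0N0)
#' standards, each with median (Q1-Q3) group summaries. No
#' multiple-testing correction is applied by default; `p_adjust =
#' "holm"` adds an adjusted-p column within each table.
#'
#' @param averaged Rater-averaged cohort table from [average_raters()].
#' @param p_adjust `"none"` (default) or any method of
#'   [stats::p.adjust()].
#' @return List of data frames `paired`, `trg`, `pcr`.
#' @export
run_group_tables <- function(averaged, p_adjust = "none") {
  if (length(unique(averaged$patient_id)) < 2L) {
    stop("need at least 2 patients for group comparisons")
  }
  pre <- averaged[averaged$timepoint == "pre", , drop = FALSE]
  early <- averaged[averaged$timepoint == "early", , drop = FALSE]
  pre <- pre[order(pre$patient_id), , drop = FALSE]
  early <- early[order(early$patient_id), , drop = FALSE]
  if (!identical(pre$patient_id, early$patient_id)) {
    stop("pre and early timepoints cover different patients")
  }

  paired <- do.call(rbind, lapply(feature_names(), function(f) {
    paired_wilcoxon(pre[[f]], early[[f]], parameter = f)
  }))

  label_table <- function(flag_col, names_ab) {
    rows <- list()
    for (tp in c("pre", "early")) {
      sub <- averaged[averaged$timepoint == tp, , drop = FALSE]
      g1 <- sub[sub[[flag_col]], , drop = FALSE]
      g2 <- sub[!sub[[flag_col]], , drop = FALSE]
      for (f in feature_names()) {
        row <- mann_whitney(g1[[f]], g2[[f]],
                            parameter = paste0(tp, "-", f),
                            names_ab = names_ab)
        row$timepoint <- tp
        rows[[length(rows) + 1L]] <- row
      }
    }
    do.call(rbind, rows)
  }
  trg <- label_table("responder_trg", c("TRG1-2", "TRG3-5"))
  pcr <- label_table("pcr", c("pCR", "non-pCR"))

  out <- list(paired = paired, trg = trg, pcr = pcr)
  if (p_adjust != "none") {
    out <- lapply(out, function(tb) {
      tb$p_adjusted <- stats::p.adjust(tb$p_value, method = p_adjust)
      tb
    })
  }
  out
}
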