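#' ROC analysis of a single feature
#'
#' Empirical ROC analysis of per-subject scores against a binary response
#' label. The AUC is the Mann-Whitney pair-counting probability (ties
#' count 1/2) that a random positive outscores a random negative; the
#' orientation is chosen so AUC >= 0.5, and the reported `direction`
#' records the positive call rule: `">"` means subjects with
#' `score > cutoff` are called positive, `"<="` means `score <= cutoff`.
#' The optimal cutoff maximizes the Youden index
#' (sensitivity + specificity - 1); among ties the smallest threshold is
#' reported. The cutoff is always one of the observed score values, so
#' the reported sensitivity and specificity are exactly attained on the
#' input data. The AUC confidence interval uses the DeLong variance
#' estimate.
#'
#' @param scores Numeric per-subject scores.
#' @param labels Binary response labels (logical, or coercible 0/1); both
#'   classes must be present.
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `direction`, `sensitivity`, `specificity` (percent),
#'   `youden`, `n_pos`, `n_neg`, plus a `curve` data frame of ROC
#'   coordinates (1 - specificity, sensitivity) for plotting.
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")

  auc_raw <- auc_rank(scores, labels)
  direction <- if (auc_raw >= 0.5) ">" else "<="
  s <- if (direction == ">") scores else -scores
  auc <- auc_rank(s, labels)

  # candidate cutoffs: observed values; positive call is score > c
  cand <- sort(unique(s))
  sens <- vapply(cand, function(cc) mean(s[labels] > cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(s[!labels] <= cc), numeric(1))
  # calling everyone positive is also admissible
  cand <- c(-Inf, cand)
  sens <- c(1, sens)
  spec <- c(0, spec)
  youden <- sens + spec - 1
  best <- which(youden >= max(youden) - 1e-12)[1L]  # smallest threshold wins ties
  cutoff <- cand[best]
  if (direction == "<=") cutoff <- -cutoff

  ci <- tryCatch({
    r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = if (direction == ">") "<" else ">")
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  }, error = function(e) c(NA_real_, auc, NA_real_))

  structure(list(auc = auc,
                 ci_low = max(0, ci[1L]), ci_high = min(1, ci[3L]),
                 cutoff = cutoff, direction = direction,
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 youden = youden[best],
                 n_pos = n_pos, n_neg = n_neg,
                 curve = data.frame(fpr = 1 - spec, tpr = sens)),
            class = "roc_result")
}

# Mann-Whitney rank AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); cutoff %s %.4g: sens %.2f%%, spec %.2f%% (%d pos / %d neg)\n",
              x$auc, x$ci_low, x$ci_high, x$direction, x$cutoff,
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Backward-elimination logistic combination of features
#'
#' Fits a logistic regression of the binary response on the candidate
#' features and iteratively removes the feature with the largest Wald
#' p-value above `alpha` until every retained feature is significant (or
#' none remain, in which case the intercept-only model is returned and
#' flagged). With `criterion = "LRT"` the elimination uses
#' likelihood-ratio p-values instead of Wald. Perfect or quasi-perfect
#' separation is detected from the glm fit and reported as a warning
#' naming the offending feature; coefficients are then unreliable.
#'
#' @param data Data frame containing the candidate feature columns.
#' @param labels Binary response (logical or 0/1), one per row of `data`.
#' @param candidates Character vector of feature column names to start
#'   from (typically the univariately significant features).
#' @param alpha Retention threshold on the per-feature p-value.
#' @param criterion `"wald"` (default) or `"LRT"`.
#' @return An object of class `texture_logistic`: `coefficients`,
#'   `retained`, `trace` (data frame of elimination steps),
#'   `fitted_probabilities`, `intercept_only` flag, `separation` flag and
#'   the final `glm` fit.
#' @export
select_features_backward <- function(data, labels, candidates,
                                     alpha = 0.05,
                                     criterion = c("wald", "LRT")) {
  criterion <- match.arg(criterion)
  labels <- as.logical(labels)
  stopifnot(nrow(data) == length(labels))
  missing_c <- setdiff(candidates, names(data))
  if (length(missing_c)) {
    stop(sprintf("candidate feature(s) not in data: %s",
                 paste(missing_c, collapse = ", ")))
  }
  if (nrow(data) < 10L) {
    warning("fewer than 10 subjects: estimates will be unstable")
  }

  current <- candidates
  trace <- data.frame(step = integer(), removed = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  separation <- FALSE
  sep_feature <- NA_character_
  fit <- NULL
  repeat {
    fml <- if (length(current)) {
      stats::reformulate(current, response = ".y")
    } else {
      stats::as.formula(".y ~ 1")
    }
    df <- data.frame(.y = labels, data[current], check.names = FALSE)
    sep_here <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = df),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep_here <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep_here && !separation) {
      separation <- TRUE
      cf <- stats::coef(fit)[-1L]
      if (length(cf)) sep_feature <- names(cf)[which.max(abs(cf))]
      warning(sprintf(
        "(quasi-)perfect separation detected%s; coefficients unreliable",
        if (is.na(sep_feature)) "" else paste0(" (feature ", sep_feature, ")")))
    }
    if (!length(current)) break
    pv <- if (criterion == "wald") {
      stats::coef(summary(fit))[current, "Pr(>|z|)"]
    } else {
      dr <- stats::drop1(fit, test = "LRT")
      stats::setNames(dr[current, "Pr(>Chi)"], current)
    }
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = current[worst],
                                     p_value = unname(pv[worst]),
                                     stringsAsFactors = FALSE))
    current <- current[-worst]
  }
  structure(list(coefficients = stats::coef(fit), retained = current,
                 trace = trace,
                 fitted_probabilities = unname(stats::fitted(fit)),
                 intercept_only = length(current) == 0L,
                 separation = separation, fit = fit,
                 criterion = criterion, alpha = alpha),
            class = "texture_logistic")
}

#' @export
print.texture_logistic <- function(x, ...) {
  cat(sprintf("<texture_logistic> retained: %s (%d elimination step%s, %s p-values, alpha %.2f)\n",
              if (x$intercept_only) "none (intercept only)" else
                paste(x$retained, collapse = ", "),
              nrow(x$trace), if (nrow(x$trace) == 1) "" else "s",
              x$criterion, x$alpha))
  invisible(x)
}

#' Predicted response probabilities from a fitted combination model
#'
#' Inverse-logit of the linear predictor: the per-subject combined
#' biomarker score in (0, 1) used as the "predicted probability"
#' predictor in the combined-model ROC analysis.
#'
#' @param model A `texture_logistic` from [select_features_backward()].
#' @param data Data frame containing every retained feature column.
#' @return Numeric vector of probabilities.
#' @export
predict_probabilities <- function(model, data) {
  stopifnot(inherits(model, "texture_logistic"))
  missing_c <- setdiff(model$retained, names(data))
  if (length(missing_c)) {
    stop(sprintf("data lacks retained feature(s): %s",
                 paste(missing_c, collapse = ", ")))
  }
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(data))
  for (f in model$retained) eta <- eta + model$coefficients[[f]] * data[[f]]
  stats::plogis(eta)
}

#' Paired comparison of two correlated AUCs (DeLong test)
#'
#' Tests whether two predictors measured on the same subjects have equal
#' AUC against the same response labels, using DeLong's nonparametric
#' test for correlated ROC curves (two-sided).
#'
#' Each AUC is reported in its predictive orientation (>= 0.5), matching
#' the convention of [roc_analysis()].
#'
#' @param scores_a,scores_b Per-subject scores for the two predictors.
#' @param labels Binary response labels.
#' @return List with `auc_a`, `auc_b`, `difference` (a minus b) and
#'   two-sided `p_value`. Identical score vectors give difference 0 and
#'   p = 1.
#' @export
compare_auc_delong <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  auc_a <- max(auc_rank(scores_a, labels), 1 - auc_rank(scores_a, labels))
  auc_b <- max(auc_rank(scores_b, labels), 1 - auc_rank(scores_b, labels))
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(auc_a = auc_a, auc_b = auc_b, difference = 0, p_value = 1))
  }
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "auto")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "auto")
  # each curve is compared in its own predictive orientation; pROC's
  # advisory about differing directions is the intended behavior here
  ht <- withCallingHandlers(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
    warning = function(w) {
      if (grepl("different direction", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(auc_a = auc_a, auc_b = auc_b, difference = auc_a - auc_b,
       p_value = ht$p.value)
}

#' Full response-prediction analysis for one label standard
#'
#' The diagnostic-performance stage of the pipeline: gate features into
#' the multivariable candidate set by univariate significance
#' (Mann-Whitney by default, univariate logistic Wald optionally), run
#' per-feature ROC analyses, fit the backward-elimination logistic
#' combination, ROC-analyze its predicted probabilities, and DeLong-test
#' the combined model against each retained single feature. All AUCs are
#' apparent (in-sample); no train/test split is performed.
#'
#' @param averaged Rater-averaged cohort table ([average_raters()]),
#'   filtered here to `timepoint`.
#' @param label_col `"pcr"` or `"responder_trg"` (or any logical column).
#' @param timepoint Which scan to analyze; default `"pre"`.
#' @param alpha Univariate gate and backward-elimination threshold.
#' @param gate `"mannwhitney"` (default) or `"logistic"`.
#' @param features Candidate feature pool; defaults to all seven.
#' @return List with `candidates`, `roc` (named list of `roc_result` per
#'   candidate), `model` (`texture_logistic` or NULL if no candidates),
#'   `roc_combined`, `delong_vs_single` (data frame), and a flat `table`
#'   data frame shaped like a predictive-values reporting table.
#' @export
response_analysis <- function(averaged, label_col = "pcr",
                              timepoint = "pre", alpha = 0.05,
                              gate = c("mannwhitney", "logistic"),
                              features = feature_names()) {
  gate <- match.arg(gate)
  sub <- averaged[averaged$timepoint == timepoint, , drop = FALSE]
  labels <- as.logical(sub[[label_col]])
  if (!any(labels) || all(labels)) stop("both response classes required")

  gate_p <- vapply(features, function(f) {
    if (gate == "mannwhitney") {
      mann_whitney(sub[[f]][labels], sub[[f]][!labels], parameter = f)$p_value
    } else {
      fit <- stats::glm(labels ~ sub[[f]], family = stats::binomial())
      stats::coef(summary(fit))[2L, "Pr(>|z|)"]
    }
  }, numeric(1))
  candidates <- features[gate_p < alpha]

  roc_single <- lapply(stats::setNames(candidates, candidates), function(f) {
    roc_analysis(sub[[f]], labels)
  })

  model <- NULL
  roc_combined <- NULL
  delong <- NULL
  if (length(candidates)) {
    model <- select_features_backward(sub, labels, candidates, alpha = alpha)
    if (!model$intercept_only) {
      probs <- predict_probabilities(model, sub)
      roc_combined <- roc_analysis(probs, labels)
      delong <- do.call(rbind, lapply(model$retained, function(f) {
        cmp <- compare_auc_delong(probs, sub[[f]], labels)
        data.frame(feature = f, auc_combined = cmp$auc_a,
                   auc_single = cmp$auc_b, difference = cmp$difference,
                   p_value = cmp$p_value, stringsAsFactors = FALSE)
      }))
    }
  }

  tab <- do.call(rbind, c(
    lapply(names(roc_single), function(f) roc_row(f, roc_single[[f]])),
    if (!is.null(roc_combined)) list(roc_row("combined_logistic", roc_combined))
  ))
  list(label = label_col, timepoint = timepoint, gate = gate,
       gate_p = gate_p, candidates = candidates, roc = roc_single,
       model = model, roc_combined = roc_combined,
       delong_vs_single = delong, table = tab)
}

roc_row <- function(name, r) {
  data.frame(parameter = name,
             cutoff = sprintf("%s %.4g", r$direction, r$cutoff),
             auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
             sensitivity = r$sensitivity, specificity = r$specificity,
             n_pos = r$n_pos, n_neg = r$n_neg,
             performance = "apparent", stringsAsFactors = FALSE)
}
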