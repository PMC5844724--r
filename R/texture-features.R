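#' Discretize intensities into equally spaced bins
#'
#' Resamples a set of ROI voxel intensities into `n_bins` equal-width bins
#' spanning the observed range. Discretization normalizes intensities
#' across patients and suppresses scanner noise before the histogram
#' features (uniformity, entropy) are computed. The last bin is
#' right-closed so the maximum falls into bin `n_bins`.
#'
#' A zero intensity range (all values identical) is not an error: all mass
#' is assigned to a single bin, so constant phantoms flow through the
#' pipeline and yield entropy 0 and uniformity 1 downstream.
#'
#' @param values Numeric vector of intensities; nonempty, finite.
#' @param n_bins Number of bins, at least 2. Default 32.
#' @return An object of class `discretized_histogram`: list with
#'   `bin_edges` (length `n_bins + 1`, strictly increasing), `counts`
#'   (integer, sums to `length(values)`), `probabilities` (sums to 1),
#'   `n_bins`.
#' @examples
#' h <- discretize(0:31, n_bins = 32)
#' all(h$probabilities == 1 / 32)
#' @export
discretize <- function(values, n_bins = 32L) {
  if (length(values) == 0L) stop("empty ROI")
  if (!all(is.finite(values))) stop("intensities must be finite")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("`n_bins` must be an integer >= 2")

  lo <- min(values)
  hi <- max(values)
  if (hi > lo) {
    width <- (hi - lo) / n_bins
    idx <- pmin.int(floor((values - lo) / width) + 1L, n_bins)
    edges <- lo + (0:n_bins) * width
  } else {
    # degenerate range: one bin holds everything; edges kept strictly
    # increasing by centering a unit-width window on the single value
    idx <- rep.int(1L, length(values))
    edges <- seq(lo - 0.5, lo + 0.5, length.out = n_bins + 1L)
  }
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 probabilities = counts / length(values), n_bins = n_bins),
            class = "discretized_histogram")
}

#' First-order statistics of raw ROI intensities
#'
#' Computes the four moment-based features on the raw (undiscretized)
#' intensities: mean, standard deviation (with the \eqn{1/(N-1)}
#' denominator), skewness \eqn{m_3 / m_2^{3/2}} and non-excess kurtosis
#' \eqn{m_4 / m_2^2}, where \eqn{m_k = \frac{1}{N}\sum_i (x_i - \bar x)^k}
#' are population central moments. A Gaussian intensity distribution has
#' skewness 0 and kurtosis 3.
#'
#' @param values Numeric vector of ROI intensities.
#' @return Named list with `mean`, `sd`, `skewness`, `kurtosis`,
#'   `n_pixels`. When the sample standard deviation is zero, skewness and
#'   kurtosis are undefined and returned as `NA` with a warning.
#' @export
first_order_stats <- function(values) {
  if (length(values) == 0L) stop("empty ROI")
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2L) stats::sd(values) else 0
  d <- values - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    warning("zero intensity variance: skewness and kurtosis undefined")
    skew <- NA_real_
    kurt <- NA_real_
  }
  list(mean = m, sd = s, skewness = skew, kurtosis = kurt, n_pixels = n)
}

#' Histogram features of a discretized intensity distribution
#'
#' Uniformity \eqn{\sum_i P(i)^2} and entropy
#' \eqn{-\sum_i P(i) \log_2 P(i)} (bits, with \eqn{0 \log 0 := 0}) of the
#' binned probabilities. Uniformity lies in \eqn{(0, 1]} and is maximal
#' (1) when all mass sits in one bin; entropy lies in
#' \eqn{[0, \log_2 n_{bins}]} and is maximal for a flat histogram. The two
#' move in opposite directions: a homogeneous tumor has high uniformity
#' and low entropy.
#'
#' `uniformity_variant = "weighted"` computes \eqn{\sum_i i \cdot P(i)^2}
#' (bin index as weight) instead. This variant is unbounded above 1 and is
#' provided only for auditability against software that defines uniformity
#' that way; the standard sum of squared probabilities is the default.
#'
#' @param hist A `discretized_histogram` (or a bare probability vector).
#' @param uniformity_variant `"standard"` (default) or `"weighted"`.
#' @return Named list with `uniformity` and `entropy`.
#' @export
histogram_stats <- function(hist, uniformity_variant = c("standard", "weighted")) {
  uniformity_variant <- match.arg(uniformity_variant)
  p <- if (inherits(hist, "discretized_histogram")) hist$probabilities else hist
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  uniformity <- if (uniformity_variant == "standard") {
    sum(p^2)
  } else {
    sum(seq_along(p) * p^2)
  }
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  list(uniformity = uniformity, entropy = entropy)
}

# Energy of the ROI intensities. The default ("minmax") is the mean of
# squared min-max-normalized intensities, bounded in [0, 1]: it is high
# when most pixels sit near the ROI maximum. "probability" sums the
# squared bin probabilities of the supplied histogram (identical to
# standard uniformity). A zero intensity range puts every pixel at the
# single (maximal) level, so energy is defined as 1.
roi_energy <- function(values, hist, variant = c("minmax", "probability")) {
  variant <- match.arg(variant)
  if (variant == "probability") return(sum(hist$probabilities^2))
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) return(1)
  mean(((values - lo) / (hi - lo))^2)
}

#' Extract the seven first-order texture features from a masked image
#'
#' The full per-image feature vector used throughout the pipeline:
#' mean, standard deviation, skewness and kurtosis are computed on the raw
#' masked intensities; the intensities are then resampled into `n_bins`
#' equally spaced bins and uniformity and entropy are computed on the
#' binned probabilities. Energy is the mean squared min-max-normalized
#' intensity (see [histogram_stats()] and the package vignette for the
#' variant switches).
#'
#' @param img A [masked_image()].
#' @param n_bins Number of discretization bins (default 32); recorded in
#'   the output as `n_bins_used`.
#' @param uniformity_variant,energy_variant Feature-definition switches;
#'   see [histogram_stats()] and Details.
#' @return A one-row `data.frame` with columns `patient_id`, `timepoint`,
#'   `rater`, `mean`, `sd`, `skewness`, `kurtosis`, `uniformity`,
#'   `energy`, `entropy`, `n_bins_used`, `n_pixels`.
#' @examples
#' img <- masked_image(matrix(runif(256), 16, 16), matrix(TRUE, 16, 16))
#' extract_features(img)
#' @export
extract_features <- function(img, n_bins = 32L,
                             uniformity_variant = c("standard", "weighted"),
                             energy_variant = c("minmax", "probability")) {
  stopifnot(inherits(img, "masked_image"))
  v <- img$pixels[img$mask]
  if (length(v) == 0L) stop("empty ROI")
  fo <- first_order_stats(v)
  h <- discretize(v, n_bins = n_bins)
  hs <- histogram_stats(h, uniformity_variant = uniformity_variant)
  en <- roi_energy(v, h, variant = energy_variant)
  data.frame(patient_id = img$patient_id, timepoint = img$timepoint,
             rater = img$rater,
             mean = fo$mean, sd = fo$sd, skewness = fo$skewness,
             kurtosis = fo$kurtosis, uniformity = hs$uniformity,
             energy = en, entropy = hs$entropy,
             n_bins_used = h$n_bins, n_pixels = fo$n_pixels,
             stringsAsFactors = FALSE)
}

# Names of the seven texture features, in reporting order.
feature_names <- function() {
  c("mean", "sd", "skewness", "kurtosis", "uniformity", "energy", "entropy")
}
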