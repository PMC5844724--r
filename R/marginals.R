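#' Piecewise-uniform intensity marginals
#'
#' The phantom generator controls the first-order statistics of a
#' synthetic tumor by histogram matching the in-ROI pixels to a target
#' marginal distribution. Targets are represented as piecewise-uniform
#' densities: `breaks` (length k+1, nondecreasing) delimit k segments and
#' `probs` gives the probability mass of each segment, spread uniformly
#' within it. This covers discrete level histograms (equal-width cells),
#' arbitrary histograms, and the peak-plus-background mixture family used
#' for the cohort defaults. A point mass (zero-width support) is allowed
#' and produces a constant ROI.
#'
#' @param breaks Numeric vector of segment boundaries, nondecreasing.
#' @param probs Probability mass per segment; nonnegative, summing to 1.
#'   Segments of zero width must carry zero mass unless the marginal is a
#'   pure point mass (use [marginal_point()]).
#' @return An object of class `intensity_marginal`.
#' @seealso [marginal_levels()], [marginal_mixture()], [marginal_point()]
#' @export
marginal_histogram <- function(breaks, probs) {
  breaks <- as.numeric(breaks)
  probs <- as.numeric(probs)
  if (length(breaks) != length(probs) + 1L) {
    stop("`breaks` must have one more element than `probs`")
  }
  if (is.unsorted(breaks)) stop("`breaks` must be nondecreasing")
  if (any(probs < 0)) stop("`probs` must be nonnegative")
  s <- sum(probs)
  if (s <= 0) stop("`probs` must have positive total mass")
  probs <- probs / s
  w <- diff(breaks)
  if (any(probs > 0 & w == 0)) {
    stop("zero-width segment with positive mass; use marginal_point() for a point mass")
  }
  structure(list(breaks = breaks, probs = probs), class = "intensity_marginal")
}

#' @describeIn marginal_histogram Degenerate marginal concentrated at one value.
#' @param value The single intensity value.
#' @export
marginal_point <- function(value) {
  structure(list(breaks = c(value, value), probs = 1, point = TRUE),
            class = "intensity_marginal")
}

#' @describeIn marginal_histogram Histogram over `length(probs)` equal-width
#'   cells spanning `[lo, hi)`; `probs` may be unnormalized weights.
#' @param lo,hi Intensity range covered by the cells.
#' @export
marginal_levels <- function(probs, lo = 0, hi = length(probs)) {
  marginal_histogram(seq(lo, hi, length.out = length(probs) + 1L), probs)
}

#' Peak-plus-background mixture marginal
#'
#' The parametric family behind the default phantom cohort: a dominant
#' narrow uniform component of mass `p_dom`, centered at relative position
#' `dom_pos` within `[lo, hi]` with width `dom_width` (as a fraction of
#' the range), over a uniform background carrying the remaining mass.
#' Raising `p_dom` concentrates the histogram (uniformity up, entropy
#' down, kurtosis up); moving `dom_pos` toward 1 pushes mass toward the
#' ROI maximum (energy up); widening the background range raises the
#' standard deviation.
#'
#' @param lo,hi Intensity range.
#' @param p_dom Mass of the dominant component, in `[0, 1]`.
#' @param dom_pos Relative position of the peak center in `[0, 1]`.
#' @param dom_width Peak width as a fraction of `hi - lo`.
#' @return An `intensity_marginal`.
#' @export
marginal_mixture <- function(lo, hi, p_dom, dom_pos, dom_width = 0.05) {
  stopifnot(hi > lo, p_dom >= 0, p_dom <= 1, dom_width > 0)
  span <- hi - lo
  ctr <- lo + dom_pos * span
  w <- dom_width * span
  a <- max(lo, ctr - w / 2)
  b <- min(hi, ctr + w / 2)
  brk <- sort(unique(c(lo, a, b, hi)))
  dens_bg <- (1 - p_dom) / span
  dens_dom <- p_dom / (b - a)
  probs <- vapply(seq_len(length(brk) - 1L), function(j) {
    seg <- brk[j + 1L] - brk[j]
    d <- dens_bg + if (brk[j] >= a && brk[j + 1L] <= b) dens_dom else 0
    seg * d
  }, numeric(1))
  marginal_histogram(brk, probs)
}

# Quantile function of a piecewise-uniform marginal; p vectorized in [0, 1].
marginal_quantile <- function(m, p) {
  stopifnot(inherits(m, "intensity_marginal"))
  if (isTRUE(m$point)) return(rep.int(m$breaks[1L], length(p)))
  cum <- c(0, cumsum(m$probs))
  cum[length(cum)] <- 1  # guard against rounding
  j <- findInterval(p, cum, all.inside = TRUE)
  # snap off zero-mass segments so interpolation stays well-defined
  k <- length(m$probs)
  for (i in which(m$probs[j] == 0)) {
    up <- j[i]
    while (up <= k && m$probs[up] == 0) up <- up + 1L
    if (up <= k) {
      j[i] <- up
      p[i] <- cum[up]
    } else {
      dn <- j[i]
      while (dn >= 1L && m$probs[dn] == 0) dn <- dn - 1L
      j[i] <- dn
      p[i] <- cum[dn + 1L]
    }
  }
  m$breaks[j] + (p - cum[j]) / m$probs[j] * (m$breaks[j + 1L] - m$breaks[j])
}

# Mean and variance of a piecewise-uniform marginal (closed form).
marginal_moments <- function(m) {
  if (isTRUE(m$point)) return(c(mean = m$breaks[1L], var = 0))
  a <- m$breaks[-length(m$breaks)]
  b <- m$breaks[-1L]
  mu <- sum(m$probs * (a + b) / 2)
  ex2 <- sum(m$probs * (a^2 + a * b + b^2) / 3)
  c(mean = mu, var = ex2 - mu^2)
}

#' Affine-standardize a marginal to a target mean and SD
#'
#' Rescales and shifts a piecewise-uniform marginal so its mean and
#' standard deviation equal the targets, leaving the histogram shape --
#' and with it every affine-invariant feature (skewness, kurtosis,
#' uniformity, entropy, energy) -- unchanged. The cohort generator uses
#' this to decouple the moment features from the shape features: each
#' patient's mean and SD are drawn independently of response group, so
#' group signal lives purely in histogram shape.
#'
#' @param m An `intensity_marginal` with positive variance.
#' @param mean,sd Target mean and standard deviation (`sd > 0`).
#' @return A standardized `intensity_marginal`.
#' @export
marginal_standardize <- function(m, mean, sd) {
  stopifnot(inherits(m, "intensity_marginal"), sd > 0)
  mom <- marginal_moments(m)
  if (mom[["var"]] <= 0) {
    stop("cannot standardize a marginal with fewer than 2 support points to a nonzero sd")
  }
  scale <- sd / sqrt(mom[["var"]])
  marginal_histogram((m$breaks - mom[["mean"]]) * scale + mean, m$probs)
}
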