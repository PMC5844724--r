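#' Specification of a single synthetic tumor phantom
#'
#' Parameters for one 2D phantom slice: a smoothed Gaussian random field
#' whose in-ROI pixels are histogram-matched to a target marginal, inside
#' an elliptical ROI. Because first-order texture features are insensitive
#' to spatial arrangement, rank-based histogram matching controls the
#' extracted features essentially exactly while the smoothing keeps the
#' image visually tumor-like (spatially coherent) rather than salt-and-
#' pepper noise.
#'
#' @param image_size Image side length in pixels (square image).
#' @param roi_axes Length-2 numeric: ellipse semi-axes in pixels. The
#'   ellipse is centered in the image and must fit inside it.
#' @param target_marginal An [marginal_histogram()] object: the target
#'   intensity distribution of the in-ROI pixels.
#' @param smoothing_scale Gaussian smoothing sigma in pixels applied to the
#'   underlying white-noise field (spatial correlation length). Default 2.
#' @param rater_jitter Boundary perturbation radius in pixels used when a
#'   second rater's mask is derived from the true ROI; `0` means identical
#'   masks.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L,
                         roi_axes = c(25, 18),
                         target_marginal = marginal_mixture(120, 330, 0.8, 0.5),
                         smoothing_scale = 2,
                         rater_jitter = 1.5,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(image_size >= 8L, length(roi_axes) == 2L, all(roi_axes >= 1),
            inherits(target_marginal, "intensity_marginal"),
            smoothing_scale >= 0, rater_jitter >= 0)
  ctr <- (image_size + 1) / 2
  if (any(roi_axes >= ctr - 1)) stop("ROI ellipse does not fit inside the image")
  structure(list(image_size = image_size, roi_axes = roi_axes,
                 target_marginal = target_marginal,
                 smoothing_scale = smoothing_scale,
                 rater_jitter = rater_jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Centered elliptical boolean mask.
ellipse_mask <- function(image_size, roi_axes) {
  ctr <- (image_size + 1) / 2
  x <- (seq_len(image_size) - ctr) / roi_axes[1L]
  y <- (seq_len(image_size) - ctr) / roi_axes[2L]
  outer(x^2, y^2, `+`) <= 1
}

#' Generate a synthetic tumor phantom
#'
#' Draws a white-noise field, smooths it at `smoothing_scale`, and
#' rank-transforms the in-ROI pixels onto the deterministic quantile grid
#' of the target marginal (value \eqn{Q((r - 0.5)/N)} for the pixel of
#' rank \eqn{r} among \eqn{N} ROI pixels). The in-ROI marginal therefore
#' matches the target exactly up to the quantile-grid discretization, so
#' extracted features converge to the target's features as the ROI grows.
#' Pixels outside the ROI carry rescaled background field (cosmetic only;
#' feature extraction never reads them). Identical spec and seed give
#' bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id,timepoint,rater Metadata for the returned image.
#' @return A [masked_image()].
#' @examples
#' img <- generate_phantom(phantom_spec(seed = 7))
#' extract_features(img)
#' @export
generate_phantom <- function(spec, patient_id = "phantom",
                             timepoint = "pre", rater = "R1") {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    field <- matrix(stats::rnorm(spec$image_size^2),
                    spec$image_size, spec$image_size)
  })
  if (spec$smoothing_scale > 0) {
    field <- EBImage::gblur(field, sigma = spec$smoothing_scale)
  }
  mask <- ellipse_mask(spec$image_size, spec$roi_axes)
  n <- sum(mask)
  q <- marginal_quantile(spec$target_marginal, (seq_len(n) - 0.5) / n)
  vals <- numeric(n)
  vals[order(field[mask])] <- q
  rng <- range(q)
  if (rng[2L] > rng[1L]) {
    frng <- range(field)
    bg <- (field - frng[1L]) / (frng[2L] - frng[1L])
    pixels <- rng[1L] + 0.5 * bg * (rng[2L] - rng[1L])
  } else {
    pixels <- matrix(0, spec$image_size, spec$image_size)
  }
  pixels[mask] <- vals
  masked_image(pixels, mask, patient_id = patient_id,
               timepoint = timepoint, rater = rater)
}

#' Randomly perturb an ROI boundary
#'
#' Emulates a second rater's manual delineation by moving the mask
#' boundary in or out by up to `jitter` pixels. A smooth random field
#' (in `[-1, 1]`) modulates the signed distance to the original boundary,
#' so the result always lies between the `jitter`-eroded and
#' `jitter`-dilated masks, and contiguous stretches of boundary move
#' together as a human tracing error would. `jitter = 0` returns the mask
#' unchanged. If the perturbation empties the mask the jitter is halved
#' and retried; if it still empties, an error is raised.
#'
#' @param mask Logical matrix, nonempty.
#' @param jitter Maximum boundary displacement in pixels, `>= 0`.
#' @param seed Integer seed.
#' @return A logical matrix of the same dimensions.
#' @export
perturb_mask <- function(mask, jitter, seed = 1L) {
  mask <- roi_binarize(mask)
  if (!any(mask)) stop("empty mask")
  if (jitter == 0) return(mask)
  stopifnot(jitter > 0)
  storage.mode(mask) <- "integer"
  d_in <- EBImage::distmap(mask)
  d_out <- EBImage::distmap(1L - mask)
  # signed distance to the boundary, centered between the pixel rings
  s <- ifelse(mask > 0, as.numeric(d_in) - 0.5, -(as.numeric(d_out) - 0.5))
  dim(s) <- dim(mask)
  withr::with_seed(seed, {
    u <- matrix(stats::rnorm(length(mask)), nrow(mask), ncol(mask))
  })
  u <- EBImage::gblur(u, sigma = 2)
  u <- u / max(abs(u))
  j <- jitter
  for (attempt in 1:3) {
    out <- s > j * u
    if (any(out)) {
      dim(out) <- dim(mask)
      return(out)
    }
    j <- j / 2
  }
  stop("mask perturbation emptied the ROI even after reducing jitter")
}
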