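#' Masked tumor-slice image
#'
#' Bundles one 2D grayscale slice with a binary region-of-interest (ROI)
#' mask and the metadata needed downstream: patient identifier, timepoint
#' (`"pre"` = before chemoradiotherapy, `"early"` = at the third week of
#' treatment) and rater identifier. This is the unit of feature extraction:
#' all seven first-order features are computed from the pixels the mask
#' selects.
#'
#' @param pixels Numeric matrix of signal intensities (arbitrary T2-weighted
#'   units).
#' @param mask Logical (or 0/1 numeric) matrix of the same dimensions;
#'   `TRUE` marks tumor pixels. Must select at least one pixel.
#' @param patient_id Character scalar.
#' @param timepoint `"pre"` or `"early"`.
#' @param rater Character scalar identifying the reader who drew the mask.
#'
#' @return An object of class `masked_image` with elements `pixels`, `mask`,
#'   `patient_id`, `timepoint`, `rater`.
#' @examples
#' img <- masked_image(matrix(rnorm(64), 8, 8),
#'                     matrix(TRUE, 8, 8), "P001", "pre", "R1")
#' extract_features(img, n_bins = 8)
#' @export
masked_image <- function(pixels, mask, patient_id = "unknown",
                         timepoint = c("pre", "early"), rater = "R1") {
  timepoint <- match.arg(timepoint)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  mask <- roi_binarize(mask)
  if (!identical(dim(pixels), dim(mask))) {
    stop(sprintf("mask shape (%s) does not match pixel shape (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(dim(pixels), collapse = "x")))
  }
  if (!any(mask)) stop("empty ROI: mask selects no pixels")
  if (!all(is.finite(pixels[mask]))) stop("masked intensities must be finite")
  structure(list(pixels = pixels, mask = mask,
                 patient_id = as.character(patient_id),
                 timepoint = timepoint, rater = as.character(rater)),
            class = "masked_image")
}

# Coerce a mask raster to logical; any value > 0 counts as foreground.
roi_binarize <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
  } else {
    m <- mask > 0
  }
  m[is.na(m)] <- FALSE
  dim(m) <- dim(mask)
  m
}

#' @export
print.masked_image <- function(x, ...) {
  cat(sprintf("<masked_image> %s / %s / rater %s: %dx%d pixels, ROI %d px\n",
              x$patient_id, x$timepoint, x$rater,
              nrow(x$pixels), ncol(x$pixels), sum(x$mask)))
  invisible(x)
}
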