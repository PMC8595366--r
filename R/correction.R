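# Camera corrections and the empirical FRET ratio-correction image.

#' Camera correction set
#'
#' @param dark_image camera dark-state image (counts per pixel).
#' @param sensitivity_image multiplicative chip-sensitivity map (strictly
#'   positive; also carries the dust correction when provided).
#' @param ratio_correction_image optional full-field multiplicative map
#'   dividing out the apparent FRET-ratio gradient; strictly positive.
#' @return object of class `correction_set`.
#' @export
correction_set <- function(dark_image, sensitivity_image = NULL,
                           ratio_correction_image = NULL) {
  stopifnot(is.matrix(dark_image))
  if (is.null(sensitivity_image))
    sensitivity_image <- matrix(1, nrow(dark_image), ncol(dark_image))
  if (!identical(dim(dark_image), dim(sensitivity_image)))
    stop("dark and sensitivity images must have the same shape", call. = FALSE)
  if (any(sensitivity_image <= 0))
    stop("sensitivity image must be strictly positive", call. = FALSE)
  if (!is.null(ratio_correction_image)) {
    if (!identical(dim(ratio_correction_image), dim(dark_image)))
      stop("ratio correction image must match the field shape", call. = FALSE)
    if (any(ratio_correction_image <= 0))
      stop("ratio correction image must be strictly positive", call. = FALSE)
  }
  structure(list(dark_image = dark_image,
                 sensitivity_image = sensitivity_image,
                 ratio_correction_image = ratio_correction_image),
            class = "correction_set")
}

#' Apply camera dark/sensitivity corrections to a raw frame
#'
#' Computes `(raw - dark) / sensitivity` elementwise.  Negative results are
#' permitted (they are flagged via the `n_negative` attribute, not clipped):
#' they carry information about read noise downstream.
#'
#' @param raw_frame raw counts matrix.
#' @param corr a [correction_set()].
#' @return corrected frame (matrix) with attribute `n_negative`.
#' @export
apply_camera_corrections <- function(raw_frame, corr) {
  stopifnot(inherits(corr, "correction_set"))
  if (!identical(dim(raw_frame), dim(corr$dark_image)))
    stop("frame shape does not match the correction set", call. = FALSE)
  out <- (raw_frame - corr$dark_image) / corr$sensitivity_image
  attr(out, "n_negative") <- sum(out < 0)
  out
}

## median over each block_size x block_size block; partial blocks at the
## field edge use the median of the available pixels (field is not shrunk)
block_median <- function(img, block_size) {
  nr <- nrow(img); nc <- ncol(img)
  br <- ceiling(nr / block_size); bc <- ceiling(nc / block_size)
  out <- matrix(NA_real_, br, bc)
  for (i in seq_len(br)) {
    r0 <- (i - 1) * block_size + 1; r1 <- min(nr, i * block_size)
    for (j in seq_len(bc)) {
      c0 <- (j - 1) * block_size + 1; c1 <- min(nc, j * block_size)
      v <- img[r0:r1, c0:c1]
      out[i, j] <- stats::median(v, na.rm = TRUE)
    }
  }
  out
}

block_centers <- function(n, block_size) {
  nb <- ceiling(n / block_size)
  starts <- (seq_len(nb) - 1) * block_size + 1
  ends <- pmin(n, seq_len(nb) * block_size)
  (starts + ends) / 2
}

#' Build the empirical ratio-correction image
#'
#' From a stack of per-frame FRET-ratio maps of unstimulated cells imaged at
#' varied positions: (1) per-pixel median of the ratio over the stack using
#' cell pixels only; (2) median over each 24 x 24 pixel block; (3) Gaussian
#' smoothing (sigma = 5, in block units) of the block image, implemented as
#' a Gaussian-weighted local-linear fit so that smooth gradients are not
#' attenuated at the field boundary; (4) smooth (cubic-spline) resizing back
#' to the full field.
#'
#' @param ratio_images list of ratio maps (matrices; values outside cells
#'   may be anything, the masks select the pixels used).
#' @param masks list of logical cell masks, same shapes.
#' @param block_size block edge in pixels (default 24).
#' @param sigma Gaussian sigma in block units (default 5).
#' @param max_uncovered_fraction build fails if more than this fraction of
#'   field pixels is never covered by any mask.
#' @return strictly positive correction image, full field shape.
#' @export
build_ratio_correction <- function(ratio_images, masks, block_size = 24,
                                   sigma = 5, max_uncovered_fraction = 0) {
  stopifnot(length(ratio_images) == length(masks), length(masks) >= 1)
  dim0 <- dim(ratio_images[[1]])
  nr <- dim0[1]; nc <- dim0[2]
  acc <- array(NA_real_, c(nr, nc, length(ratio_images)))
  for (k in seq_along(ratio_images)) {
    if (!identical(dim(ratio_images[[k]]), dim0) ||
        !identical(dim(masks[[k]]), dim0))
      stop("all ratio images and masks must share one shape", call. = FALSE)
    v <- ratio_images[[k]]
    v[!masks[[k]]] <- NA_real_
    acc[, , k] <- v
  }
  med <- apply(acc, c(1, 2), stats::median, na.rm = TRUE)
  uncovered <- mean(is.na(med))
  if (uncovered > max_uncovered_fraction)
    stop(sprintf(paste0("field coverage incomplete: %.1f%% of pixels are ",
                        "never covered by a cell mask"), 100 * uncovered),
         call. = FALSE)
  bm <- block_median(med, block_size)
  sm <- gaussian_local_linear_smooth(bm, sigma)
  out <- spline_upsample(sm, block_centers(nr, block_size),
                         block_centers(nc, block_size), nr, nc)
  if (any(!is.finite(out)) || any(out <= 0))
    stop("ratio correction image is not strictly positive; ",
         "check input coverage and values", call. = FALSE)
  out
}

#' Apply the ratio correction
#'
#' Divides a FRET-ratio image elementwise by the correction image.
#' Undefined (NA) pixels stay undefined.
#'
#' @param ratio_image ratio map (NA outside the cell mask).
#' @param correction strictly positive correction image, same shape.
#' @return corrected ratio map.
#' @export
apply_ratio_correction <- function(ratio_image, correction) {
  if (!identical(dim(ratio_image), dim(correction)))
    stop("ratio image and correction shapes differ", call. = FALSE)
  if (any(correction <= 0))
    stop("correction image must be strictly positive", call. = FALSE)
  ratio_image / correction
}
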