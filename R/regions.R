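# Front/middle/rear region definition, region activity, 1D profiles and
# kymograph assembly.

#' Define front, rear and middle subcellular regions
#'
#' The front edge point is the boundary pixel lying farthest along the
#' movement direction; the front region is the `region_size_px` mask pixels
#' closest (Euclidean) to that point, ties broken lexicographically by
#' (row, col); the rear region likewise from the opposite extreme.  The
#' middle region is a rectangular window (full mask width) around the
#' central third of the cell's axial extent.  If the cell holds fewer than
#' `region_size_px` pixels the whole mask is used, with a warning.
#'
#' @param mask logical cell mask (nonempty).
#' @param movement_direction +1 (up) or -1 (down) along the channel axis.
#' @param region_size_px region size in pixels (default 800).
#' @return object of class `region_set`: logical `front_mask`, `rear_mask`,
#'   `middle_mask`, plus the edge points used.
#' @export
edge_regions <- function(mask, movement_direction, region_size_px = 800) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (movement_direction == 0) stop("zero movement direction", call. = FALSE)
  front_pt <- locate_rear_target(mask, movement_direction, 0)
  rear_pt <- locate_rear_target(mask, movement_direction, 180)
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  size <- min(region_size_px, n)
  if (n < region_size_px)
    warning(sprintf("cell area (%d px) below region size (%d px); using whole mask",
                    n, region_size_px))
  pick <- function(pt) {
    d <- sqrt((px[, 1] - pt["row"])^2 + (px[, 2] - pt["col"])^2)
    sel <- order(d, px[, 1], px[, 2])[seq_len(size)]
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[px[sel, , drop = FALSE]] <- TRUE
    m
  }
  rows_in <- range(px[, 1])
  third <- (rows_in[2] - rows_in[1] + 1) / 3
  mid_rows <- (px[, 1] >= rows_in[1] + third) & (px[, 1] < rows_in[2] + 1 - third)
  middle <- matrix(FALSE, nrow(mask), ncol(mask))
  middle[px[mid_rows, , drop = FALSE]] <- TRUE
  structure(list(front_mask = pick(front_pt), rear_mask = pick(rear_pt),
                 middle_mask = middle, region_size_px = region_size_px,
                 front_point = front_pt, rear_point = rear_pt),
            class = "region_set")
}

## sum of `img` over region, excluding undefined pixels; errors when no
## valid pixel remains
region_sum <- function(img, region, what = "region") {
  ok <- region & !is.na(img)
  if (!any(ok)) stop(what, " has no valid pixels", call. = FALSE)
  sum(img[ok])
}

#' Region activity from a FRET pair (ratio of sums)
#'
#' For each region the activity is the summed acceptor divided by the summed
#' donor over the region's valid pixels (a ratio of sums, not a mean of
#' per-pixel ratios), per the configured orientation.
#'
#' @param donor,acceptor background-subtracted channels (NA outside mask).
#' @param regions an [edge_regions()] result.
#' @param cell_mask logical whole-cell mask.
#' @param config a [polarflip_config()].
#' @return named numeric: `front`, `rear`, `middle`, `whole`.
#' @export
region_activity <- function(donor, acceptor, regions, cell_mask,
                            config = polarflip_config()) {
  stopifnot(inherits(regions, "region_set"))
  flip <- config$fret_orientation == "donor_over_acceptor"
  one <- function(region, what) {
    ok <- region & !is.na(donor) & !is.na(acceptor)
    if (!any(ok)) stop(what, " has no valid pixels", call. = FALSE)
    s_a <- sum(acceptor[ok]); s_d <- sum(donor[ok])
    if (flip) s_d / s_a else s_a / s_d
  }
  c(front = one(regions$front_mask, "front region"),
    rear = one(regions$rear_mask, "rear region"),
    middle = one(regions$middle_mask, "middle region"),
    whole = one(cell_mask, "cell mask"))
}

#' Normalized region signal (single-reporter mode)
#'
#' Fraction of the whole-cell signal found in each region: the region sum
#' divided by the sum over the entire segmented cell body.  Used for the
#' myosin reporter, where relative subcellular distribution is the readout.
#'
#' @param channel background-subtracted reporter channel (NA outside mask;
#'   nonnegative within).
#' @param regions an [edge_regions()] result.
#' @param cell_mask logical whole-cell mask.
#' @return named numeric in `[0, 1]`: `front`, `rear`, `middle`, `whole`.
#' @export
normalized_region_signal <- function(channel, regions, cell_mask) {
  stopifnot(inherits(regions, "region_set"))
  total <- region_sum(channel, cell_mask, "cell mask")
  if (total <= 0) stop("whole-cell signal sum is not positive", call. = FALSE)
  c(front = region_sum(channel, regions$front_mask, "front region") / total,
    rear = region_sum(channel, regions$rear_mask, "rear region") / total,
    middle = region_sum(channel, regions$middle_mask, "middle region") / total,
    whole = 1)
}

#' 1D activity profile along the channel axis
#'
#' For each image row intersecting the mask, the ratio of sums of the two
#' channels (FRET mode) or the mean of the single channel, indexed relative
#' to the centroid row.  Rows interior to the mask with no valid pixel give
#' NA entries.
#'
#' @param donor channel frame (or the only channel in single-channel mode).
#' @param acceptor optional second channel; when given the profile is the
#'   per-row summed-acceptor / summed-donor ratio.
#' @param mask logical cell mask.
#' @param config a [polarflip_config()] (ratio orientation).
#' @return data.frame with `row`, `offset` (row - centroid row) and `value`.
#' @export
profile_1d <- function(donor, acceptor = NULL, mask,
                       config = polarflip_config()) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- which(mask, arr.ind = TRUE)
  centroid_row <- mean(px[, 1])
  rows <- seq(min(px[, 1]), max(px[, 1]))
  flip <- config$fret_orientation == "donor_over_acceptor"
  val <- vapply(rows, function(r) {
    sel <- mask[r, ]
    if (!any(sel)) return(NA_real_)
    if (is.null(acceptor)) {
      v <- donor[r, sel]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else {
      d <- donor[r, sel]; a <- acceptor[r, sel]
      ok <- !is.na(d) & !is.na(a)
      if (!any(ok)) return(NA_real_)
      if (flip) sum(d[ok]) / sum(a[ok]) else sum(a[ok]) / sum(d[ok])
    }
  }, numeric(1))
  data.frame(row = rows, offset = rows - centroid_row, value = val)
}

#' Resample a profile to a fixed length with a cubic smoothing spline
#'
#' Fits a cubic smoothing spline with the convention that smoothing
#' parameter p = 0 gives the least-squares straight line and p = 1 the
#' interpolating spline (implemented as penalty weight `(1 - p) / p` on the
#' integrated squared second derivative), then evaluates it at
#' `target_length` equally spaced points spanning the profile from rear to
#' front.
#'
#' @param x positions of the profile samples (must be ordered rear to
#'   front; >= 4 defined points required).
#' @param y profile values (NAs dropped).
#' @param target_length number of output points.
#' @param smoothing_p smoothing parameter in `[0, 1]` (default 0.5).
#' @return numeric vector of length `target_length` (rear first).
#' @export
normalize_profile <- function(x, y, target_length, smoothing_p = 0.5) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 defined profile points", call. = FALSE)
  if (smoothing_p < 0 || smoothing_p > 1)
    stop("smoothing_p must lie in [0, 1]", call. = FALSE)
  xo <- seq(min(x), max(x), length.out = target_length)
  if (smoothing_p == 0) {
    fit <- stats::lm(y ~ x)
    return(unname(stats::predict(fit, data.frame(x = xo))))
  }
  if (smoothing_p == 1) {
    # total fit: the natural interpolating cubic spline (the lambda -> 0
    # limit of the smoothing spline)
    return(stats::splinefun(x, y, method = "natural")(xo))
  }
  lambda <- (1 - smoothing_p) / smoothing_p
  fit <- stats::smooth.spline(x, y, lambda = lambda, all.knots = TRUE,
                              keep.data = FALSE)
  stats::predict(fit, xo)$y
}

#' Assemble a rear-registered kymograph
#'
#' Averages per-cell length-normalized profiles at every time point.  All
#' profiles must already be resampled to a common length (rear at index 1)
#' and share the stimulation-aligned time axis.
#'
#' @param profiles list over cells; each element a matrix of
#'   `target_length` rows x `n_frames` columns (NA allowed).
#' @param time_s optional shared time axis (length `n_frames`).
#' @return object of class `kymograph`: `matrix` (position x time, rear at
#'   row 1), `n_cells` per column, `time_s`.
#' @export
build_kymograph <- function(profiles, time_s = NULL) {
  stopifnot(length(profiles) >= 1)
  d <- dim(profiles[[1]])
  for (p in profiles) if (!identical(dim(p), d))
    stop("all profiles must be resampled to the same dimensions", call. = FALSE)
  arr <- array(unlist(profiles), c(d[1], d[2], length(profiles)))
  m <- apply(arr, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  n_cells <- vapply(seq_len(d[2]), function(j)
    sum(vapply(profiles, function(p) any(is.finite(p[, j])), logical(1))),
    integer(1))
  if (any(n_cells == 0))
    stop("no cells contribute at time point(s) ",
         paste(which(n_cells == 0), collapse = ", "), call. = FALSE)
  structure(list(matrix = m, n_cells = n_cells, time_s = time_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d positions x %d time points (%d-%d cells/column)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$n_cells), max(x$n_cells)))
  invisible(x)
}

#' @export
#' @importFrom graphics image axis
plot.kymograph <- function(x, ..., xlab = "time (s)",
                           ylab = "position from rear (normalized)") {
  tt <- if (!is.null(x$time_s)) x$time_s else seq_len(ncol(x$matrix))
  image(tt, seq_len(nrow(x$matrix)) / nrow(x$matrix), t(x$matrix),
        xlab = xlab, ylab = ylab, useRaster = TRUE, ...)
  invisible(x)
}
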