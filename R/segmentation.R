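# Background estimation, cell segmentation, ratio computation, per-frame
# linking, kinematics, and the stimulation rear-target geometry.

## Local-median background on a coarse grid: background-seed pixels are the
## low quantile of the summed image (cells are bright); for each grid node
## the median of seed pixels in a window of `window_px` is taken and the
## node values are bilinearly interpolated to the full field.
estimate_background <- function(sum_img, bg_seed, window_px = 64,
                                grid_step = 32) {
  nr <- nrow(sum_img); nc <- ncol(sum_img)
  gr <- unique(pmin(nr, seq(1, nr + grid_step - 1, by = grid_step)))
  gc <- unique(pmin(nc, seq(1, nc + grid_step - 1, by = grid_step)))
  fallback <- stats::median(sum_img[bg_seed])
  if (!is.finite(fallback)) fallback <- stats::median(sum_img)
  node <- matrix(fallback, length(gr), length(gc))
  h <- window_px / 2
  for (i in seq_along(gr)) {
    r0 <- max(1, round(gr[i] - h)); r1 <- min(nr, round(gr[i] + h))
    for (j in seq_along(gc)) {
      c0 <- max(1, round(gc[j] - h)); c1 <- min(nc, round(gc[j] + h))
      sel <- bg_seed[r0:r1, c0:c1]
      if (any(sel)) node[i, j] <- stats::median(sum_img[r0:r1, c0:c1][sel])
    }
  }
  # bilinear interpolation of the node grid to the full field
  interp1 <- function(x, y, xo) stats::approx(x, y, xout = xo, rule = 2)$y
  tmp <- matrix(NA_real_, nr, length(gc))
  for (j in seq_along(gc)) tmp[, j] <- if (length(gr) > 1)
    interp1(gr, node[, j], seq_len(nr)) else rep(node[1, j], nr)
  bg <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) bg[i, ] <- if (length(gc) > 1)
    interp1(gc, tmp[i, ], seq_len(nc)) else rep(tmp[i, 1], nc)
  bg
}

#' Segment one two-channel frame
#'
#' Segmentation runs on the sum of the two (camera-corrected) channels:
#' conservative background/object seeding by quantiles, local-median
#' background subtraction, edge enhancement by subtracting a broad Gaussian
#' blur (sigma = 5) from the image, Otsu binarization of the enhanced image,
#' hole filling and size filtering, keeping the largest object.  The
#' estimated background is subtracted from each channel and pixels outside
#' the mask are set to NA so they drop out of all downstream sums.
#'
#' @param donor,acceptor camera-corrected channel frames (matrices).
#' @param config a [polarflip_config()] (controls seeds quantiles, local
#'   window and minimum object size).
#' @return list with `found` (logical), `mask`, `background`, `donor_bg`,
#'   `acceptor_bg` (background-subtracted channels, NA outside the mask).
#'   When no object passes the size filter, `found = FALSE` and the masks /
#'   channels are NULL.
#' @export
segment_frame <- function(donor, acceptor, config = polarflip_config()) {
  if (!identical(dim(donor), dim(acceptor)))
    stop("donor and acceptor frames must have the same shape", call. = FALSE)
  s <- donor + acceptor
  q <- stats::quantile(s, config$bg_quantiles, names = FALSE)
  bg_seed <- s <= q[1]
  # denoise only when the background is actually noisy: an exactly two-level
  # image (constant background) is thresholded without any blurring
  if (config$pre_smooth_sigma > 0 && stats::mad(s[bg_seed]) > 0) {
    s <- as.matrix(EBImage::gblur(s, sigma = config$pre_smooth_sigma))
    q <- stats::quantile(s, config$bg_quantiles, names = FALSE)
    bg_seed <- s <= q[1]
  }
  bg <- estimate_background(s, bg_seed, window_px = config$bg_window_px)
  s_bg <- s - bg
  enh <- s_bg - as.matrix(EBImage::gblur(s_bg, sigma = 5))
  rng <- range(enh)
  # robust background noise scale, for the object-intensity gate
  noise_sd <- stats::mad(s_bg[bg_seed])
  mask <- NULL
  if (rng[2] > rng[1]) {
    scaled <- (enh - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    cand <- scaled > thr
    cand <- as.matrix(EBImage::fillHull(EBImage::Image(cand))) > 0
    lab <- EBImage::bwlabel(EBImage::Image(cand))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= config$min_object_px)
    # intensity gate: a real cell is far brighter than background noise
    if (length(keep) > 0 && noise_sd > 0)
      keep <- keep[vapply(keep, function(l)
        mean(s_bg[as.integer(lab) == l]) > config$min_object_snr * noise_sd,
        logical(1))]
    if (length(keep) > 0) {
      largest <- keep[which.max(sizes[keep])]
      mask <- matrix(as.integer(lab) == largest, nrow(donor), ncol(donor))
    }
  }
  if (is.null(mask))
    return(list(found = FALSE, mask = NULL, background = bg,
                donor_bg = NULL, acceptor_bg = NULL))
  # per-channel background with the same seed pixels and neighborhood
  bg_d <- estimate_background(donor, bg_seed, window_px = config$bg_window_px)
  bg_a <- estimate_background(acceptor, bg_seed, window_px = config$bg_window_px)
  d <- donor - bg_d; a <- acceptor - bg_a
  d[!mask] <- NA_real_; a[!mask] <- NA_real_
  list(found = TRUE, mask = mask, background = bg, donor_bg = d,
       acceptor_bg = a)
}

#' Compute the FRET ratio image
#'
#' Acceptor divided by donor inside the mask (or the inverse, per the
#' configured orientation); undefined outside the mask and wherever the
#' denominator channel is <= 0.
#'
#' @param donor,acceptor background-subtracted channels.
#' @param mask logical cell mask (nonempty).
#' @param config a [polarflip_config()]; `fret_orientation` selects the
#'   ratio orientation.
#' @return ratio map (NA where undefined).
#' @export
compute_ratio_image <- function(donor, acceptor, mask,
                                config = polarflip_config()) {
  if (!identical(dim(donor), dim(acceptor)) || !identical(dim(donor), dim(mask)))
    stop("donor, acceptor and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (config$fret_orientation == "acceptor_over_donor") {
    num <- acceptor; den <- donor
  } else {
    num <- donor; den <- acceptor
  }
  out <- matrix(NA_real_, nrow(donor), ncol(donor))
  ok <- mask & !is.na(den) & !is.na(num) & (den > 0)
  out[ok] <- num[ok] / den[ok]
  out
}

## observation summary of one mask
mask_observation <- function(mask, frame_index) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  cr <- mean(px[, 1]); cc <- mean(px[, 2])
  # equivalent-ellipse major axis from second moments (+1/12 pixelation term)
  vr <- mean((px[, 1] - cr)^2) + 1 / 12
  vc <- mean((px[, 2] - cc)^2) + 1 / 12
  vrc <- mean((px[, 1] - cr) * (px[, 2] - cc))
  lam <- (vr + vc) / 2 + sqrt(((vr - vc) / 2)^2 + vrc^2)
  list(frame_index = frame_index, mask = mask,
       centroid = c(row = cr, col = cc), area_px = n,
       major_axis_px = 4 * sqrt(lam))
}

#' Link per-frame masks into a single-cell track
#'
#' One cell per channel: consecutive detections are linked when their masks
#' overlap; gaps of at most one missing frame are bridged.  If the overlap
#' chain breaks, the longest contiguous segment is kept with a warning.
#' When a frame holds several objects the caller (see [segment_frame()])
#' has already kept the largest.
#'
#' @param masks list over frames of logical masks (`NULL` for frames with
#'   no detection).
#' @param time_s optional vector of frame times (seconds).
#' @return object of class `cell_track`: observations, skipped frames, and
#'   the frame range retained.
#' @export
link_track <- function(masks, time_s = NULL) {
  det <- which(!vapply(masks, is.null, logical(1)))
  if (length(det) < 2) stop("need detections in at least 2 frames", call. = FALSE)
  segs <- list(); cur <- det[1]
  for (k in seq_along(det)[-1]) {
    i_prev <- cur[length(cur)]; i <- det[k]
    gap_ok <- (i - i_prev) <= 2             # bridge at most one skipped frame
    ovl <- gap_ok && sum(masks[[i_prev]] & masks[[i]]) > 0
    if (ovl) cur <- c(cur, i)
    else { segs[[length(segs) + 1]] <- cur; cur <- i }
  }
  segs[[length(segs) + 1]] <- cur
  if (length(segs) > 1) {
    warning("track split at zero-overlap link(s); keeping the longest segment")
  }
  seg <- segs[[which.max(vapply(segs, length, integer(1)))]]
  obs <- lapply(seg, function(i) mask_observation(masks[[i]], i))
  skipped <- setdiff(seq(min(seg), max(seg)), seg)
  structure(list(observations = obs, frames = seg, skipped_frames = skipped,
                 time_s = if (!is.null(time_s)) time_s[seg] else NULL,
                 n_segments = length(segs)),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("cell_track: %d observations (frames %d..%d, %d skipped)\n",
              length(x$observations), min(x$frames), max(x$frames),
              length(x$skipped_frames)))
  invisible(x)
}

## majority sign of the channel-axis displacement over the last `k` steps;
## axis is oriented "up" (+1 = decreasing row index)
movement_sign_at <- function(rows, i, k = 3) {
  i0 <- max(2, i - k + 1)
  d <- sign(-(rows[i0:i] - rows[(i0:i) - 1]))
  d <- d[d != 0]
  if (length(d) == 0) 0 else sign(sum(d))
}

#' Per-frame kinematics of a tracked cell
#'
#' Raw centroid speed between consecutive frames, loess-smoothed speed
#' (local quadratic regression, span 10 % of the trace by default), signed
#' channel-axis velocity oriented so the pre-stimulus direction is positive,
#' and relative length/area normalized to the reference (stimulation-onset)
#' frame.
#'
#' @param track a [link_track()] result.
#' @param config a [polarflip_config()] (frame interval, pixel size, span).
#' @param reference_frame frame index used for rel_length / rel_area and for
#'   the pre-stimulus direction (default: the frame at t = 0 if the track
#'   has times, else the first frame).
#' @return the track with an added data.frame `kinematics`: columns frame,
#'   time_s, centroid_row, centroid_col, speed_um_s, speed_smoothed,
#'   signed_velocity_um_s, area_px, major_axis_px, rel_length, rel_area,
#'   movement_sign; plus `direction0` (+1 = up).
#' @export
compute_kinematics <- function(track, config = polarflip_config(),
                               reference_frame = NULL) {
  stopifnot(inherits(track, "cell_track"))
  obs <- track$observations
  n <- length(obs)
  if (n < 3) stop("track too short for kinematics (need >= 3 frames)",
                  call. = FALSE)
  dt <- config$frame_interval_s; px <- config$pixel_size_um
  frames <- vapply(obs, `[[`, integer(1), "frame_index")
  rows <- vapply(obs, function(o) o$centroid["row"], numeric(1))
  cols <- vapply(obs, function(o) o$centroid["col"], numeric(1))
  time_s <- if (!is.null(track$time_s)) track$time_s else (frames - frames[1]) * dt
  step_dt <- c(NA, diff(frames)) * dt
  disp_px <- c(NA, sqrt(diff(rows)^2 + diff(cols)^2))
  speed <- disp_px * px / step_dt
  ok <- !is.na(speed)
  sm <- rep(NA_real_, n)
  if (sum(ok) >= 8) {
    span <- max(config$loess_span, 6 / sum(ok))  # >= 6 points for a stable local quadratic
    fit <- stats::loess(speed[ok] ~ time_s[ok], span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    sm[ok] <- stats::fitted(fit)
  } else sm[ok] <- speed[ok]
  if (is.null(reference_frame)) {
    reference_frame <- if (!is.null(track$time_s) && any(track$time_s == 0))
      frames[which(track$time_s == 0)] else frames[1]
  }
  iref <- which(frames == reference_frame)
  if (length(iref) != 1)
    stop("reference frame not part of the track", call. = FALSE)
  msign <- vapply(seq_len(n), function(i) movement_sign_at(rows, i), numeric(1))
  # original direction: majority movement sign up to the reference frame
  pre <- msign[2:max(2, iref)]
  direction0 <- if (sum(pre > 0) >= sum(pre < 0)) 1 else -1
  vel_axis <- c(NA, -diff(rows)) * px / step_dt      # + = up
  signed_vel <- vel_axis * direction0                # + = original direction
  sv_sm <- rep(NA_real_, n)
  if (sum(ok) >= 8) {
    span <- max(config$loess_span, 6 / sum(ok))  # >= 6 points for a stable local quadratic
    fit2 <- stats::loess(signed_vel[ok] ~ time_s[ok], span = span, degree = 2,
                         family = "gaussian",
                         control = stats::loess.control(surface = "direct"))
    sv_sm[ok] <- stats::fitted(fit2)
  } else sv_sm[ok] <- signed_vel[ok]
  len <- vapply(obs, `[[`, numeric(1), "major_axis_px")
  area <- vapply(obs, `[[`, numeric(1), "area_px")
  kin <- data.frame(frame = frames, time_s = time_s,
                    centroid_row = rows, centroid_col = cols,
                    speed_um_s = speed, speed_smoothed = sm,
                    signed_velocity_um_s = signed_vel,
                    signed_velocity_smoothed = sv_sm,
                    area_px = area, major_axis_px = len,
                    rel_length = len / len[iref], rel_area = area / area[iref],
                    movement_sign = msign)
  track$kinematics <- kin
  track$direction0 <- direction0
  track$reference_frame <- reference_frame
  track
}

#' Locate the stimulation target on the cell perimeter
#'
#' Finds the boundary pixel lying at `target_angle_deg` from the movement
#' direction, as seen from the centroid (180 deg = the cell rear).
#' Deterministic tie-break: larger centroid distance, then smaller row,
#' then smaller column.
#'
#' @param mask logical cell mask (nonempty).
#' @param movement_direction +1 (up, decreasing rows) or -1 (down); a
#'   two-vector `c(drow, dcol)` is also accepted.  Zero direction is an
#'   error (callers fall back to the previous frame's direction).
#' @param target_angle_deg angle from the movement direction, degrees.
#' @return named vector `c(row, col)` of the target pixel.
#' @export
locate_rear_target <- function(mask, movement_direction,
                               target_angle_deg = 180) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (length(movement_direction) == 1) {
    if (movement_direction == 0)
      stop("zero movement direction: no previous direction available",
           call. = FALSE)
    dirv <- c(-sign(movement_direction), 0)  # +1 = up = decreasing row
  } else {
    if (all(movement_direction == 0))
      stop("zero movement direction: no previous direction available",
           call. = FALSE)
    dirv <- movement_direction / sqrt(sum(movement_direction^2))
  }
  th <- target_angle_deg * pi / 180
  # rotate the direction vector by the target angle (row/col coordinates)
  u <- c(cos(th) * dirv[1] - sin(th) * dirv[2],
         sin(th) * dirv[1] + cos(th) * dirv[2])
  px <- which(mask, arr.ind = TRUE)
  cr <- mean(px[, 1]); cc <- mean(px[, 2])
  # boundary = mask pixels with a non-mask 4-neighbor (or at the field edge)
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2); padded[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- padded[1:nr, 2:(nc + 1)] & padded[3:(nr + 2), 2:(nc + 1)] &
    padded[2:(nr + 1), 1:nc] & padded[2:(nr + 1), 3:(nc + 2)]
  bnd <- which(mask & !interior, arr.ind = TRUE)
  v <- cbind(bnd[, 1] - cr, bnd[, 2] - cc)
  d <- sqrt(rowSums(v^2))
  cosang <- (v[, 1] * u[1] + v[, 2] * u[2]) / pmax(d, .Machine$double.eps)
  ord <- order(-cosang, -d, bnd[, 1], bnd[, 2])
  c(row = unname(bnd[ord[1], 1]), col = unname(bnd[ord[1], 2]))
}
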