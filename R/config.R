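#' Analysis configuration
#'
#' Builds the configuration object used throughout the pipeline.  Defaults
#' are the acquisition and analysis constants of the channel-migration
#' stimulation assays: 3 s frame interval, 0.21 um pixels, 800-pixel
#' front/rear regions, a 6-frame (15 s) pre-stimulus baseline, a 1 %
#' rise/decay threshold for event onsets, a 2 % rear-rise and 0.03
#' activity-unit front-engagement threshold for response stratification,
#' and the four center-stimulation windows Control1 = [-60, -42] s,
#' Control2 = [-39, -21] s, Control3 = [-18, 0] s plus a peak window of
#' half-width 9 s centered on the activity maximum in [3, 33] s.
#'
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param pixel_size_um pixel size in micrometers (> 0).
#' @param region_size_px number of pixels in each front/rear region.
#' @param baseline_window_frames pre-stimulus frames averaged for the
#'   classification baseline.
#' @param event_rise_fraction relative rise (rear) / decay (front) marking an
#'   event onset, as a fraction of the t = 0 value.
#' @param class_rear_rise_fraction relative rear rise separating
#'   no-response from responding cells.
#' @param front_engagement_gap activity-unit gap `min(front) - max(rear)`
#'   above which the front is called unengaged.
#' @param windows named list of time windows (seconds relative to the first
#'   stimulation pulse): `control1`, `control2`, `control3` (length-2
#'   vectors), `peak_search` (length-2) and `peak_halfwidth` (scalar).
#' @param fret_orientation `"acceptor_over_donor"` (default) or
#'   `"donor_over_acceptor"`; which ratio is reported as activity.
#' @param min_object_px minimum segmented object size in pixels.
#' @param pre_smooth_sigma Gaussian sigma (pixels) of the mild denoising
#'   applied to the summed image before enhancement/thresholding (0 = off).
#' @param min_object_snr candidate objects whose mean background-subtracted
#'   intensity is below this multiple of the background noise (robust MAD)
#'   are rejected; guards against noise-only frames.
#' @param bg_quantiles length-2 vector of quantiles on the summed image that
#'   conservatively seed background and object pixels.
#' @param bg_window_px local neighborhood (pixels) for the median background.
#' @param loess_span loess span, as a fraction of trace length, for speed
#'   smoothing.
#' @param smoothing_p cubic smoothing-spline parameter in `[0, 1]`
#'   (0 = straight line, 1 = interpolating spline) for profile resampling.
#' @param target_angle_deg stimulation target angle relative to the movement
#'   direction (180 = cell rear).
#' @param ratio_correction optional path to a ratio-correction image (TIFF);
#'   `NULL` disables the stage (not needed for myosin imaging).
#' @param speed_only_classification logical; classify using migration
#'   criteria only (myosin line without an activity sensor).
#' @return object of class `polarflip_config` (a validated named list).
#' @seealso [validate_config()] to build one from a YAML file.
#' @export
polarflip_config <- function(frame_interval_s = 3,
                             pixel_size_um = 0.21,
                             region_size_px = 800,
                             baseline_window_frames = 6,
                             event_rise_fraction = 0.01,
                             class_rear_rise_fraction = 0.02,
                             front_engagement_gap = 0.03,
                             windows = list(control1 = c(-60, -42),
                                            control2 = c(-39, -21),
                                            control3 = c(-18, 0),
                                            peak_search = c(3, 33),
                                            peak_halfwidth = 9),
                             fret_orientation = c("acceptor_over_donor",
                                                  "donor_over_acceptor"),
                             min_object_px = 200,
                             pre_smooth_sigma = 1,
                             min_object_snr = 5,
                             bg_quantiles = c(0.25, 0.99),
                             bg_window_px = 64,
                             loess_span = 0.1,
                             smoothing_p = 0.5,
                             target_angle_deg = 180,
                             ratio_correction = NULL,
                             speed_only_classification = FALSE) {
  fret_orientation <- match.arg(fret_orientation)
  cfg <- list(frame_interval_s = frame_interval_s,
              pixel_size_um = pixel_size_um,
              region_size_px = region_size_px,
              baseline_window_frames = baseline_window_frames,
              event_rise_fraction = event_rise_fraction,
              class_rear_rise_fraction = class_rear_rise_fraction,
              front_engagement_gap = front_engagement_gap,
              windows = windows,
              fret_orientation = fret_orientation,
              min_object_px = min_object_px,
              pre_smooth_sigma = pre_smooth_sigma,
              min_object_snr = min_object_snr,
              bg_quantiles = bg_quantiles,
              bg_window_px = bg_window_px,
              loess_span = loess_span,
              smoothing_p = smoothing_p,
              target_angle_deg = target_angle_deg,
              ratio_correction = ratio_correction,
              speed_only_classification = speed_only_classification)
  check_config(cfg)
  structure(cfg, class = "polarflip_config")
}

check_config <- function(cfg) {
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("config field '%s' must be a single positive number", field),
           call. = FALSE)
  }
  for (f in c("frame_interval_s", "pixel_size_um", "region_size_px",
              "baseline_window_frames", "event_rise_fraction",
              "class_rear_rise_fraction", "front_engagement_gap",
              "min_object_px", "bg_window_px", "loess_span", "min_object_snr"))
    num_pos(f)
  if (!is.numeric(cfg$pre_smooth_sigma) || cfg$pre_smooth_sigma < 0)
    stop("config field 'pre_smooth_sigma' must be >= 0", call. = FALSE)
  if (cfg$smoothing_p < 0 || cfg$smoothing_p > 1)
    stop("config field 'smoothing_p' must lie in [0, 1]", call. = FALSE)
  q <- cfg$bg_quantiles
  if (length(q) != 2 || any(q <= 0) || any(q >= 1) || q[1] >= q[2])
    stop("config field 'bg_quantiles' must be two increasing values in (0, 1)",
         call. = FALSE)
  w <- cfg$windows
  need <- c("control1", "control2", "control3", "peak_search", "peak_halfwidth")
  if (!all(need %in% names(w)))
    stop("config field 'windows' must name ", paste(need, collapse = ", "),
         call. = FALSE)
  ivs <- w[c("control1", "control2", "control3", "peak_search")]
  for (nm in names(ivs)) {
    v <- ivs[[nm]]
    if (length(v) != 2 || v[1] >= v[2])
      stop(sprintf("window '%s' must be an increasing [start, end] pair", nm),
           call. = FALSE)
  }
  if (w$peak_halfwidth <= 0) stop("'peak_halfwidth' must be positive", call. = FALSE)
  ctr <- ivs[c("control1", "control2", "control3")]
  for (i in 1:2) for (j in (i + 1):3) {
    a <- ctr[[i]]; b <- ctr[[j]]
    if (a[2] > b[1] && b[2] > a[1])
      stop(sprintf("windows '%s' and '%s' overlap", names(ctr)[i], names(ctr)[j]),
           call. = FALSE)
  }
  if (!(ctr$control1[2] <= ctr$control2[1] && ctr$control2[2] <= ctr$control3[1]))
    stop("control windows must be time-ordered control1 < control2 < control3",
         call. = FALSE)
  invisible(cfg)
}

#' Read and validate an analysis configuration file
#'
#' Reads a YAML file, fills in the package defaults for any key it does not
#' set (an empty file yields the full defaults) and rejects unknown keys and
#' out-of-range values.
#'
#' @param path path to a YAML file, or `NULL`/missing for pure defaults.
#' @return a validated [polarflip_config()] object.
#' @export
validate_config <- function(path = NULL) {
  defaults <- polarflip_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config file must contain a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(unclass(defaults)))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- unclass(defaults)
  for (nm in names(user)) {
    v <- user[[nm]]
    if (nm == "windows") {
      for (wn in names(v)) cfg$windows[[wn]] <- unlist(v[[wn]])
    } else if (is.list(v)) cfg[[nm]] <- v
    else cfg[[nm]] <- unlist(v)
  }
  check_config(cfg)
  structure(cfg, class = "polarflip_config")
}

#' @export
print.polarflip_config <- function(x, ...) {
  cat("polarflip analysis configuration\n")
  cat(sprintf("  frame interval: %g s, pixel size: %g um\n",
              x$frame_interval_s, x$pixel_size_um))
  cat(sprintf("  front/rear region size: %d px, baseline: %d frames\n",
              as.integer(x$region_size_px), as.integer(x$baseline_window_frames)))
  cat(sprintf("  thresholds: event %.3g, rear rise %.3g, engagement gap %.3g\n",
              x$event_rise_fraction, x$class_rear_rise_fraction,
              x$front_engagement_gap))
  cat(sprintf("  ratio orientation: %s\n", x$fret_orientation))
  invisible(x)
}
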