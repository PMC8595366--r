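# Event-order detection, response stratification, and the
# center-stimulation responder statistic.

## First linear-interpolated crossing of `y` through `thr` at t >= 0, in the
## given direction ("up": from below to >= thr; "down": reverse).  A crossing
## must persist at the sample after the bracketing pair (when one exists):
## this debounces single-sample noise spikes and leaves monotone
## piecewise-linear traces exact.
first_crossing <- function(time_s, y, thr, direction = c("up", "down")) {
  direction <- match.arg(direction)
  n <- length(y)
  post <- which(time_s >= 0)
  for (k in post[-length(post)]) {
    y0 <- y[k]; y1 <- y[k + 1]
    if (is.na(y0) || is.na(y1)) next
    beyond <- function(v) if (direction == "up") v >= thr else v <= thr
    if (!beyond(y1) || beyond(y0)) next
    if (k + 2 <= n && !is.na(y[k + 2]) && !beyond(y[k + 2])) next
    return(interp_crossing(time_s[k], time_s[k + 1], y0, y1, thr))
  }
  NA_real_
}

#' Detect the order-of-events timings
#'
#' From stimulation-aligned front/rear activity traces and the signed
#' channel-axis velocity: the rear response is the first post-stimulus time
#' the rear activity exceeds a 1 % rise over its t = 0 value, the front
#' response the first 1 % decay of the front below its t = 0 value, cell
#' stalling the first zero crossing of the signed velocity, and the
#' cross-point the first intersection of the front and rear traces.  All
#' times are linearly interpolated between the bracketing samples;
#' undetected events are NA.
#'
#' @param time_s time grid (seconds; must contain a sample at t = 0, the
#'   stimulation onset).
#' @param front,rear region activity traces on that grid.
#' @param velocity signed channel-axis velocity (+ = original direction).
#' @param config a [polarflip_config()] (`event_rise_fraction`).
#' @return object of class `event_timing` with `t_rear_response_s`,
#'   `t_front_response_s`, `t_stall_s`, `t_crosspoint_s`.
#' @export
detect_events <- function(time_s, front, rear, velocity,
                          config = polarflip_config()) {
  n <- length(time_s)
  if (length(front) != n || length(rear) != n || length(velocity) != n)
    stop("traces must share one time grid", call. = FALSE)
  i0 <- which(abs(time_s) < 1e-9)
  if (length(i0) != 1)
    stop("traces must contain exactly one sample at t = 0", call. = FALSE)
  ef <- config$event_rise_fraction
  t_rear <- first_crossing(time_s, rear, rear[i0] * (1 + ef), "up")
  t_front <- first_crossing(time_s, front, front[i0] * (1 - ef), "down")
  t_stall <- first_crossing(time_s, velocity, 0, "down")
  t_cross <- first_crossing(time_s, front - rear, 0, "down")
  structure(list(t_rear_response_s = t_rear, t_front_response_s = t_front,
                 t_stall_s = t_stall, t_crosspoint_s = t_cross),
            class = "event_timing")
}

#' @export
print.event_timing <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not detected" else sprintf("%.2f s", v)
  cat("event timing (post-stimulation):\n")
  cat("  rear response: ", fmt(x$t_rear_response_s), "\n")
  cat("  front response:", fmt(x$t_front_response_s), "\n")
  cat("  stall:         ", fmt(x$t_stall_s), "\n")
  cat("  cross-point:   ", fmt(x$t_crosspoint_s), "\n")
  invisible(x)
}

## mean over the `k` samples strictly before t = 0
baseline_mean <- function(time_s, y, k) {
  pre <- which(time_s < 0)
  if (length(pre) < k) stop("insufficient pre-stimulus history: need ",
                            k, " frames", call. = FALSE)
  mean(y[utils::tail(pre, k)])
}

## mean over the final `window_s` seconds of the trace
final_window_mean <- function(time_s, y, window_s = 15) {
  sel <- time_s >= max(time_s) - window_s
  mean(y[sel], na.rm = TRUE)
}

#' Classify the transient-stimulation response
#'
#' Decision cascade over the post-stimulus traces, relative to the 15 s
#' (6-frame) pre-stimulus baseline: (1) maximal rear rise < 2 % ->
#' `no_response`; (2) rear rise >= 2 % but the front stays disengaged
#' (minimum front activity minus maximum rear activity > 0.03) -> `medium`;
#' otherwise both edges engaged: (3) `reversed` when the migration direction
#' and the front/rear activity ordering are both flipped over the final
#' 15 s of the trace, (4) else `strong` (typically a transient direction
#' flip that reverts).  The computed quantities are retained as evidence.
#'
#' @param time_s,front,rear stimulation-aligned traces (sample at t = 0).
#' @param velocity signed channel-axis velocity (+ = original direction).
#' @param config a [polarflip_config()].
#' @return object of class `response_label` with `transient_class` and an
#'   `evidence` list.
#' @export
classify_transient <- function(time_s, front, rear, velocity,
                               config = polarflip_config()) {
  base_rear <- baseline_mean(time_s, rear, config$baseline_window_frames)
  post <- time_s >= 0
  rise <- max(rear[post], na.rm = TRUE) / base_rear - 1
  gap <- min(front[post], na.rm = TRUE) - max(rear[post], na.rm = TRUE)
  dir_end <- final_window_mean(time_s, velocity)
  act_flip <- final_window_mean(time_s, rear) > final_window_mean(time_s, front)
  cls <- if (rise < config$class_rear_rise_fraction) "no_response"
    else if (gap > config$front_engagement_gap) "medium"
    else if (dir_end < 0 && act_flip) "reversed"
    else "strong"
  structure(list(transient_class = cls,
                 evidence = list(rear_rise = rise, engagement_gap = gap,
                                 final_velocity_um_s = dir_end,
                                 activity_axis_flipped = act_flip,
                                 rear_baseline = base_rear)),
            class = "response_label")
}

#' Classify the persistent-stimulation response
#'
#' A cell is a `reverser` iff, over the final 15 s of the trace, its
#' movement direction is opposite to the pre-stimulus direction AND its
#' front/rear activity ordering has flipped.  If the magnitude of the net
#' post-stimulus displacement is below one cell length the terminal
#' direction is ambiguous and the cell is labeled `non_reverser` with a
#' warning.  With `speed_only_classification` (myosin line without an
#' activity sensor) the activity criterion is skipped.
#'
#' @param time_s,front,rear,velocity as in [classify_transient()].
#' @param cell_length_um mean cell length, micrometers (for the net
#'   displacement guard); `NULL` skips the guard.
#' @param config a [polarflip_config()].
#' @return object of class `response_label` with `persistent_class`.
#' @export
classify_persistent <- function(time_s, front, rear, velocity,
                                cell_length_um = NULL,
                                config = polarflip_config()) {
  post <- which(time_s >= 0)
  dt <- c(diff(time_s), 0)
  net_disp <- sum(velocity[post] * dt[post], na.rm = TRUE)
  ambiguous <- !is.null(cell_length_um) && abs(net_disp) < cell_length_um
  dir_flip <- final_window_mean(time_s, velocity) < 0
  act_flip <- if (config$speed_only_classification) TRUE
              else final_window_mean(time_s, rear) > final_window_mean(time_s, front)
  cls <- if (dir_flip && act_flip && !ambiguous) "reverser" else "non_reverser"
  if (ambiguous && dir_flip && act_flip)
    warning("terminal direction ambiguous (net displacement below one cell ",
            "length); labeling non_reverser")
  structure(list(persistent_class = cls,
                 evidence = list(net_displacement_um = net_disp,
                                 direction_flipped = dir_flip,
                                 activity_axis_flipped = act_flip)),
            class = "response_label")
}

#' @export
print.response_label <- function(x, ...) {
  if (!is.null(x$transient_class))
    cat("response class (transient):", x$transient_class, "\n")
  if (!is.null(x$persistent_class))
    cat("response class (persistent):", x$persistent_class, "\n")
  ev <- x$evidence
  for (nm in names(ev))
    cat(sprintf("  %s: %s\n", nm, format(ev[[nm]], digits = 4)))
  invisible(x)
}

#' Center-stimulation window response
#'
#' Computes the whole-cell activity means in the three control windows and
#' the peak window (half-width 9 s, centered on the activity maximum in
#' [3, 33] s), then the control response mean(Control2)/mean(Control1) and
#' the peak response mean(Peak)/mean(Control3).
#'
#' @param time_s time grid covering at least [-60, +42] s.
#' @param whole whole-cell activity trace.
#' @param config a [polarflip_config()] (window definitions).
#' @return object of class `center_stim_result`: `control_response`,
#'   `peak_response`, `peak_time_s`, `window_means`.
#' @export
center_stim_response <- function(time_s, whole, config = polarflip_config()) {
  w <- config$windows
  need <- c(w$control1[1], w$peak_search[2] + w$peak_halfwidth)
  if (min(time_s) > need[1] || max(time_s) < need[2])
    stop(sprintf("trace must cover [%g, %g] s around stimulation onset",
                 need[1], need[2]), call. = FALSE)
  wmean <- function(iv) {
    sel <- time_s >= iv[1] & time_s <= iv[2]
    mean(whole[sel], na.rm = TRUE)
  }
  m1 <- wmean(w$control1); m2 <- wmean(w$control2); m3 <- wmean(w$control3)
  search <- which(time_s >= w$peak_search[1] & time_s <= w$peak_search[2])
  ipk <- search[which.max(whole[search])]
  peak_time <- time_s[ipk]
  mp <- wmean(c(peak_time - w$peak_halfwidth, peak_time + w$peak_halfwidth))
  structure(list(control_response = m2 / m1, peak_response = mp / m3,
                 peak_time_s = peak_time,
                 window_means = c(control1 = m1, control2 = m2,
                                  control3 = m3, peak = mp)),
            class = "center_stim_result")
}

#' @export
print.center_stim_result <- function(x, ...) {
  cat(sprintf("center stimulation: control response %.4f, peak response %.4f (peak at %g s)\n",
              x$control_response, x$peak_response, x$peak_time_s))
  invisible(x)
}

#' Estimate the responder fraction of a center-stimulation cohort
#'
#' Median-symmetry estimate: the control-response distribution is symmetric
#' about its median m, so half of the inherently non-responding cells are
#' expected to fall below m in the peak-response distribution;
#' `1 - 2 P(peak < m)` then estimates the responder fraction.  The
#' stringent lower bound counts cells whose peak response exceeds the 95th
#' percentile of the control responses.  Both thresholds are cohort-derived
#' and reported.
#'
#' @param results list of [center_stim_response()] results (>= 20 cells).
#' @return object of class `responder_fraction`: `f_median`, `f_stringent`,
#'   `median_threshold`, `stringent_threshold`, `n`.
#' @export
estimate_responder_fraction <- function(results) {
  stopifnot(length(results) >= 20)
  ctrl <- vapply(results, function(r) r$control_response, numeric(1))
  peak <- vapply(results, function(r) r$peak_response, numeric(1))
  if (stats::sd(ctrl) == 0)
    stop("degenerate control distribution (zero spread)", call. = FALSE)
  m <- stats::median(ctrl)
  t95 <- unname(stats::quantile(ctrl, 0.95))
  f_median <- min(1, max(0, 1 - 2 * mean(peak < m)))
  f_stringent <- min(1, max(0, mean(peak > t95)))
  structure(list(f_median = f_median, f_stringent = f_stringent,
                 median_threshold = m, stringent_threshold = t95,
                 n = length(results)),
            class = "responder_fraction")
}

#' @export
print.responder_fraction <- function(x, ...) {
  cat(sprintf("responder fraction (n = %d):\n", x$n))
  cat(sprintf("  median-symmetry estimate: %.3f (threshold %.4f)\n",
              x$f_median, x$median_threshold))
  cat(sprintf("  stringent lower bound:    %.3f (threshold %.4f)\n",
              x$f_stringent, x$stringent_threshold))
  invisible(x)
}
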