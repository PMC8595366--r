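# Dataset layout and TIFF/JSON/CSV input-output.
#
# Layout: one directory per cell holding `donor.tif` + `acceptor.tif` (FRET
# mode) or `myosin.tif` + `cyto.tif`, plus `meta.json` with acquisition
# metadata and the stimulation log.  TIFF pages are 32-bit float; because
# float TIFF storage is only portable inside [0, 1], values are stored
# divided by a full-scale constant recorded in the sidecar (65535 counts
# for channel data, 8 for ratio/correction images).

CHANNEL_FULL_SCALE <- 65535
RATIO_FULL_SCALE <- 8

write_stack_tiff <- function(frames, path, full_scale = CHANNEL_FULL_SCALE) {
  if (!is.list(frames)) frames <- list(frames)
  pages <- lapply(frames, function(m) {
    m[!is.finite(m)] <- 0
    m <- m / full_scale
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

read_stack_tiff <- function(path, full_scale = CHANNEL_FULL_SCALE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) m * full_scale)
}

#' Write a ratio-correction image as 32-bit float TIFF
#'
#' @param correction strictly positive matrix (values must stay below the
#'   recorded full scale of 8).
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_correction_tiff <- function(correction, path) {
  stopifnot(all(correction > 0), all(correction < RATIO_FULL_SCALE))
  write_stack_tiff(list(correction), path, full_scale = RATIO_FULL_SCALE)
}

#' Read a ratio-correction image written by [write_correction_tiff()]
#' @param path TIFF path.
#' @return matrix.
#' @export
read_correction_tiff <- function(path) {
  read_stack_tiff(path, full_scale = RATIO_FULL_SCALE)[[1]]
}

#' Write a synthetic scene to a per-cell dataset directory
#'
#' Writes one multi-page TIFF per channel, a `meta.json` sidecar
#' (acquisition parameters, stimulation log, storage scale, ground-truth
#' class) and a `truth_events.csv` with the configured event schedule.
#'
#' @param scene a rendered [simulate_scene()] result.
#' @param dir output directory (created).
#' @param write_truth_masks also write the ground-truth masks (8-bit TIFF).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, write_truth_masks = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"), !is.null(scene$frames))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- scene$frames
  ch_files <- paste0(fs$ch_names, ".tif")
  write_stack_tiff(fs$ch1, file.path(dir, ch_files[1]))
  write_stack_tiff(fs$ch2, file.path(dir, ch_files[2]))
  if (write_truth_masks) {
    pages <- lapply(scene$track$masks, function(m) m * 1)
    tiff::writeTIFF(pages, file.path(dir, "truth_masks.tif"),
                    bits.per.sample = 8L)
  }
  acq <- fs$acq
  kin <- scene$kinetics
  meta <- list(
    channels = as.list(ch_files), channel_names = as.list(fs$ch_names),
    mode = fs$mode,
    frame_interval_s = acq$frame_interval_s,
    pixel_size_um = acq$pixel_size_um,
    field_shape = acq$field_shape,
    dark_offset = acq$dark_offset,
    channel_full_scale = CHANNEL_FULL_SCALE,
    stim_frame = fs$stim_frame,
    assay = if (length(fs$stim_log$frame) > 0 &&
                max(fs$stim_log$frame) >= length(fs$ch1)) "persistent"
            else "transient",
    stim_log = fs$stim_log,
    seed = scene$seed,
    truth_class = scene$class_label)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  truth <- data.frame(event = c("rear_response", "front_response", "stall",
                                "crosspoint"),
                      time_s = c(kin$rear_rise_onset_s, kin$front_decay_onset_s,
                                 kin$stall_time_s, kin$crosspoint_time_s))
  utils::write.csv(truth, file.path(dir, "truth_events.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a per-cell dataset directory into a frame stack
#'
#' @param dir directory written by [write_scene()] (or laid out the same
#'   way by an acquisition export).
#' @return object of class `frame_stack`.
#' @export
read_frame_stack <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in meta$channels)
    if (!file.exists(file.path(dir, f)))
      stop("missing channel file ", f, " in ", dir, call. = FALSE)
  scale <- if (!is.null(meta$channel_full_scale)) meta$channel_full_scale
           else CHANNEL_FULL_SCALE
  ch1 <- read_stack_tiff(file.path(dir, meta$channels[[1]]), scale)
  ch2 <- read_stack_tiff(file.path(dir, meta$channels[[2]]), scale)
  if (length(ch1) != length(ch2))
    stop("channel stacks have different lengths in ", dir, call. = FALSE)
  n <- length(ch1)
  acq <- acquisition_params(frame_interval_s = meta$frame_interval_s,
                            pixel_size_um = meta$pixel_size_um,
                            field_shape = meta$field_shape,
                            dark_offset = meta$dark_offset)
  time_s <- (seq_len(n) - meta$stim_frame) * meta$frame_interval_s
  structure(list(ch1 = ch1, ch2 = ch2,
                 ch_names = unlist(meta$channel_names),
                 mode = meta$mode, time_s = time_s,
                 stim_frame = meta$stim_frame,
                 stim_log = as.data.frame(meta$stim_log),
                 acq = acq, seed = meta$seed,
                 assay = if (is.null(meta$assay)) "persistent" else meta$assay,
                 truth_class = meta$truth_class),
            class = "frame_stack")
}
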