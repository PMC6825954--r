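# Readers and writers for the open interchange formats: PNG/TIFF frame
# sequences, paw-log CSV, gait-table CSV, run-result JSON.

PAW_LABELS <- c("RF", "LF", "RH", "LH")

# left/right column pairs of the raw gait table and the averaged slot each
# pair feeds; body speed is carried as one column per paw.
GAIT_SIDED_COLS <- list(
  stride_front = c("stride_front_left", "stride_front_right"),
  stride_hind = c("stride_hind_left", "stride_hind_right"),
  stand_front = c("stand_front_left", "stand_front_right"),
  swing_front = c("swing_front_left", "swing_front_right"),
  cycle_front = c("cycle_front_left", "cycle_front_right"),
  stand_hind = c("stand_hind_left", "stand_hind_right"),
  swing_hind = c("swing_hind_left", "swing_hind_right"),
  cycle_hind = c("cycle_hind_left", "cycle_hind_right"),
  swing_speed_front = c("swing_speed_front_left", "swing_speed_front_right"),
  swing_speed_hind = c("swing_speed_hind_left", "swing_speed_hind_right")
)
BODY_SPEED_COLS <- c("body_speed_rf", "body_speed_lf", "body_speed_rh", "body_speed_lh")
GAIT_ID_COLS <- c("animal_id", "genotype", "age_weeks", "run_id")

#' Read one raster image as an RGB array
#'
#' @param path PNG or TIFF file, 8 bits per channel.
#' @return numeric `h x w x 3` array on the 0-255 scale; grayscale images
#'   are promoted to three identical channels, alpha is dropped.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported raster format '%s' (PNG or TIFF expected)", ext))
  promote_rgb(img * 255)
}

#' Read an ordered frame sequence plus background image
#'
#' Frame files are taken in lexical order; the designated background file
#' is excluded from the frame list.
#'
#' @param directory directory containing the raster frames.
#' @param resolution a [resolution_spec()].
#' @param background file name (within `directory`) of the background
#'   image; default `"background.png"`.
#' @param species optional [species_profile()], attached to the result.
#' @return a [run_input()].
#' @export
read_frame_sequence <- function(directory, resolution,
                                background = "background.png", species = NULL) {
  files <- sort(list.files(directory, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (!(background %in% files))
    stopf("input error: background file '%s' not found in %s", background, directory)
  frame_files <- setdiff(files, background)
  if (length(frame_files) == 0L)
    stopf("input error: no frame files in %s", directory)
  frames <- lapply(file.path(directory, frame_files), read_raster)
  bg <- read_raster(file.path(directory, background))
  run_input(frames, bg, resolution, species)
}

#' Read a paw-detection log
#'
#' @param path CSV with columns `frame` (positive integer) and `paw`
#'   (one of RF, LF, RH, LH). Duplicate rows are collapsed and frame lists
#'   returned ascending regardless of row order.
#' @return a [paw_tracks()] object.
#' @export
read_paw_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "paw") %in% names(d)))
    stopf("parse error: paw log needs columns 'frame' and 'paw'")
  bad <- setdiff(unique(d$paw), PAW_LABELS)
  if (length(bad))
    stopf("parse error: unknown paw label(s): %s", paste(bad, collapse = ", "))
  if (!is.numeric(d$frame) || any(!is.finite(d$frame)) ||
      any(d$frame != as.integer(d$frame)) || any(d$frame < 1))
    stopf("parse error: 'frame' must contain positive integers")
  get <- function(p) d$frame[d$paw == p]
  paw_tracks(f_RF = get("RF"), f_LF = get("LF"),
             f_RH = get("RH"), f_LH = get("LH"))
}

#' Read a per-run gait-parameter table
#'
#' One row per run with identifier columns (`animal_id`, `genotype`,
#' `age_weeks`, `run_id`), left/right columns for the paired parameters
#' (stride lengths in cm; stand, swing and step-cycle times in s; swing
#' speeds in cm/s), one body-speed column per paw (cm/s), and optionally
#' `weight_g` and per-run silhouette columns (`l_sil_cm`, `a_sil_mm2`).
#'
#' @param path CSV file.
#' @return data frame of class `gait_raw` (left/right kept raw; averaging
#'   happens in [average_left_right()]).
#' @export
read_gait_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_gait_raw(d)
}

#' @rdname read_gait_table
#' @param d data frame in the raw (sided) gait schema.
#' @export
validate_gait_raw <- function(d) {
  required <- c(GAIT_ID_COLS, unlist(GAIT_SIDED_COLS), BODY_SPEED_COLS)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stopf("schema error: missing column(s): %s", paste(missing, collapse = ", "))
  meas <- c(unlist(GAIT_SIDED_COLS), BODY_SPEED_COLS)
  for (cn in meas) {
    v <- d[[cn]]
    if (!is.numeric(v)) stopf("validation error: column %s is not numeric", cn)
    if (any(v < 0, na.rm = TRUE))
      stopf("validation error: negative value in %s", cn)
  }
  class(d) <- c("gait_raw", "data.frame")
  d
}

#' Write / read a run silhouette result (JSON)
#'
#' The JSON carries `silhouette_length_cm`, `area_with_tail_mm2`,
#' `area_without_tail_mm2`, `f_start`, `f_stop`, `n_frames_used` and the
#' `per_frame` table; numbers are written at full precision so a
#' round-trip reproduces the values.
#'
#' @param x a `run_silhouette` from [process_run()].
#' @param path output JSON file.
#' @return `path`, invisibly (writer); a `run_silhouette` (reader).
#' @export
write_run_result <- function(x, path) {
  stopifnot(inherits(x, "run_silhouette"))
  obj <- list(
    silhouette_length_cm = x$silhouette_length_cm,
    area_with_tail_mm2 = x$area_with_tail_mm2,
    area_without_tail_mm2 = x$area_without_tail_mm2,
    f_start = x$window$f_start, f_stop = x$window$f_stop,
    n_frames_used = x$n_frames_used,
    per_frame = x$per_frame)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_result
#' @export
read_run_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    silhouette_length_cm = obj$silhouette_length_cm,
    area_with_tail_mm2 = obj$area_with_tail_mm2,
    area_without_tail_mm2 = obj$area_without_tail_mm2,
    window = structure(list(f_start = obj$f_start, f_stop = obj$f_stop),
                       class = "frame_window"),
    n_frames_used = obj$n_frames_used,
    per_frame = as.data.frame(obj$per_frame)
  ), class = "run_silhouette")
}

#' Write a frame sequence to PNG files
#'
#' Inverse of [read_frame_sequence()]; used to materialise synthetic runs.
#'
#' @param run a [run_input()].
#' @param directory output directory (created if needed).
#' @param background file name for the background image.
#' @return the directory, invisibly.
#' @export
write_frame_sequence <- function(run, directory, background = "background.png") {
  stopifnot(inherits(run, "run_input"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(run$frames))
    png::writePNG(run$frames[[i]] / 255,
                  file.path(directory, sprintf("frame_%04d.png", i)))
  png::writePNG(run$background / 255, file.path(directory, background))
  invisible(directory)
}

#' Write a paw log / gait table CSV
#'
#' @param tracks a [paw_tracks()]; `d` a gait data frame.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_paw_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "paw_tracks"))
  rows <- do.call(rbind, lapply(PAW_LABELS, function(p) {
    f <- tracks[[paste0("f_", p)]]
    if (length(f)) data.frame(frame = f, paw = p) else NULL
  }))
  rows <- rows[order(rows$frame, rows$paw), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_paw_tracks
#' @param d data frame.
#' @export
write_gait_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
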