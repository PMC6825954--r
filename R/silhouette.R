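# Silhouette pipeline: frame-window selection from paw logs, background
# subtraction, tail removal, measurement, and run-level aggregation.

#' Image resolution specification
#'
#' @param x_mm mm per pixel along the walkway axis (image columns), > 0.
#' @param y_mm mm per pixel across the walkway (image rows), > 0; defaults
#'   to `x_mm` (isotropic pixels).
#' @return an object of class `resolution_spec`.
#' @export
resolution_spec <- function(x_mm, y_mm = x_mm) {
  if (!is.numeric(x_mm) || length(x_mm) != 1L || !is.finite(x_mm) || x_mm <= 0 ||
      !is.numeric(y_mm) || length(y_mm) != 1L || !is.finite(y_mm) || y_mm <= 0)
    stopf("resolution: x_mm and y_mm must be finite and > 0")
  structure(list(x_mm = x_mm, y_mm = y_mm), class = "resolution_spec")
}

#' Species parameter presets
#'
#' Loads the packaged species configuration (YAML): the physical diamond
#' radius used for tail removal and the background-subtraction threshold.
#' The rat preset uses a 9 mm radius, the mouse preset 5 mm; both use an
#' intensity threshold of 10 (8-bit scale).
#'
#' @param species `"rat"`, `"mouse"`, or `"custom"`.
#' @param r_d_mm,threshold overrides (required for `"custom"`).
#' @return a named list with `species`, `r_d_mm`, `threshold`.
#' @export
species_profile <- function(species = c("rat", "mouse", "custom"),
                            r_d_mm = NULL, threshold = NULL) {
  species <- match.arg(species)
  cfg_path <- system.file("config", "species.yaml", package = "silgait")
  cfg <- yaml::read_yaml(cfg_path)
  if (species == "custom") {
    if (is.null(r_d_mm)) stopf("custom species profile requires r_d_mm")
    prof <- list(r_d_mm = r_d_mm, threshold = threshold %||% cfg$default_threshold)
  } else {
    prof <- cfg[[species]]
    if (!is.null(r_d_mm)) prof$r_d_mm <- r_d_mm
    if (!is.null(threshold)) prof$threshold <- threshold
  }
  if (prof$r_d_mm <= 0) stopf("r_d_mm must be > 0")
  c(list(species = species), prof)
}

#' Diamond structuring element from a physical radius
#'
#' Converts the physical tail-removal radius to pixels with half-up
#' rounding on the walkway-axis resolution (5 mm at 0.7 mm/px gives 7 px;
#' 9 mm at 1 mm/px gives 9 px), with a minimum of one pixel. The element
#' contains all pixels within Manhattan distance `r_d_px` of the origin
#' (`2*r^2 + 2*r + 1` pixels).
#'
#' @param r_d_mm physical radius in mm, > 0.
#' @param resolution a [resolution_spec()].
#' @return an object of class `diamond_se` with `r_d_mm`, `r_d_px`,
#'   `n_pixels`, and the offset matrix `offsets` (columns dr, dc).
#' @export
make_diamond_se <- function(r_d_mm, resolution) {
  if (!is.numeric(r_d_mm) || length(r_d_mm) != 1L || !is.finite(r_d_mm) || r_d_mm <= 0)
    stopf("r_d_mm must be a single finite value > 0")
  stopifnot(inherits(resolution, "resolution_spec"))
  r_px <- max(1L, as.integer(round_half_up(r_d_mm / resolution$x_mm)))
  offs <- diamond_offsets(r_px)
  structure(list(r_d_mm = r_d_mm, r_d_px = r_px,
                 n_pixels = nrow(offs), offsets = offs),
            class = "diamond_se")
}

# lattice points with |dr| + |dc| <= r
diamond_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[abs(g$dr) + abs(g$dc) <= r, , drop = FALSE])
}

#' Per-paw frame-index lists
#'
#' @param f_RF,f_LF,f_RH,f_LH positive integer frame indices where the
#'   right-front, left-front, right-hind and left-hind paw is detected.
#'   Each vector is de-duplicated and sorted ascending.
#' @return an object of class `paw_tracks`.
#' @export
paw_tracks <- function(f_RF, f_LF, f_RH, f_LH) {
  fix <- function(v, nm) {
    if (length(v) == 0L) return(integer(0))
    if (any(!is.finite(v)) || any(v != as.integer(v)) || any(v < 1))
      stopf("paw track %s: frame indices must be positive integers", nm)
    sort(unique(as.integer(v)))
  }
  structure(list(f_RF = fix(f_RF, "RF"), f_LF = fix(f_LF, "LF"),
                 f_RH = fix(f_RH, "RH"), f_LH = fix(f_LH, "LH")),
            class = "paw_tracks")
}

#' Analysis frame window from paw detections
#'
#' The window begins at the first frame where both hind paws have appeared
#' (maximum of the first right-hind and left-hind detections) and ends at
#' the frame where the first front paw leaves the recording area (minimum
#' of the last right-front and left-front detections).
#'
#' @param tracks a [paw_tracks()] object with all four lists non-empty.
#' @return a list of class `frame_window` with `f_start`, `f_stop`.
#' @export
compute_frame_window <- function(tracks) {
  stopifnot(inherits(tracks, "paw_tracks"))
  if (any(vapply(tracks, length, integer(1)) == 0L))
    stopf("missing paw: all four paw-track lists must be non-empty")
  f_start <- max(tracks$f_RH[1L], tracks$f_LH[1L])
  f_stop <- min(tracks$f_RF[length(tracks$f_RF)], tracks$f_LF[length(tracks$f_LF)])
  if (f_start > f_stop)
    stopf("empty frame window: f_start (%d) > f_stop (%d)", f_start, f_stop)
  structure(list(f_start = f_start, f_stop = f_stop), class = "frame_window")
}

#' Background subtraction
#'
#' A pixel is foreground when its absolute difference from the background
#' image strictly exceeds the threshold in at least one of the R, G, B
#' layers (channel-wise logical OR). Grayscale inputs are treated as three
#' identical channels.
#'
#' @param frame,background numeric arrays `h x w x 3` (or `h x w`
#'   grayscale matrices) on the 0-255 scale, same shape.
#' @param threshold intensity threshold `T_h >= 0`; default 10.
#' @return logical matrix (stage `FG`).
#' @export
subtract_background <- function(frame, background, threshold = 10) {
  frame <- promote_rgb(frame); background <- promote_rgb(background)
  if (!identical(dim(frame), dim(background)))
    stopf("shape mismatch: frame %s vs background %s",
          paste(dim(frame), collapse = "x"), paste(dim(background), collapse = "x"))
  if (threshold < 0) stopf("threshold must be >= 0")
  d <- abs(frame - background)
  fg <- d[, , 1L] > threshold | d[, , 2L] > threshold | d[, , 3L] > threshold
  attr(fg, "stage") <- "FG"
  fg
}

# grayscale matrix -> h x w x 3, pass-through for 3-channel arrays
promote_rgb <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stopf("frames must be h x w x 3 arrays (or grayscale matrices)")
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Measure a single-frame silhouette
#'
#' Finds the leftmost and rightmost silhouette pixels along the walkway
#' axis (image columns) and returns the Euclidean distance between them
#' after subtracting the structuring-element radius from the along-walkway
#' span (the opening typically leaves a tail stub about one radius long).
#' If the span is smaller than the radius the length is reported as 0.
#' Areas are pixel counts times the pixel area, with the tail (from the
#' cleaned un-opened mask) and without it (from the opened mask).
#'
#' @param mask_r stage-`R` mask: hole-filled, largest object of the opened
#'   foreground (tail removed).
#' @param mask_fg_cleaned hole-filled largest object of the raw foreground
#'   (tail kept); pass `mask_r` to skip the with-tail area.
#' @param se a [make_diamond_se()] object.
#' @param resolution a [resolution_spec()].
#' @return an object of class `frame_silhouette`: `length_cm`,
#'   `area_with_tail_mm2`, `area_without_tail_mm2`, `endpoints`.
#' @export
measure_silhouette <- function(mask_r, mask_fg_cleaned, se, resolution) {
  if (!any(mask_r)) stopf("no silhouette: empty mask")
  cols <- which(colSums(mask_r) > 0L)
  x2 <- cols[1L]; x1 <- cols[length(cols)]
  cent <- mean(row(mask_r)[mask_r])
  pick_row <- function(x) {
    rows <- which(mask_r[, x])
    rows[order(abs(rows - cent), rows)][1L]
  }
  y1 <- pick_row(x1); y2 <- pick_row(x2)
  dx <- x1 - x2 - se$r_d_px
  length_mm <- if (dx < 0) 0 else
    sqrt((dx * resolution$x_mm)^2 + ((y1 - y2) * resolution$y_mm)^2)
  px_area <- resolution$x_mm * resolution$y_mm
  structure(list(
    length_cm = length_mm / 10,
    area_with_tail_mm2 = sum(mask_fg_cleaned) * px_area,
    area_without_tail_mm2 = sum(mask_r) * px_area,
    endpoints = c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  ), class = "frame_silhouette")
}

#' Run input container
#'
#' @param frames list of `h x w x 3` numeric arrays (0-255), one per video
#'   frame, 1-based contiguous indexing.
#' @param background one `h x w x 3` array of the same shape.
#' @param resolution a [resolution_spec()].
#' @param species a [species_profile()] (optional; needed by
#'   [process_run()] unless `se`/`threshold` are passed there).
#' @return an object of class `run_input`.
#' @export
run_input <- function(frames, background, resolution, species = NULL) {
  if (length(frames) < 1L) stopf("input error: need at least one frame")
  frames <- lapply(frames, promote_rgb)
  background <- promote_rgb(background)
  d0 <- dim(frames[[1L]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d0))
      stopf("shape error: frame %d is %s, expected %s", i,
            paste(dim(frames[[i]]), collapse = "x"), paste(d0, collapse = "x"))
  if (!identical(dim(background), d0))
    stopf("shape error: background does not match frame dimensions")
  stopifnot(inherits(resolution, "resolution_spec"))
  structure(list(frames = frames, background = background,
                 resolution = resolution, species = species),
            class = "run_input")
}

#' Process one run: silhouette length and areas
#'
#' Applies, for every frame of the paw-defined window, the full chain:
#' background subtraction, diamond opening (tail removal), hole filling,
#' largest-object retention, and length/area measurement. The run-level
#' silhouette length and areas are the maxima over the per-frame values.
#' The with-tail area uses the hole-filled largest component of the raw
#' foreground (no opening). In-window frames with an empty mask are
#' skipped with a warning.
#'
#' @param run a [run_input()].
#' @param tracks a [paw_tracks()] set; all indices must be inside the run.
#' @param se optional [make_diamond_se()]; defaults to the run's species
#'   profile radius.
#' @param threshold optional background threshold; defaults to the species
#'   profile (10).
#' @return an object of class `run_silhouette` with `silhouette_length_cm`,
#'   `area_with_tail_mm2`, `area_without_tail_mm2`, `window`,
#'   `n_frames_used` and a `per_frame` data frame.
#' @export
process_run <- function(run, tracks, se = NULL, threshold = NULL) {
  stopifnot(inherits(run, "run_input"))
  window <- compute_frame_window(tracks)
  n <- length(run$frames)
  if (max(unlist(unclass(tracks))) > n)
    stopf("paw track frame index exceeds run length (%d frames)", n)
  prof <- run$species
  if (is.null(se)) {
    if (is.null(prof)) stopf("no structuring element: supply se or a species profile")
    se <- make_diamond_se(prof$r_d_mm, run$resolution)
  }
  threshold <- threshold %||% (prof$threshold %||% 10)
  frames_used <- integer(0)
  per <- list()
  for (f in window$f_start:window$f_stop) {
    fg <- subtract_background(run$frames[[f]], run$background, threshold)
    if (!any(fg)) { warning(sprintf("frame %d: empty foreground, skipped", f)); next }
    opened <- open_remove_tail(fg, se)
    filled <- fill_holes(opened)
    if (!any(filled)) { warning(sprintf("frame %d: silhouette removed by opening, skipped", f)); next }
    body <- retain_largest_object(filled)
    with_tail <- retain_largest_object(fill_holes(fg))
    m <- measure_silhouette(body, with_tail, se, run$resolution)
    frames_used <- c(frames_used, f)
    per[[length(per) + 1L]] <- data.frame(
      frame = f, length_cm = m$length_cm,
      area_with_tail_mm2 = m$area_with_tail_mm2,
      area_without_tail_mm2 = m$area_without_tail_mm2,
      x1 = m$endpoints["x1"], y1 = m$endpoints["y1"],
      x2 = m$endpoints["x2"], y2 = m$endpoints["y2"], row.names = NULL)
  }
  if (length(per) == 0L)
    stopf("no silhouette: every frame in the window [%d, %d] was empty",
          window$f_start, window$f_stop)
  per <- do.call(rbind, per)
  structure(list(
    silhouette_length_cm = max(per$length_cm),
    area_with_tail_mm2 = max(per$area_with_tail_mm2),
    area_without_tail_mm2 = max(per$area_without_tail_mm2),
    window = window, n_frames_used = nrow(per), per_frame = per
  ), class = "run_silhouette")
}

#' @export
print.run_silhouette <- function(x, ...) {
  cat("Run silhouette\n")
  cat(sprintf("  frame window     : %d-%d (%d frames used)\n",
              x$window$f_start, x$window$f_stop, x$n_frames_used))
  cat(sprintf("  length           : %.2f cm\n", x$silhouette_length_cm))
  cat(sprintf("  area (with tail) : %.1f mm^2\n", x$area_with_tail_mm2))
  cat(sprintf("  area (no tail)   : %.1f mm^2\n", x$area_without_tail_mm2))
  invisible(x)
}

#' @export
print.frame_window <- function(x, ...) {
  cat(sprintf("frame window [%d, %d]\n", x$f_start, x$f_stop)); invisible(x)
}

#' @export
print.diamond_se <- function(x, ...) {
  cat(sprintf("diamond structuring element: r_d = %g mm = %d px (%d pixels)\n",
              x$r_d_mm, x$r_d_px, x$n_pixels)); invisible(x)
}
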