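# Gait-parameter scaling by body-size factors, left/right averaging and
# run-to-animal aggregation.

#' Names of the gait parameters carried through scaling
#'
#' Eleven parameters: front/hind stride length (cm); front/hind stand,
#' swing and step-cycle times (s); body speed and front/hind swing speed
#' (cm/s).
#'
#' @return character vector of parameter (column) names.
#' @export
gait_parameter_names <- function() {
  c("stride_front", "stride_hind",
    "stand_front", "swing_front", "cycle_front",
    "stand_hind", "swing_hind", "cycle_hind",
    "body_speed", "swing_speed_front", "swing_speed_hind")
}

#' @rdname gait_parameter_names
#' @export
speed_parameter_names <- function() {
  c("body_speed", "swing_speed_front", "swing_speed_hind")
}

#' Average left/right paw columns into per-run gait records
#'
#' Paired parameters are the arithmetic mean of the left and right paw;
#' body speed is the mean over all four paws. Identifier columns and any
#' extra columns (weight, per-run silhouette values) are carried through.
#'
#' @param raw a `gait_raw` data frame ([read_gait_table()] schema).
#' @return data frame of class `gait_records`, one row per run, with the
#'   columns of [gait_parameter_names()].
#' @export
average_left_right <- function(raw) {
  raw <- validate_gait_raw(as.data.frame(raw))
  for (nm in names(GAIT_SIDED_COLS)) {
    sides <- raw[, GAIT_SIDED_COLS[[nm]], drop = FALSE]
    if (anyNA(sides))
      stopf("validation error: missing side value(s) in %s", nm)
  }
  if (anyNA(raw[, BODY_SPEED_COLS]))
    stopf("validation error: missing per-paw body-speed value(s)")
  out <- raw[, GAIT_ID_COLS, drop = FALSE]
  for (nm in names(GAIT_SIDED_COLS))
    out[[nm]] <- rowMeans(raw[, GAIT_SIDED_COLS[[nm]], drop = FALSE])
  out$body_speed <- rowMeans(raw[, BODY_SPEED_COLS, drop = FALSE])
  out <- out[, c(GAIT_ID_COLS, gait_parameter_names()[c(1:8)], "body_speed"), drop = FALSE]
  out$swing_speed_front <- rowMeans(raw[, GAIT_SIDED_COLS$swing_speed_front, drop = FALSE])
  out$swing_speed_hind <- rowMeans(raw[, GAIT_SIDED_COLS$swing_speed_hind, drop = FALSE])
  extra <- setdiff(names(raw), c(GAIT_ID_COLS, unlist(GAIT_SIDED_COLS), BODY_SPEED_COLS))
  for (cn in extra) out[[cn]] <- raw[[cn]]
  class(out) <- c("gait_records", "data.frame")
  out
}

#' Scale gait parameters by a body-size factor
#'
#' Divides each gait parameter by the chosen denominator: silhouette
#' length (cm), silhouette area (mm^2), body weight (g) or age (weeks).
#' The `froude` method instead divides the speed parameters by
#' `sqrt(g * l_sil)` (g = 981 cm/s^2), yielding a dimensionless
#' locomotion number, and applies to speed parameters only (other slots
#' are returned as `NA`).
#'
#' @param records a `gait_records` data frame (or any data frame carrying
#'   the parameter columns).
#' @param method one of `"length"`, `"froude"`, `"area"`, `"weight"`,
#'   `"age"`.
#' @param denominator positive scalar or per-row vector: `l_sil` in cm for
#'   `length`/`froude`, `a_sil` in mm^2 for `area`, weight in g, age in
#'   weeks.
#' @param gravity acceleration of gravity in cm/s^2 (default 981, coherent
#'   with speeds in cm/s).
#' @param parameters which parameter columns to scale; defaults to all
#'   eleven (speed parameters only for `froude`).
#' @return data frame of class `scaled_gait` with the same shape; scaled
#'   columns replace the raw values. Attributes `method`, `denominator`
#'   and `gravity` record the bookkeeping.
#' @export
scale_gait <- function(records, method = c("length", "froude", "area", "weight", "age"),
                       denominator, gravity = 981, parameters = NULL) {
  method <- match.arg(method)
  records <- as.data.frame(records)
  n <- nrow(records)
  if (!is.numeric(denominator) || !(length(denominator) %in% c(1L, n)))
    stopf("scaling error: denominator must be a scalar or one value per row")
  if (any(!is.finite(denominator)) || any(denominator <= 0))
    stopf("scaling error: denominator must be finite and > 0")
  all_params <- intersect(gait_parameter_names(), names(records))
  if (is.null(parameters))
    parameters <- if (method == "froude") intersect(speed_parameter_names(), all_params) else all_params
  if (method == "froude" && length(setdiff(parameters, speed_parameter_names())))
    stopf("method error: froude scaling applies only to speed parameters")
  div <- if (method == "froude") sqrt(gravity * denominator) else denominator
  out <- records
  for (p in all_params)
    out[[p]] <- if (p %in% parameters) records[[p]] / div else records[[p]] * NA_real_
  if (method == "froude") out[, setdiff(all_params, parameters)] <- NA_real_
  structure(out, method = method, denominator = denominator, gravity = gravity,
            class = c("scaled_gait", "data.frame"))
}

#' Body-weight silhouette-length index
#'
#' A body-condition index analogous to the body mass index:
#' weight divided by the squared silhouette length, in g/cm^2.
#'
#' @param weight_g body weight in grams, > 0.
#' @param l_sil_cm silhouette length in cm, > 0.
#' @return numeric index (g/cm^2), vectorised.
#' @export
weight_length_index <- function(weight_g, l_sil_cm) {
  if (any(!is.finite(weight_g)) || any(weight_g <= 0) ||
      any(!is.finite(l_sil_cm)) || any(l_sil_cm <= 0))
    stopf("parameter error: weight and silhouette length must be > 0")
  weight_g / l_sil_cm^2
}

#' Aggregate per-run records to animal level
#'
#' Arithmetic mean of every numeric parameter over an animal's runs at
#' each age point. Scaling must be applied per run before aggregation
#' (scaled animal values are means of per-run scaled values, not scaled
#' means).
#'
#' @param records a `gait_records` or `scaled_gait` data frame; may carry
#'   extra numeric columns (per-run `l_sil_cm`, `a_sil_mm2`, `weight_g`)
#'   which are averaged too.
#' @param by grouping columns; default animal, genotype and age.
#' @return data frame of class `animal_records`, one row per animal x age.
#' @export
aggregate_animal <- function(records, by = c("animal_id", "genotype", "age_weeks")) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stopf("aggregation error: zero runs")
  by <- intersect(by, names(records))
  num <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                 c(by, "run_id"))
  out <- stats::aggregate(records[num], by = records[by], FUN = mean)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("animal_records", "data.frame")
  out
}
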