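# Synthetic data: rendered rodent-like walkway frames with known
# silhouette geometry, paw logs, and longitudinal gait cohorts with
# length-coupled parameters.

#' Specification of a synthetic rodent render
#'
#' The body is a capsule-like shape: a rectangle with a blunt (flat) rump
#' at the tail base and a half-disk head cap at the nose, so the
#' nose-to-tail-base ground-truth length is exactly the distance between
#' the two extremities. The tail is a curved, tapering ribbon whose base
#' width defaults to one pixel less than the structuring-element diameter
#' (matching the premise that the opening radius is adjusted to the tail
#' size: the tail is removed, and the surviving tail stub spans about one
#' radius, which is what the length formula corrects for).
#'
#' @param body_length_mm nose-to-tail-base ground truth, mm.
#' @param species `"rat"` or `"mouse"`; sets the resolution and the
#'   tail-removal radius defaults.
#' @param body_width_mm body width; must be at least the structuring
#'   element diameter (default: species-typical).
#' @param tail_length_mm tail length (default 0.8 x body length).
#' @param tail_tip_width_px ribbon width at the tail tip, px.
#' @param tail_base_width_px ribbon width at the tail base, px; must stay
#'   below twice the pixel radius so the opening removes the tail.
#' @param orientation_deg body axis angle relative to the walkway, degrees.
#' @param tail_sag_frac downward bow of the tail as a fraction of its
#'   length.
#' @param background_level,body_level 8-bit intensities of walkway and
#'   animal.
#' @param noise_sd additive pixel noise sd; samples are clamped to under
#'   half the background-subtraction threshold so segmentation is exact.
#' @param step_px animal translation per frame along the walkway, px.
#' @param resolution a [resolution_spec()]; defaults to 1 mm/px (rat) or
#'   0.7 mm/px (mouse). The renderer assumes isotropic pixels.
#' @return list of class `synthetic_rodent_spec`.
#' @export
synthetic_rodent_spec <- function(body_length_mm,
                                  species = c("rat", "mouse"),
                                  body_width_mm = NULL,
                                  tail_length_mm = NULL,
                                  tail_tip_width_px = 2,
                                  tail_base_width_px = NULL,
                                  orientation_deg = 0,
                                  tail_sag_frac = 0.10,
                                  background_level = 40,
                                  body_level = 200,
                                  noise_sd = 2,
                                  step_px = 6,
                                  resolution = NULL) {
  species <- match.arg(species)
  prof <- species_profile(species)
  if (is.null(resolution))
    resolution <- resolution_spec(if (species == "rat") 1 else 0.7)
  if (resolution$x_mm != resolution$y_mm)
    stopf("renderer requires isotropic pixels")
  se <- make_diamond_se(prof$r_d_mm, resolution)
  if (is.null(body_width_mm))
    body_width_mm <- if (species == "rat") 50 else 26
  if (is.null(tail_length_mm)) tail_length_mm <- 0.8 * body_length_mm
  if (is.null(tail_base_width_px)) tail_base_width_px <- 2L * se$r_d_px - 1L
  if (body_width_mm < 2 * prof$r_d_mm)
    stopf("body_width_mm must be >= twice the structuring-element radius")
  if (tail_base_width_px >= 2L * se$r_d_px)
    stopf("tail base width must be < twice the pixel radius (opening must remove the tail)")
  if (body_length_mm <= 0 || tail_length_mm <= 0)
    stopf("lengths must be > 0")
  structure(list(
    species = species, profile = prof, resolution = resolution, se = se,
    body_length_mm = body_length_mm, body_width_mm = body_width_mm,
    tail_length_mm = tail_length_mm,
    tail_tip_width_px = tail_tip_width_px,
    tail_base_width_px = tail_base_width_px,
    orientation_deg = orientation_deg, tail_sag_frac = tail_sag_frac,
    background_level = background_level, body_level = body_level,
    noise_sd = noise_sd, step_px = step_px
  ), class = "synthetic_rodent_spec")
}

# body/tail membership on the pixel grid; x0, y0 = tail-base position in
# pixel coordinates (x = column, y = row). Returns list(body, tail) masks.
rasterize_rodent <- function(spec, nr, nc, x0, y0) {
  px <- spec$resolution$x_mm
  L <- spec$body_length_mm / px
  H <- spec$body_width_mm / px
  tl <- spec$tail_length_mm / px
  R <- H / 2
  th <- spec$orientation_deg * pi / 180
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc) - x0
  ys <- matrix(rep(seq_len(nr), times = nc), nr, nc) - y0
  xi <- cos(th) * xs + sin(th) * ys    # along-body coordinate
  eta <- -sin(th) * xs + cos(th) * ys  # across-body coordinate
  body <- (xi >= 0 & xi <= L - R & abs(eta) <= R) |
    ((xi - (L - R))^2 + eta^2 <= R^2 & xi > L - R)
  # constant-width tail root (one SE radius) before the linear taper, so
  # the rasterized base keeps its full width next to the body
  hold <- spec$se$r_d_px + 1
  u <- pmin(pmax((-xi - hold) / (tl - hold), 0), 1)  # 0 at base, 1 at tip
  eta_c <- spec$tail_sag_frac * tl * u^2
  w <- spec$tail_base_width_px + (spec$tail_tip_width_px - spec$tail_base_width_px) * u
  # half-pixel slack keeps the rasterized base at its nominal width under
  # small rotations; the drawn width stays below the SE diameter, so the
  # opening still removes the tail
  tail <- xi < 0 & xi >= -tl & abs(eta - eta_c) <= w / 2
  list(body = body, tail = tail)
}

#' Render a synthetic run: frames, background, paw log, ground truth
#'
#' Draws the animal translating along the walkway over `n_frames` frames
#' at a contrast far above the segmentation threshold, adds sub-threshold
#' pixel noise, and emits a paw log in which both hind paws are first
#' detected on frame 2 and the front paws disappear after frame
#' `n_frames - 1`, so the analysis window is frames 2 to `n_frames - 1`.
#'
#' @param spec a [synthetic_rodent_spec()].
#' @param n_frames number of frames, >= 3.
#' @param seed RNG seed (noise); identical seeds give identical frames.
#' @return list of class `synthetic_run`: `run` ([run_input()]), `tracks`
#'   ([paw_tracks()]), `truth` (ground-truth length in mm and per-frame
#'   body pixel counts and extremity positions).
#' @export
render_run <- function(spec, n_frames = 4, seed = 1) {
  stopifnot(inherits(spec, "synthetic_rodent_spec"))
  if (n_frames < 3L) stopf("need at least 3 frames")
  set.seed(seed)
  px <- spec$resolution$x_mm
  L <- spec$body_length_mm / px
  tl <- spec$tail_length_mm / px
  H <- spec$body_width_mm / px
  margin <- 2 * spec$se$r_d_px + 4
  nc <- ceiling(tl + L + (n_frames - 1) * spec$step_px + 2 * margin)
  nr <- ceiling(max(H, spec$tail_base_width_px) +
                  2 * (spec$tail_sag_frac * tl + margin))
  y0 <- round(nr / 2 - spec$tail_sag_frac * tl / 2)
  x0_first <- margin + tl
  if (x0_first + L + (n_frames - 1) * spec$step_px > nc - margin + 1 ||
      y0 - H / 2 < 1 || y0 + H / 2 + spec$tail_sag_frac * tl > nr)
    stopf("render error: geometry exceeds frame")
  clamp <- spec$profile$threshold / 2 - 0.1
  bg <- array(spec$background_level, dim = c(nr, nc, 3L))
  frames <- vector("list", n_frames)
  truth_pf <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    x0 <- x0_first + (f - 1) * spec$step_px
    m <- rasterize_rodent(spec, nr, nc, x0, y0)
    sil <- m$body | m$tail
    img <- bg
    for (ch in 1:3) img[, , ch] <- img[, , ch] + sil * (spec$body_level - spec$background_level)
    noise <- array(pmin(pmax(stats::rnorm(nr * nc * 3, 0, spec$noise_sd),
                             -clamp), clamp), dim = c(nr, nc, 3L))
    frames[[f]] <- pmin(pmax(img + noise, 0), 255)
    th <- spec$orientation_deg * pi / 180
    truth_pf[[f]] <- data.frame(
      frame = f, body_pixels = sum(m$body), tail_pixels = sum(m$tail & !m$body),
      x_tailbase = x0, y_tailbase = y0,
      x_nose = x0 + L * cos(th), y_nose = y0 + L * sin(th))
  }
  run <- run_input(frames, bg, spec$resolution, spec$profile)
  tracks <- paw_tracks(f_RF = 1:(n_frames - 1), f_LF = 1:(n_frames - 1),
                       f_RH = 2:n_frames, f_LH = 2:n_frames)
  structure(list(run = run, tracks = tracks,
                 truth = list(body_length_mm = spec$body_length_mm,
                              per_frame = do.call(rbind, truth_pf)),
                 spec = spec),
            class = "synthetic_run")
}

#' Specification of a synthetic longitudinal cohort
#'
#' Emulates a repeated-measures design: two genotypes followed over the
#' species' age points, several runs per animal and age. Per animal x
#' age, the body length is drawn around the genotype's growth trajectory;
#' stride lengths are proportional to length and body speed to the square
#' root of length (constant Froude number), both with multiplicative
#' log-normal noise; durations are independent of length; swing speeds
#' are stride over swing time. Weight grows with the cube of length.
#'
#' @param species `"rat"` (five age points) or `"mouse"` (three).
#' @param n_per_genotype animals per genotype, >= 2.
#' @param ages age points in weeks; species default.
#' @param wt_length_mm wild-type mean silhouette length at each age, mm.
#' @param tg_length_factor multiplicative genotype effect on length
#'   (default: transgenic rats 7% smaller, transgenic mice 5% larger).
#' @param animal_sd_mm between-animal length sd; `within_sd_mm` adds
#'   age-point-level length fluctuation.
#' @param within_sd_mm see above.
#' @param stride_coupling cm of stride per cm of body length (front,
#'   hind); 0 decouples stride from size.
#' @param froude_number dimensionless body-speed level; 0 decouples speed
#'   from size (speed then falls back to a fixed mean).
#' @param noise_sd multiplicative (log-scale) noise sd on stride and body
#'   speed.
#' @param duration_means named means (s) for stand/swing, front/hind;
#'   `duration_sd` their log-scale sd.
#' @param duration_sd see above.
#' @param tg_effects named list of direct multiplicative genotype effects
#'   on gait parameters (e.g. `list(stride_hind = 0.95)`), applied on top
#'   of any size-mediated effect; default none.
#' @param runs_per_animal runs per animal and age point.
#' @param run_sd,side_sd log-scale run-to-run and left/right asymmetry sd.
#' @param l_sil_noise_cm additive sd of the per-run silhouette length
#'   "measurement" (the cohort generator simulates pipeline output).
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(species = c("rat", "mouse"),
                                  n_per_genotype = 12,
                                  ages = NULL,
                                  wt_length_mm = NULL,
                                  tg_length_factor = NULL,
                                  animal_sd_mm = NULL,
                                  within_sd_mm = 2,
                                  stride_coupling = c(front = 0.75, hind = 0.76),
                                  froude_number = NULL,
                                  noise_sd = 0.075,
                                  duration_means = NULL,
                                  duration_sd = 0.08,
                                  tg_effects = list(),
                                  runs_per_animal = 3,
                                  run_sd = 0.03, side_sd = 0.015,
                                  l_sil_noise_cm = 0.05) {
  species <- match.arg(species)
  if (n_per_genotype < 2) stopf("parameter error: need >= 2 animals per genotype")
  if (noise_sd < 0 || duration_sd < 0 || run_sd < 0 || side_sd < 0)
    stopf("parameter error: sds must be >= 0")
  if (species == "rat") {
    ages <- ages %||% c(10, 26, 42, 55, 63)
    wt_length_mm <- wt_length_mm %||% c(190, 212, 222, 228, 225)
    tg_length_factor <- tg_length_factor %||% 0.93
    animal_sd_mm <- animal_sd_mm %||% 6
    froude_number <- froude_number %||% 0.21
    duration_means <- duration_means %||%
      c(stand_front = 0.24, swing_front = 0.105, stand_hind = 0.25, swing_hind = 0.115)
  } else {
    ages <- ages %||% c(21, 32, 46)
    wt_length_mm <- wt_length_mm %||% c(82, 86, 89)
    tg_length_factor <- tg_length_factor %||% 1.05
    animal_sd_mm <- animal_sd_mm %||% 3
    froude_number <- froude_number %||% 0.33
    duration_means <- duration_means %||%
      c(stand_front = 0.13, swing_front = 0.075, stand_hind = 0.14, swing_hind = 0.08)
  }
  if (length(wt_length_mm) != length(ages))
    stopf("parameter error: wt_length_mm must match the number of age points")
  structure(list(
    species = species, n_per_genotype = n_per_genotype, ages = ages,
    wt_length_mm = wt_length_mm, tg_length_factor = tg_length_factor,
    animal_sd_mm = animal_sd_mm, within_sd_mm = within_sd_mm,
    stride_coupling = stride_coupling, froude_number = froude_number,
    noise_sd = noise_sd, duration_means = duration_means,
    duration_sd = duration_sd, tg_effects = tg_effects,
    runs_per_animal = runs_per_animal, run_sd = run_sd, side_sd = side_sd,
    l_sil_noise_cm = l_sil_noise_cm
  ), class = "synthetic_cohort_spec")
}

#' Generate a longitudinal gait cohort
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param seed RNG seed; identical seeds give identical datasets.
#' @param genotypes genotype labels (wild type first).
#' @return list of class `synthetic_cohort`: `runs` (per-run sided gait
#'   table in the [read_gait_table()] schema, plus `weight_g`, `l_sil_cm`,
#'   `a_sil_mm2`, `a_sil_with_tail_mm2`), `animals` (animal x age means
#'   via [average_left_right()] + [aggregate_animal()]), `truth`
#'   (animal x age true lengths), `spec`.
#' @export
generate_cohort <- function(spec, seed = 1, genotypes = c("WT", "TG")) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(seed)
  g_cm <- 981
  rows <- list(); truth <- list()
  dm <- spec$duration_means
  eff <- function(geno, param) {
    if (geno == genotypes[2L] && !is.null(spec$tg_effects[[param]]))
      spec$tg_effects[[param]] else 1
  }
  aid <- 0L
  for (geno in genotypes) {
    len_factor <- if (geno == genotypes[2L]) spec$tg_length_factor else 1
    for (i in seq_len(spec$n_per_genotype)) {
      aid <- aid + 1L
      animal <- sprintf("%s%03d", tolower(geno), aid)
      a_dev <- stats::rnorm(1, 0, spec$animal_sd_mm)
      for (j in seq_along(spec$ages)) {
        L_mm <- spec$wt_length_mm[j] * len_factor + a_dev +
          stats::rnorm(1, 0, spec$within_sd_mm)
        L_cm <- L_mm / 10
        # zero coupling decouples stride from size: fixed species-level mean
        mean_stride <- mean(spec$wt_length_mm) / 10 * 0.755
        base_f <- if (spec$stride_coupling[["front"]] > 0)
          spec$stride_coupling[["front"]] * L_cm else mean_stride
        base_h <- if (spec$stride_coupling[["hind"]] > 0)
          spec$stride_coupling[["hind"]] * L_cm else mean_stride
        stride_f <- base_f * exp(stats::rnorm(1, 0, spec$noise_sd)) * eff(geno, "stride_front")
        stride_h <- base_h * exp(stats::rnorm(1, 0, spec$noise_sd)) * eff(geno, "stride_hind")
        bspeed <- if (spec$froude_number > 0)
          spec$froude_number * sqrt(g_cm * L_cm) *
            exp(stats::rnorm(1, 0, spec$noise_sd)) * eff(geno, "body_speed")
        else 30 * exp(stats::rnorm(1, 0, spec$noise_sd)) * eff(geno, "body_speed")
        dur <- dm * exp(stats::rnorm(4, 0, spec$duration_sd)) *
          vapply(names(dm), function(p) eff(geno, p), numeric(1))
        w_g <- 0.040 * L_cm^3 * exp(stats::rnorm(1, 0, 0.04))
        a_sil <- 0.28 * L_mm^2 * exp(stats::rnorm(1, 0, 0.03))
        truth[[length(truth) + 1L]] <- data.frame(
          animal_id = animal, genotype = geno, age_weeks = spec$ages[j],
          true_length_mm = L_mm)
        for (r in seq_len(spec$runs_per_animal)) {
          rn <- function(v) v * exp(stats::rnorm(length(v), 0, spec$run_sd))
          sides <- function(v) v * exp(stats::rnorm(2, 0, spec$side_sd))
          st_f <- sides(rn(stride_f)); st_h <- sides(rn(stride_h))
          sw_f <- sides(rn(dur[["swing_front"]])); sw_h <- sides(rn(dur[["swing_hind"]]))
          sd_f <- sides(rn(dur[["stand_front"]])); sd_h <- sides(rn(dur[["stand_hind"]]))
          bs <- rn(bspeed) * exp(stats::rnorm(4, 0, spec$side_sd))
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = animal, genotype = geno, age_weeks = spec$ages[j],
            run_id = sprintf("%s_a%02d_r%d", animal, j, r),
            stride_front_left = st_f[1], stride_front_right = st_f[2],
            stride_hind_left = st_h[1], stride_hind_right = st_h[2],
            stand_front_left = sd_f[1], stand_front_right = sd_f[2],
            swing_front_left = sw_f[1], swing_front_right = sw_f[2],
            cycle_front_left = sd_f[1] + sw_f[1], cycle_front_right = sd_f[2] + sw_f[2],
            stand_hind_left = sd_h[1], stand_hind_right = sd_h[2],
            swing_hind_left = sw_h[1], swing_hind_right = sw_h[2],
            cycle_hind_left = sd_h[1] + sw_h[1], cycle_hind_right = sd_h[2] + sw_h[2],
            swing_speed_front_left = st_f[1] / sw_f[1],
            swing_speed_front_right = st_f[2] / sw_f[2],
            swing_speed_hind_left = st_h[1] / sw_h[1],
            swing_speed_hind_right = st_h[2] / sw_h[2],
            body_speed_rf = bs[1], body_speed_lf = bs[2],
            body_speed_rh = bs[3], body_speed_lh = bs[4],
            weight_g = w_g,
            l_sil_cm = L_cm + stats::rnorm(1, 0, spec$l_sil_noise_cm),
            a_sil_mm2 = a_sil,
            a_sil_with_tail_mm2 = 1.26 * a_sil)
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  runs <- validate_gait_raw(runs)
  animals <- aggregate_animal(average_left_right(runs))
  structure(list(runs = runs, animals = animals,
                 truth = do.call(rbind, truth), spec = spec),
            class = "synthetic_cohort")
}
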