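test_that("frame window follows hind-paw entry and front-paw exit", {
  tr <- paw_tracks(f_RF = 2:90, f_LF = 2:87, f_RH = 3:4, f_LH = 5:6)
  w <- compute_frame_window(tr)
  expect_equal(c(w$f_start, w$f_stop), c(5, 87))
  tr2 <- paw_tracks(1:10, 1:10, 1:10, 1:10)
  w2 <- compute_frame_window(tr2)
  expect_equal(c(w2$f_start, w2$f_stop), c(1, 10))
  expect_error(compute_frame_window(paw_tracks(1:4, 1:4, 9, 1:4)),
               "empty frame window")
  expect_error(compute_frame_window(paw_tracks(integer(0), 1:4, 1:4, 1:4)),
               "missing paw")
})

test_that("background subtraction is a strict per-channel OR threshold", {
  bg <- array(100, dim = c(2, 2, 3))
  fr <- bg
  fr[1, 1, ] <- 110                       # diff exactly 10: background
  fr[1, 2, ] <- c(100, 100, 111)          # one channel over: foreground
  m <- subtract_background(fr, bg, threshold = 10)
  expect_false(m[1, 1])
  expect_true(m[1, 2])
  expect_false(any(subtract_background(bg, bg, 10)))
  expect_error(subtract_background(array(0, c(3, 2, 3)), bg, 10), "shape")
})

test_that("physical radii convert to pixel radii with half-up rounding", {
  expect_equal(make_diamond_se(5, resolution_spec(0.7))$r_d_px, 7L)
  expect_equal(make_diamond_se(9, resolution_spec(1))$r_d_px, 9L)
  expect_equal(make_diamond_se(0.2, resolution_spec(1))$r_d_px, 1L)  # floor at 1
  expect_equal(make_diamond_se(2.5, resolution_spec(1))$r_d_px, 3L)  # half rounds up
  expect_error(make_diamond_se(0, resolution_spec(1)), "> 0")
})

test_that("diamond element enumerates the Manhattan ball", {
  se <- make_diamond_se(9, resolution_spec(1))
  expect_equal(se$n_pixels, 181L)
  expect_equal(se$n_pixels, 2L * 9L^2 + 2L * 9L + 1L)
  expect_true(all(abs(se$offsets[, 1]) + abs(se$offsets[, 2]) <= 9))
})

test_that("silhouette length applies the radius-corrected Euclidean distance", {
  res1 <- resolution_spec(1)
  m <- matrix(FALSE, 21, 260)
  m[11, 11:250] <- TRUE
  f <- measure_silhouette(m, m, make_diamond_se(9, res1), res1)
  expect_equal(f$length_cm, 23.0)                         # (250-11-9)*1mm
  res07 <- resolution_spec(0.7)
  m2 <- matrix(FALSE, 21, 140)
  m2[11, 21:121] <- TRUE                                  # x-span 100 px
  f2 <- measure_silhouette(m2, m2, make_diamond_se(5, res07), res07)
  expect_equal(f2$length_cm * 10, (100 - 7) * 0.7)        # 65.1 mm
  # single pixel: span smaller than the radius clamps to zero
  m3 <- matrix(FALSE, 5, 5); m3[3, 3] <- TRUE
  expect_equal(measure_silhouette(m3, m3, make_diamond_se(9, res1), res1)$length_cm, 0)
})

test_that("areas are pixel counts times pixel area", {
  res <- resolution_spec(0.7)
  m <- matrix(FALSE, 40, 40)
  m[1:25, 1:40] <- TRUE                                   # 1000 px
  f <- measure_silhouette(m, m, make_diamond_se(5, res), res)
  expect_equal(f$area_without_tail_mm2, 1000 * 0.49)
  # with-tail mask is a superset, so its area dominates
  big <- m; big[30, 1:10] <- TRUE
  f2 <- measure_silhouette(m, big, make_diamond_se(5, res), res)
  expect_gte(f2$area_with_tail_mm2, f2$area_without_tail_mm2)
})

test_that("run processing takes per-frame maxima over the paw window", {
  spec <- synthetic_rodent_spec(200, species = "rat")
  sr <- render_run(spec, n_frames = 5, seed = 3)
  rs <- process_run(sr$run, sr$tracks)
  expect_equal(rs$window$f_start, 2)
  expect_equal(rs$window$f_stop, 4)
  expect_equal(rs$n_frames_used, nrow(rs$per_frame))
  expect_equal(rs$silhouette_length_cm, max(rs$per_frame$length_cm))
  expect_equal(rs$area_with_tail_mm2, max(rs$per_frame$area_with_tail_mm2))
  expect_true(all(rs$per_frame$area_with_tail_mm2 >=
                    rs$per_frame$area_without_tail_mm2))
  # one-frame window reproduces that frame's values
  one <- process_run(sr$run, paw_tracks(2:3, 2:3, 3, 3))
  expect_equal(one$silhouette_length_cm, one$per_frame$length_cm[1])
})

test_that("widening the frame window never decreases run-level values", {
  spec <- synthetic_rodent_spec(180, species = "rat")
  sr <- render_run(spec, n_frames = 5, seed = 4)
  narrow <- process_run(sr$run, paw_tracks(1:3, 1:3, 3, 3))
  wide <- process_run(sr$run, paw_tracks(1:4, 1:4, 2:4, 2:4))
  expect_gte(wide$silhouette_length_cm, narrow$silhouette_length_cm)
  expect_gte(wide$area_without_tail_mm2, narrow$area_without_tail_mm2)
})

test_that("empty in-window frames are skipped with a warning, all-empty errors", {
  spec <- synthetic_rodent_spec(180, species = "rat")
  sr <- render_run(spec, n_frames = 4, seed = 5)
  run <- sr$run
  run$frames[[3]] <- run$background          # animal absent on frame 3
  expect_warning(rs <- process_run(run, sr$tracks), "skipped")
  expect_equal(rs$n_frames_used, 1L)
  blank <- run_input(list(run$background, run$background, run$background),
                     run$background, run$resolution, species_profile("rat"))
  expect_error(suppressWarnings(process_run(blank, paw_tracks(1:2, 1:2, 2:3, 2:3))),
               "no silhouette")
})

test_that("foreground pixels only shrink through opening", {
  spec <- synthetic_rodent_spec(150, species = "rat")
  sr <- render_run(spec, n_frames = 3, seed = 6)
  fg <- subtract_background(sr$run$frames[[2]], sr$run$background, 10)
  op <- open_remove_tail(fg, spec$se)
  expect_lte(sum(op), sum(fg))
  expect_true(all(which(op) %in% which(fg)))   # opening is anti-extensive
})
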