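test_that("scene configuration enforces acquisition and geometry invariants", {
  expect_error(scene_config(frame_interval_s = 1, exposure_s = 2),
               "frame interval")
  expect_error(scene_config(height_px = 20L), "channel too short")
  expect_error(scene_config(bleach_survival = 0), "bleach_survival")
  expect_error(scene_config(bleach_survival = 1.2), "bleach_survival")
  expect_error(scene_config(fiducial_pos = c(5L, 8L)), "fiducial")
  cfg <- scene_config()
  expect_s3_class(cfg, "scene_config")
  expect_output(print(cfg), "plateau")
})

test_that("generation is deterministic: same config, identical stacks", {
  cfg <- small_config()
  a <- generate_timelapse(cfg)
  b <- generate_timelapse(cfg)
  expect_identical(a$fluor, b$fluor)
  expect_identical(a$bf, b$bf)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("photometric conservation: flux equals unit times emitting count", {
  cfg <- quiet_config()
  sc <- generate_timelapse(cfg)
  bg_total <- sum(sc$truth$background)
  cells <- sc$truth$cells
  rel_err <- vapply(seq_len(dim(sc$fluor)[3]), function(fi) {
    rc <- cells[cells$frame == fi, ]
    want <- rc$intact_fluor * cfg$unit_intensity
    got <- sum(sc$fluor[, , fi]) - bg_total
    abs(got - want) / max(want, 1)
  }, 0)
  expect_lt(max(rel_err), 1e-6)
})

test_that("zero unit intensity leaves background only, with truth intact", {
  cfg <- quiet_config(unit_intensity = 0)
  sc <- generate_timelapse(cfg)
  expect_equal(sc$fluor[, , 10], sc$truth$background, tolerance = 1e-12)
  expect_gt(max(sc$truth$cells$bound_clamps), 0)
  expect_gt(max(sc$truth$cells$total_clamps), 0)
})

test_that("truth bookkeeping: foci inside the cell, drift as applied, phases", {
  cfg <- small_config(drift_per_frame = c(0.05, 0.02))
  sc <- generate_timelapse(cfg)
  cells <- sc$truth$cells
  f1 <- cells[cells$n_foci >= 1, ]
  expect_true(all(f1$f1_row >= f1$row0 & f1$f1_row <= f1$row1))
  f2 <- cells[cells$n_foci == 2, ]
  expect_true(all(f2$f2_row >= f2$row0 & f2$f2_row <= f2$row1))
  expect_true(all(f2$f1_clamps + f2$f2_clamps == f2$bound_clamps))
  expect_equal(sc$truth$drift_applied,
               matrix(round(sc$truth$drift_true), ncol = 2),
               ignore_attr = TRUE)
  # phase labels partition the cycle
  expect_true(all(cells$phase_label[cells$phase < 0] == "pre-initiation"))
  expect_true(all(cells$phase_label[cells$phase > 1] == "post-termination"))
  # bound never exceeds the emitting pool
  expect_true(all(cells$bound_fluor_emit <= cells$intact_fluor + 1e-9))
  # a single focus precedes sister separation, two follow it
  rep_frames <- cells[cells$phase >= 0 & cells$phase <= 1 &
                        cells$bound_clamps > 0, ]
  expect_true(all(rep_frames$n_foci[rep_frames$phase <
                                      cfg$sister_sep_frac] == 1))
  expect_true(all(rep_frames$n_foci[rep_frames$phase >=
                                      cfg$sister_sep_frac] == 2))
})

test_that("cycle timing draws respect the configured truncated normals", {
  cfg <- scene_config(n_cycles = 200L, seed = 3L)
  cyc <- clampdyn:::draw_cycle_times(cfg)
  expect_true(all(cyc$t_rep_s / 60 >= 40 & cyc$t_rep_s / 60 <= 95))
  expect_true(all(cyc$b_s / 60 >= 5 & cyc$d_s / 60 >= 5))
  expect_lt(abs(mean(cyc$t_rep_s) / 60 - 68), 3 * 10 / sqrt(200))
  expect_lt(abs(mean(cyc$t_double_s) / 60 - 84.3), 1.5)
})

test_that("simulated on-times: censoring, quantization and competing risks", {
  # no bleaching, effectively infinite dwell: everything right-censored
  s <- simulate_on_times(50, 1e12, Inf, 5, movie_length = 100, seed = 1)
  expect_true(all(s$censored))
  expect_true(all(s$on_times == 100))
  # observed time quantizes up to the frame grid
  s2 <- simulate_on_times(2000, 195, 500, 5, movie_length = 1e5, seed = 2)
  expect_true(all(s2$on_times %% 5 == 0))
  tt <- attr(s2, "truth")
  expect_true(all(s2$on_times[!s2$censored] - tt$t_true[!s2$censored] >= 0))
  expect_true(all(s2$on_times[!s2$censored] - tt$t_true[!s2$censored] < 5))
  # competing exponential risks: mean of the minimum is the harmonic sum
  want <- 1 / (1 / 195 + 1 / 500)
  expect_lt(abs(mean(tt$t_true) - want), 3 * want / sqrt(2000))
})

test_that("PALM movie: pre-activation frame, spot lifetime, truth linkage", {
  cfg <- scene_config(seed = 2L)
  mov <- generate_palm_movie(cfg, t_unload = 100, n_spots = 9,
                             t_bleach_wall = 400, n_frames = 30L, seed = 4)
  expect_identical(dim(mov$stack)[3], 31L)
  tt <- mov$truth
  expect_identical(nrow(tt), 9L)
  # all spots inside their cells
  for (i in seq_len(9)) expect_gt(mov$cell_mask[tt$row[i], tt$col[i]], 0L)
  # pre-activation frame holds no spot signal: compare local intensity
  for (i in which(tt$on_frames >= 3)) {
    pre <- spot_photometry(mov$stack[, , 1], tt[i, ])
    on <- spot_photometry(mov$stack[, , 2], tt[i, ])
    expect_gt(on, pre + 500)
    # and after disappearance the signal is gone
    foff <- tt$on_frames[i] + 2L
    if (foff + 1L <= 31L) {
      off <- spot_photometry(mov$stack[, , foff + 1L], tt[i, ])
      expect_lt(off, on / 2)
    }
  }
})

test_that("calibration field: isolation, recovery, stepwise bleaching", {
  # empty field is pure background
  f0 <- generate_calibration_field(500, 0, seed = 1)
  expect_lt(abs(mean(f0$stack) - 30), 2)
  # isolated spots at the configured separation
  f <- generate_calibration_field(500, 200, seed = 2)
  expect_gte(min(stats::dist(f$truth[, c("row", "col")])), 12)
  ph <- spot_photometry(f$stack[, , 1], f$truth)
  expect_lt(abs(mean(ph) / 500 - 1), 0.02)
  # stack variant bleaches in single downward steps of ~one unit
  fs <- generate_calibration_field(500, 40, n_frames = 25L, survival = 0.9,
                                   seed = 3)
  bl <- fs$truth[!is.na(fs$truth$bleach_frame) &
                   fs$truth$bleach_frame %in% 5:20, ]
  expect_gt(nrow(bl), 5)
  steps <- vapply(seq_len(nrow(bl)), function(i) {
    tr <- vapply(seq_len(25), function(fr)
      spot_photometry(fs$stack[, , fr], bl[i, ]), 0)
    bf <- bl$bleach_frame[i]
    mean(tr[seq_len(bf)]) - mean(tr[(bf + 1L):25])
  }, 0)
  expect_lt(abs(mean(steps) / 500 - 1), 0.1)
})

test_that("scene TIFF round trip preserves pixel values and truth files", {
  cfg <- quiet_config()
  sc <- generate_timelapse(cfg)
  dir <- tempfile("scene")
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  back <- read_stack(file.path(dir, "fluorescence.tif"))
  expect_identical(dim(back), dim(sc$fluor))
  expect_lt(max(abs(back - pmin(pmax(sc$fluor, 0), 65535))), 1.01)
  truth <- utils::read.csv(file.path(dir, "truth_cells.csv"))
  expect_identical(nrow(truth), nrow(sc$truth$cells))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(meta$intensity_scale, 65535L)
  unlink(dir, recursive = TRUE)
})
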