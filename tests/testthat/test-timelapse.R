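test_that("rolling-ball background subtraction removes smooth background", {
  # constant frame vanishes exactly
  expect_equal(subtract_background(matrix(120, 40, 30), 15),
               matrix(0, 40, 30))
  expect_error(subtract_background(matrix(1, 5, 5), 0), "positive")
  # a PSF-sized spot on a sloped background keeps its integral
  h <- 48; w <- 30
  plane <- outer(seq_len(h), seq_len(w), function(r, c) 100 + 0.5 * r + 0.3 * c)
  lay <- matrix(0, h, w); lay[24, 15] <- 2000
  frame <- plane + EBImage::filter2(lay, clampdyn:::psf_kernel(1.3))
  out <- subtract_background(frame, 15)
  # integrate the spot locally above the residual floor (morphological
  # background estimation leaves a small plane residual near borders)
  floor_lvl <- stats::median(out[1:10, 1:10])
  spot_sum <- sum(out[18:30, 9:21] - floor_lvl)
  expect_lt(abs(spot_sum - 2000) / 2000, 0.05)
  # under shot noise the residual off-structure stays at the noise scale
  set.seed(1)
  noisy <- matrix(stats::rpois(40 * 30, 100), 40, 30)
  res <- subtract_background(noisy, 15)
  expect_lt(stats::median(res), 30)   # well below the background level
  expect_gt(mean(res), 0)             # clipped at zero, biased high not low
})

test_that("illumination correction flattens a beam-modulated scene", {
  frame <- matrix(200, 40, 30)
  expect_equal(correct_illumination(frame, matrix(1, 40, 30)), frame)
  expect_equal(correct_illumination(frame, matrix(7, 40, 30)), frame)
  beam <- clampdyn:::beam_image(40, 30, 15)
  corr <- correct_illumination(frame * beam, beam)
  inner <- corr[10:30, 8:22]
  expect_true(all(inner / 200 > 0.98 & inner / 200 < 1.02))
  expect_error(correct_illumination(frame, matrix(0, 40, 30)), "positive")
  bad <- matrix(1, 40, 30); bad[1] <- NaN
  expect_error(correct_illumination(frame, bad), "positive|finite")
  expect_error(correct_illumination(frame, matrix(1, 10, 10)), "shape")
})

test_that("fiducial drift correction recovers applied shifts to 1 px", {
  h <- 40; w <- 30; nf <- 60
  kern <- clampdyn:::psf_kernel(1.3)
  mk_stack <- function(drifts) {
    st <- array(0, dim = c(h, w, nf))
    set.seed(4)
    for (fi in seq_len(nf)) {
      lay <- matrix(0, h, w)
      lay[10 + drifts[fi, 1], 8 + drifts[fi, 2]] <- 3000
      st[, , fi] <- EBImage::filter2(lay, kern) + 100 +
        matrix(stats::rnorm(h * w, 0, 3), h, w)
    }
    st
  }
  region <- list(rows = 7:13, cols = 5:11)
  # zero drift
  st0 <- mk_stack(matrix(0L, nf, 2))
  dr0 <- correct_drift(st0, region)
  expect_true(all(dr0$shifts$drow == 0 & dr0$shifts$dcol == 0))
  # linear drift 0.2 px/frame
  lin <- cbind(round(0.2 * (seq_len(nf) - 1)), 0L)
  dr1 <- correct_drift(mk_stack(lin), region, max_shift = 14)
  expect_true(all(abs(dr1$shifts$drow - lin[, 1]) <= 1))
  # sinusoidal drift, amplitude 3 px (shifts are relative to frame 1)
  sine <- cbind(round(3 * sin(seq_len(nf) / 6)), round(2 * cos(seq_len(nf) / 9)))
  rel <- sweep(sine, 2, sine[1, ])
  dr2 <- correct_drift(mk_stack(sine), region)
  expect_true(all(abs(dr2$shifts$drow - rel[, 1]) <= 1))
  expect_true(all(abs(dr2$shifts$dcol - rel[, 2]) <= 1))
  # losing the fiducial names the frame
  st_lost <- st0
  st_lost[, , 31:nf] <- 100
  expect_error(correct_drift(st_lost, region), "frame 31")
})

test_that("kymograph columns are perpendicular sums over the channel", {
  st <- array(0, dim = c(20, 12, 5))
  st[7, 4, 3] <- 11
  region <- list(rows = 1:20, cols = 3:9)
  k <- build_kymograph(st, region)
  expect_identical(dim(unclass(k)), c(5L, 20L))
  expect_equal(k[3, 7], 11)
  expect_equal(sum(k), 11)
  # exact mass conservation against the raw frames
  set.seed(2)
  st2 <- array(stats::runif(20 * 12 * 5), dim = c(20, 12, 5))
  k2 <- build_kymograph(st2, region)
  for (fi in 1:5)
    expect_equal(sum(k2[fi, ]), sum(st2[, 3:9, fi]), tolerance = 1e-12)
  expect_error(build_kymograph(st, list(rows = integer(0), cols = 1:3)),
               "empty")
})

test_that("line-profile decomposition: conservation, robustness, recovery", {
  set.seed(11)
  # uniform cell: no foci at all
  prof <- c(stats::rnorm(8, 0, 4), stats::rnorm(24, 700, 12),
            stats::rnorm(8, 0, 4))
  d <- decompose_cell(prof, c(9, 32))
  expect_identical(d$foci_count, 0L)
  expect_lt(d$foci, 3 * d$noise + 1e-9)
  # conservation is exact for arbitrary profiles
  for (i in 1:25) {
    p <- stats::runif(40, 0, 50)
    p[15:22] <- p[15:22] + stats::runif(1, 0, 4000)
    dd <- decompose_cell(p, c(10, 30))
    expect_equal(dd$background + dd$cytoplasm + dd$foci, sum(p[10:30]),
                 tolerance = 1e-9)
  }
  # constructed two-focus profile: split recovered within 15%
  g <- function(x0, s) 3000 * s * exp(-((1:40) - x0)^2 / (2 * 1.3^2))
  base <- 50 + 600 * as.numeric(1:40 %in% 10:33)
  prof2 <- base + g(17, 0.45) + g(26, 0.55) + stats::rnorm(40, 0, 8)
  d2 <- decompose_cell(prof2, c(10, 33))
  expect_identical(d2$foci_count, 2L)
  split <- vapply(d2$runs, function(idx) sum(prof2[idx] - 50 - 600), 0)
  tot <- 3000 * sqrt(2 * pi) * 1.3
  expect_lt(abs(d2$foci / tot - 1), 0.1)
  expect_lt(abs(split[1] / (0.45 * tot) - 1), 0.15)
  expect_lt(abs(split[2] / (0.55 * tot) - 1), 0.15)
  # constant offset moves the background estimate, not the foci
  d3 <- decompose_cell(prof2 + 250, c(10, 33))
  expect_equal(d3$bg_per_px, d2$bg_per_px + 250, tolerance = 3)
  expect_lt(abs(d3$foci - d2$foci) / d2$foci, 0.05)
  # degenerate inputs
  expect_error(decompose_cell(prof2, c(10, 10)), "narrower")
  expect_error(decompose_cell(prof2, c(1, 40)), "outside")
})

test_that("cycle segmentation recovers division and replication timing", {
  cfg <- scene_config(n_cycles = 6L, seed = 31L)
  sc <- generate_timelapse(cfg)
  reg <- scene_regions(sc)
  an <- analyze_timelapse(sc$fluor, sc$bf, sc$truth$beam, reg$channel,
                          reg$fiducial, cfg$frame_interval_s,
                          cfg$birth_length_px)
  cyc <- sc$truth$cycles
  sel <- Filter(function(t) isTRUE(t$flags$selected), an$traces)
  expect_gt(length(sel), 1)
  fr_min <- cfg$frame_interval_s / 60
  for (tr in sel) {
    # match the truth cycle by birth frame
    tcyc <- cyc[which.min(abs(cyc$birth_s / cfg$frame_interval_s -
                                tr$birth_frame)), ]
    expect_lt(abs(tr$doubling_min - tcyc$t_double_s / 60), 2 * fr_min + 1e-9)
    expect_lt(abs(tr$replication_min - tcyc$t_rep_s / 60), 2 * fr_min + 1e-9)
  }
  # first and last cycles are not division-bounded
  expect_false(an$traces[[1]]$flags$complete)
  expect_false(an$traces[[length(an$traces)]]$flags$complete)
})

test_that("a movie with no foci yields cycles flagged non-replicating", {
  cfg <- scene_config(n_cycles = 3L, seed = 8L, k_p = 0)
  sc <- generate_timelapse(cfg)
  reg <- scene_regions(sc)
  an <- analyze_timelapse(sc$fluor, sc$bf, sc$truth$beam, reg$channel,
                          reg$fiducial, cfg$frame_interval_s,
                          cfg$birth_length_px)
  expect_gt(length(an$traces), 0)
  expect_true(all(is.na(vapply(an$traces, `[[`, 0L, "initiation_frame"))))
})

test_that("selection flags: truncation, early focus, clean populations", {
  # a trace with a focus in its very first frames fails diffuse-start
  tr <- fake_trace(bound = c(5, rep(20, 10), 0), total = rep(60, 12),
                   init = 1, term = 11)
  tr$present <- c(TRUE, TRUE, rep(TRUE, 9), FALSE)
  tr$frames$length_px <- round(16 * 2^(seq(0, 1, length.out = 12)))
  out <- select_cells(list(tr), birth_length_px = 16)
  expect_false(out[[1]]$flags$diffuse_ends)
  expect_true(out[[1]]$flags$length_ok)
  expect_true(out[[1]]$flags$growth_ok)
  # most complete cycles of a default movie pass all four criteria
  cfg <- scene_config(n_cycles = 8L, seed = 41L)
  sc <- generate_timelapse(cfg)
  reg <- scene_regions(sc)
  an <- analyze_timelapse(sc$fluor, sc$bf, sc$truth$beam, reg$channel,
                          reg$fiducial, cfg$frame_interval_s,
                          cfg$birth_length_px)
  complete <- Filter(function(t) isTRUE(t$flags$complete), an$traces)
  sel <- Filter(function(t) isTRUE(t$flags$selected), complete)
  expect_gte(length(sel) / length(complete), 0.6)
  expect_identical(an$selection_report$n_selected, length(sel))
})

test_that("recovered foci intensity tracks the true bound count", {
  cfg <- scene_config(n_cycles = 4L, seed = 51L)
  sc <- generate_timelapse(cfg)
  reg <- scene_regions(sc)
  an <- analyze_timelapse(sc$fluor, sc$bf, sc$truth$beam, reg$channel,
                          reg$fiducial, cfg$frame_interval_s,
                          cfg$birth_length_px)
  cells <- sc$truth$cells
  got <- c(); want <- c()
  for (tr in an$traces) {
    if (is.na(tr$initiation_frame)) next
    m <- merge(tr$frames, cells[, c("frame", "bound_fluor_emit", "phase")],
               by = "frame")
    keep <- m$phase > 0.1 & m$phase < 1
    got <- c(got, m$foci[keep]); want <- c(want, m$bound_fluor_emit[keep])
  }
  expect_gt(length(got), 30)
  expect_gt(stats::cor(got, want), 0.9)
})
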