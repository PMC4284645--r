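test_that("a-trous decomposition reconstructs the frame", {
  set.seed(1)
  fr <- matrix(stats::rpois(60 * 50, 100), 60, 50)
  det <- atrous_decompose(fr, 3)
  recon <- Reduce(`+`, det) + attr(det, "smooth")
  expect_equal(recon, fr, tolerance = 1e-10)
  bad <- fr; bad[5, 5] <- NaN
  expect_error(atrous_decompose(bad), "non-finite")
})

test_that("wavelet spot detection: false positives, sensitivity, resolution", {
  set.seed(2)
  # blank shot-noise frames: fewer than 0.1 spurious spots per frame
  fp <- sum(vapply(1:100, function(i) {
    fr <- matrix(stats::rpois(60 * 50, 100), 60, 50) - 100
    nrow(detect_spots(fr, k = 3))
  }, 0L))
  expect_lt(fp / 100, 0.1)
  # a spot with peak ~5x the background noise is almost always found
  kern <- clampdyn:::psf_kernel(1.3)
  hits <- 0L; amp <- 5 * 10 * 2 * pi * 1.3^2   # peak = 5 sd of Poisson(100)
  for (i in 1:200) {
    lay <- matrix(0, 40, 40); lay[20, 20] <- amp
    fr <- matrix(stats::rpois(1600, EBImage::filter2(lay, kern) + 100),
                 40, 40) - 100
    sp <- detect_spots(fr, k = 3)
    if (nrow(sp) && any((sp$row - 20)^2 + (sp$col - 20)^2 < 9)) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.95)
  # two spots 10 px apart resolve into two regions
  lay2 <- matrix(0, 40, 40); lay2[15, 20] <- 3000; lay2[25, 20] <- 3000
  fr2 <- EBImage::filter2(lay2, kern)
  sp2 <- detect_spots(fr2, k = 3)
  expect_identical(nrow(sp2), 2L)
  expect_lt(abs(sum(sp2$intensity) / 6000 - 1), 0.2)
})

test_that("trace building: persistence, on-time recovery, cell rejection", {
  cfg <- scene_config(seed = 3L)
  mov <- generate_palm_movie(cfg, t_unload = 60, n_spots = 12,
                             t_bleach_wall = 1e6, n_frames = 40L,
                             n_outside = 2L, seed = 6)
  traces <- build_traces(mov$stack, mov$cell_mask, mov$frame_interval)
  expect_gt(attr(traces, "n_rejected_outside"), 0)
  tt <- mov$truth
  # each truth spot maps to one trace with the right on-time (+/- 1 frame)
  for (i in seq_len(nrow(tt))) {
    dd <- vapply(traces, function(tr)
      sqrt((tr$pos[1] - tt$row[i])^2 + (tr$pos[2] - tt$col[i])^2), 0)
    j <- which.min(dd)
    expect_lt(dd[j], 2)
    expect_lte(abs(traces[[j]]$on_time_s / 5 - tt$on_frames[i]), 1)
  }
  # a spot alive through the movie end is censored
  mov2 <- generate_palm_movie(cfg, t_unload = 1e9, n_spots = 1,
                              t_bleach_wall = 1e9, n_frames = 25L, seed = 7)
  tr2 <- build_traces(mov2$stack, mov2$cell_mask, mov2$frame_interval)
  expect_identical(length(tr2), 1L)
  expect_true(tr2[[1]]$censored)
  expect_equal(tr2[[1]]$on_time_s, 25 * 5)
})

test_that("single-step filter separates one-step from multi-step traces", {
  set.seed(4)
  noise <- function(n) stats::rnorm(n, 0, 30)
  one <- c(rep(1000, 12), rep(10, 6)) + noise(18)
  expect_true(as.logical(filter_single_step(one)))
  two <- c(rep(2000, 8), rep(1000, 8), rep(10, 6)) + noise(22)
  expect_false(as.logical(filter_single_step(two)))
  up <- c(rep(10, 8), rep(1000, 10)) + noise(18)
  expect_false(as.logical(filter_single_step(up)))
  # partial drop (not to background) is not a clean disappearance
  shallow <- c(rep(1000, 10), rep(600, 8)) + noise(18)
  expect_false(as.logical(filter_single_step(shallow)))
  expect_error(filter_single_step(c(1, 2)), "shorter")
})

test_that("censored-exponential fit: degenerate, consistent, oracle-checked", {
  # all observations equal, fine frames: estimate ~ the common value
  s_eq <- on_time_set(rep(100, 50), frame_interval = 0.1, exposure = 0.05,
                      movie_length = 1000)
  expect_equal(as.numeric(fit_on_times(s_eq)), 100, tolerance = 0.001)
  # fine-frame uncensored limit equals the sample mean to float precision
  set.seed(6)
  d <- 1e-6
  t_int <- round(stats::rexp(100, 1 / 140) / d) * d + d
  s_fine <- on_time_set(t_int, frame_interval = d, exposure = d / 2,
                        movie_length = 1e9)
  expect_equal(as.numeric(fit_on_times(s_fine)), mean(t_int) - d / 2,
               tolerance = 1e-9)
  # consistency at n = 10^4 with 5 s frames
  s1 <- simulate_on_times(10000, 140, Inf, 5, movie_length = 1e5, seed = 11)
  expect_gt(fit_on_times(s1), 137)
  expect_lt(fit_on_times(s1), 143)
  # heavy right-censoring still recovers the constant within 5%
  s2 <- simulate_on_times(10000, 140, Inf, 5, movie_length = 100, seed = 12)
  expect_gt(mean(s2$censored), 0.4)
  fit2 <- as.numeric(fit_on_times(s2))
  expect_lt(abs(fit2 / 140 - 1), 0.05)
  # brute-force grid maximization of the censored likelihood agrees
  grid <- seq(60, 300, by = 0.25)
  ll <- vapply(grid, function(tau) clampdyn:::on_time_loglik(tau, s2), 0)
  expect_lt(abs(grid[which.max(ll)] - fit2), 0.5)
  # independent route: survival-package exponential fit on interval data
  lower <- ifelse(s2$censored, s2$on_times, pmax(s2$on_times - 5, 0.01))
  surv_fit <- survival::survreg(
    survival::Surv(lower, s2$on_times,
                   ifelse(s2$censored, 0, 3), type = "interval") ~ 1,
    dist = "exponential")
  expect_lt(abs(exp(stats::coef(surv_fit)) / fit2 - 1), 0.02)
  # an all-censored set cannot be fitted
  s3 <- on_time_set(rep(50, 20), 5, 0.4, censored = rep(TRUE, 20),
                    movie_length = 50)
  expect_error(fit_on_times(s3), "censored")
})

test_that("bleach constant: duty-cycle scaling and fast-movie recovery", {
  fast <- simulate_on_times(800, 1e9, 70, 0.7, movie_length = 700,
                            exposure = 0.4, seed = 13)
  bt <- bleach_time(fast, duty = 1)
  # duty 1: wall clock equals the exposure-domain constant
  expect_equal(bt$t_bleach_wall, bt$t_bleach_exposure)
  # exposure-domain constant: wall-clock 70 s at duty 0.4/0.7
  expect_lt(abs(bt$t_bleach_exposure / (70 * 0.4 / 0.7) - 1), 0.1)
  # slow-movie rescaling: 40 s of illumination at duty 0.08 -> 500 s
  bt2 <- list(t_bleach_exposure = 40)
  expect_equal(40 / 0.08, 500)
  bt3 <- bleach_time(fast, duty = 0.4 / 5)
  expect_lt(abs(bt3$t_bleach_wall / (bt3$t_bleach_exposure / 0.08) - 1),
            1e-9)
  expect_error(bleach_time(fast, duty = 0), "duty")
  expect_error(bleach_time(fast, duty = 1.5), "duty")
})

test_that("bleach-corrected unloading time and its bootstrap interval", {
  s <- simulate_on_times(84, 195, 500, 5, movie_length = 600, seed = 14)
  t_obs <- fit_on_times(s)
  # no bleaching: the unloading time is the observed constant
  est_inf <- unloading_time(t_obs, Inf, s, B = 200, seed = 1)
  expect_equal(est_inf$t_unload, as.numeric(t_obs))
  # rate subtraction at the designed operating point
  expect_equal(1 / (1 / 140.3 - 1 / 500), 195.1, tolerance = 0.1)
  est <- unloading_time(t_obs, 500, s, B = 500, seed = 2)
  expect_true(est$ci[1] < est$t_unload & est$t_unload < est$ci[2])
  expect_output(print(est), "bootstrap CI")
  # bleaching-dominated data are refused
  expect_error(unloading_time(600, 500, s, B = 10), "bleaching-dominated")
})

test_that("rate additivity round-trip is unbiased at large n", {
  s <- simulate_on_times(10000, 195, 500, 5, movie_length = 3000, seed = 15)
  t_obs <- fit_on_times(s)
  t_un <- 1 / (1 / t_obs - 1 / 500)
  expect_lt(abs(t_un / 195 - 1), 0.05)
})

test_that("bootstrap CI coverage is near nominal at n = 84", {
  cov <- 0L; n_rep <- 200L
  for (i in seq_len(n_rep)) {
    st <- simulate_on_times(84, 195, 500, 5, movie_length = 600,
                            seed = 5000 + i)
    est <- unloading_time(fit_on_times(st), 500, st, B = 300, seed = i)
    if (est$ci[1] <= 195 && 195 <= est$ci[2]) cov <- cov + 1L
  }
  expect_gte(cov / n_rep, 0.92)
  expect_lte(cov / n_rep, 0.98)
})

test_that("PALM movie pipeline recovers the unloading time end to end", {
  cfg <- scene_config(seed = 9L)
  mov <- generate_palm_movie(cfg, t_unload = 195, n_spots = 84,
                             t_bleach_wall = 500, seed = 21)
  pa <- analyze_palm(mov, t_bleach_wall = 500, B = 400, seed = 3)
  expect_identical(pa$estimate$n_obs, length(pa$traces))
  expect_gte(length(pa$traces), 75)
  # the movie-derived estimate agrees with fitting the truth on-times
  truth_set <- mov$on_times
  t_truth <- 1 / (1 / fit_on_times(truth_set) - 1 / 500)
  expect_lt(abs(pa$estimate$t_unload - t_truth) / t_truth, 0.15)
  expect_true(pa$estimate$ci[1] < 195 & 195 < pa$estimate$ci[2])
})
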