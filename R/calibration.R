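#' Single-fluorophore intensity standard from calibration fields
#'
#' Detects isolated single-molecule spots in one or more calibration fields
#' (wavelet detection), measures each by aperture photometry, and takes a
#' trimmed mean as the unit intensity `I1` (camera counts per fluorophore per
#' frame). Spots closer than `min_sep` to a neighbour are discarded so the
#' photometry apertures do not overlap.
#'
#' @param fields a single field (matrix), a stack (array, first frame used),
#'   or a list of either.
#' @param exposure_s acquisition exposure of the fields, s.
#' @param trim trim fraction of the trimmed mean (default 0.1).
#' @param min_sep isolation distance, px.
#' @param radius photometry box half-width.
#' @param k detection threshold multiplier.
#' @return object of class `calibration_standard`: `I1`, `sem`, `n_spots`,
#'   `exposure_s`.
#' @export
unit_intensity <- function(fields, exposure_s, trim = 0.1, min_sep = 10,
                           radius = 4L, k = 3) {
  if (!is.list(fields)) fields <- list(fields)
  ints <- numeric(0)
  for (f in fields) {
    fr <- if (length(dim(f)) == 3L) f[, , 1] else f
    fr_bg <- subtract_background(fr, ball_radius_px = 8)
    sp <- detect_spots(fr_bg, k = k)
    if (!nrow(sp)) next
    if (nrow(sp) > 1) {
      dd <- as.matrix(stats::dist(sp[, c("row", "col")]))
      diag(dd) <- Inf
      sp <- sp[apply(dd, 1, min) > min_sep, , drop = FALSE]
    }
    if (nrow(sp)) ints <- c(ints, spot_photometry(fr, sp, radius))
  }
  if (length(ints) < 10)
    stop("calibration error: only ", length(ints),
         " isolated spots found (need >= 10)")
  i1 <- mean(ints, trim = trim)
  structure(list(I1 = i1,
                 sem = stats::sd(ints) / sqrt(length(ints)),
                 n_spots = length(ints), exposure_s = exposure_s),
            class = "calibration_standard")
}

#' @export
print.calibration_standard <- function(x, ...) {
  cat(sprintf(
    "Single-fluorophore standard: I1 = %.4g +/- %.2g counts/frame (n = %d, %g s exposure)\n",
    x$I1, x$sem, x$n_spots, x$exposure_s))
  invisible(x)
}

#' Rescale a calibration standard to a different exposure
#'
#' Emitted counts are linear in exposure time.
#'
#' @param standard a `calibration_standard`.
#' @param exposure_s target exposure, s.
#' @return a rescaled `calibration_standard`.
#' @export
scale_standard <- function(standard, exposure_s) {
  stopifnot(inherits(standard, "calibration_standard"), exposure_s > 0)
  f <- exposure_s / standard$exposure_s
  structure(list(I1 = standard$I1 * f, sem = standard$sem * f,
                 n_spots = standard$n_spots, exposure_s = exposure_s),
            class = "calibration_standard")
}

#' Photobleaching correction of an intensity trace
#'
#' Multiplies the intensity at frame `n` (0-based count of fluorescence
#' exposures since the start of the movie) by `p^(-n)`, undoing geometric
#' per-exposure bleaching with survival probability `p`.
#'
#' @param intensity numeric vector.
#' @param p per-exposure survival probability in (0, 1].
#' @param frame_index 0-based exposure indices (default `0:(length-1)`); pass
#'   the global movie frame indices when the trace is a window of a longer
#'   movie.
#' @return corrected trace with the correction factors as attribute
#'   `factors`.
#' @export
bleach_correction <- function(intensity, p, frame_index = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("survival probability p must be in (0, 1]")
  if (is.null(frame_index)) frame_index <- seq_along(intensity) - 1
  if (length(frame_index) != length(intensity))
    stop("frame_index length mismatch")
  fac <- p^(-frame_index)
  structure(intensity * fac, factors = fac)
}

#' Unbleached fraction across a cycle for a cell in balanced growth
#'
#' In steady exponential growth, content doubles every cycle while each
#' existing fluorophore survives an exposure with probability `p`; newly
#' synthesized fluorophores enter intact and a daughter inherits its
#' mother's unbleached fraction. Iterating the discrete balance
#' `I[n+1] = p I[n] + (N[n+1] - N[n])` with `N[n] = N0 * 2^(n/T)` to its
#' generation-to-generation fixed point yields the expected unbleached
#' fraction at every frame of the cycle — nearly constant, close to the
#' continuous-limit value `g/(g - log(p))` with `g = log(2)/T`. Dividing a
#' measured trace by these fractions is the photobleaching correction
#' appropriate for a growing cell; the naive `p^(-n)` of
#' [bleach_correction()] is exact only for a fixed cohort of fluorophores
#' (constant content).
#'
#' @param p per-exposure survival probability in (0, 1].
#' @param n_frames frames per cycle (content doubles over these).
#' @param tol convergence tolerance of the fixed point.
#' @return numeric vector of length `n_frames`: expected unbleached fraction
#'   at frames `0..n_frames-1` of the cycle.
#' @export
bleach_equilibrium_fractions <- function(p, n_frames, tol = 1e-12) {
  if (!is.numeric(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  stopifnot(n_frames >= 1)
  if (p == 1 || n_frames == 1) return(rep(1, n_frames))
  T <- n_frames - 1L
  N <- 2^((0:T) / T)
  f0 <- 1
  repeat {
    I <- numeric(T + 1L)
    I[1] <- f0 * N[1]
    for (n in seq_len(T)) I[n + 1L] <- p * I[n] + (N[n + 1L] - N[n])
    f_end <- I[T + 1L] / N[T + 1L]
    if (abs(f_end - f0) < tol) break
    f0 <- f_end
  }
  I / N
}

#' Convert intensity to absolute molecule numbers
#'
#' Divides by the single-fluorophore unit intensity; for a homodimeric
#' protein labelled on both subunits the fluorophore count is halved to give
#' the dimer (complex) count. First-order uncertainty from the standard's
#' s.e.m. is attached.
#'
#' @param intensity numeric (counts).
#' @param standard a `calibration_standard` (exposure-matched; use
#'   [scale_standard()] otherwise).
#' @param dimeric halve the fluorophore count (default TRUE).
#' @return molecule counts with attribute `se`.
#' @export
to_molecules <- function(intensity, standard, dimeric = TRUE) {
  if (!inherits(standard, "calibration_standard"))
    stop("calibration error: missing or invalid standard")
  n <- intensity / standard$I1
  if (dimeric) n <- n / 2
  structure(n, se = abs(n) * standard$sem / standard$I1)
}

#' Convert a decomposed cycle trace to molecule counts
#'
#' Applies photobleaching correction and the intensity calibration to the
#' foci and total (cytoplasm + foci) intensities of a segmented cell-cycle
#' trace. Exposures are counted from the trace's own first frame: in a
#' growing cell continuous synthesis holds the unbleached fraction near a
#' generation-to-generation equilibrium, so counting from the movie start
#' would over-correct ever more strongly for later generations, while the
#' within-cycle count leaves only a small (percent-level) residual bias from
#' synthesis dilution and the inherited pre-bleached pool.
#'
#' @param trace a `cell_cycle_trace` from [segment_cycles()].
#' @param standard a `calibration_standard`.
#' @param survival per-exposure survival probability.
#' @param dimeric report dimer counts (default TRUE).
#' @param mode `"equilibrium"` (default) divides by the balanced-growth
#'   unbleached fractions of [bleach_equilibrium_fractions()];
#'   `"geometric"` applies the fixed-cohort `p^(-n)` of
#'   [bleach_correction()] counted from the trace's first frame.
#' @return the trace with a `molecules` data.frame added: per-frame `bound`,
#'   `total`, `bound_fraction`.
#' @export
quantify_trace <- function(trace, standard, survival, dimeric = TRUE,
                           mode = c("equilibrium", "geometric")) {
  stopifnot(inherits(trace, "cell_cycle_trace"))
  mode <- match.arg(mode)
  raw_foci <- trace$frames$foci
  raw_tot <- trace$frames$cytoplasm + trace$frames$foci
  if (mode == "equilibrium") {
    f <- bleach_equilibrium_fractions(survival, nrow(trace$frames))
    foci_c <- raw_foci / f
    tot_c <- raw_tot / f
  } else {
    gi <- trace$frames$frame - trace$frames$frame[1]  # exposures since birth
    foci_c <- bleach_correction(raw_foci, survival, gi)
    tot_c <- bleach_correction(raw_tot, survival, gi)
  }
  bound <- as.numeric(to_molecules(foci_c, standard, dimeric))
  total <- as.numeric(to_molecules(tot_c, standard, dimeric))
  trace$molecules <- data.frame(
    frame = trace$frames$frame, bound = bound, total = total,
    bound_fraction = ifelse(total > 0, bound / total, NA_real_))
  trace
}

#' Align single-cell traces on replication phase and average
#'
#' Resamples each quantified trace onto a normalized replication phase in
#' [0, 1] (0 = initiation, 1 = termination) by linear interpolation, and
#' returns pointwise population means with s.e.m., plateau statistics over a
#' phase window, and the averaged bound-fraction curve (computed per cell,
#' then averaged).
#'
#' @param traces list of traces processed by [quantify_trace()]; traces
#'   without both initiation and termination are excluded (logged in the
#'   result).
#' @param n_grid number of phase points (default 101).
#' @param plateau_window phase window for the plateau statistics
#'   (default c(0.3, 0.9), i.e. the central two thirds of replication).
#' @return object of class `population_curves`: `phase`, `bound_mean`,
#'   `bound_sem`, `total_mean`, `fraction_mean`, `plateau` (mean, sd, sem,
#'   n), `n_traces`, `n_excluded`.
#' @export
align_and_average <- function(traces, n_grid = 101L,
                              plateau_window = c(0.3, 0.9)) {
  usable <- Filter(function(t) !is.null(t$molecules) &&
                     !is.na(t$initiation_frame) &&
                     !is.na(t$termination_frame) &&
                     t$termination_frame > t$initiation_frame, traces)
  n_exc <- length(traces) - length(usable)
  if (length(usable) < 2)
    stop("need at least 2 traces with defined initiation and termination")
  phase <- seq(0, 1, length.out = n_grid)
  bound <- total <- frac <- matrix(NA_real_, length(usable), n_grid)
  plateau_cell <- numeric(length(usable))
  pooled <- numeric(0)
  for (i in seq_along(usable)) {
    tr <- usable[[i]]
    ph <- (tr$molecules$frame - tr$initiation_frame) /
      (tr$termination_frame - tr$initiation_frame)
    bound[i, ] <- stats::approx(ph, tr$molecules$bound, xout = phase,
                                rule = 2)$y
    total[i, ] <- stats::approx(ph, tr$molecules$total, xout = phase,
                                rule = 2)$y
    frac[i, ] <- stats::approx(ph, tr$molecules$bound_fraction, xout = phase,
                               rule = 2)$y
    win <- ph >= plateau_window[1] & ph <= plateau_window[2]
    plateau_cell[i] <- mean(tr$molecules$bound[win])
    pooled <- c(pooled, tr$molecules$bound[win])
  }
  n <- length(usable)
  structure(list(
    phase = phase,
    bound_mean = colMeans(bound), bound_sem = apply(bound, 2, stats::sd) /
      sqrt(n),
    total_mean = colMeans(total),
    fraction_mean = colMeans(frac),
    plateau = list(mean = mean(plateau_cell),
                   sd = stats::sd(pooled),
                   sem = stats::sd(pooled) / sqrt(n),
                   per_cell = plateau_cell, n = n),
    plateau_window = plateau_window,
    n_traces = n, n_excluded = n_exc),
    class = "population_curves")
}

#' @export
print.population_curves <- function(x, ...) {
  cat(sprintf("Population curves from %d aligned traces (%d excluded)\n",
              x$n_traces, x$n_excluded))
  cat(sprintf(
    "  plateau (phase %.2g-%.2g): %.4g bound clamps (s.d. %.3g, s.e.m. %.3g)\n",
    x$plateau_window[1], x$plateau_window[2],
    x$plateau$mean, x$plateau$sd, x$plateau$sem))
  cat(sprintf("  bound fraction at mid-replication: %.3g\n",
              x$fraction_mean[which.min(abs(x$phase - 0.5))]))
  invisible(x)
}

#' @export
plot.population_curves <- function(x, ...) {
  graphics::plot(x$phase, x$bound_mean, type = "l", lwd = 2, col = 2,
                 xlab = "replication phase", ylab = "molecules",
                 ylim = c(0, max(x$total_mean, na.rm = TRUE)), ...)
  graphics::lines(x$phase, x$total_mean, lwd = 2, col = 4)
  graphics::legend("topleft", c("DNA-bound", "total"), col = c(2, 4), lwd = 2,
                   bty = "n")
  invisible(x)
}
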