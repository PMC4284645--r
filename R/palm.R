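#' A-trous B3-spline wavelet decomposition
#'
#' Undecimated wavelet transform with the separable B3-spline kernel
#' (1,4,6,4,1)/16 and holes doubling at each level; detail plane j is the
#' difference between successive smoothed planes.
#'
#' @param frame numeric matrix.
#' @param levels number of detail planes.
#' @return list of detail matrices (length `levels`) with the final smooth
#'   plane as attribute `smooth`.
#' @export
atrous_decompose <- function(frame, levels = 3L) {
  if (any(!is.finite(frame))) stop("non-finite pixels in frame")
  b3 <- c(1, 4, 6, 4, 1) / 16
  cur <- frame
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    step <- 2^(j - 1)
    sm <- atrous_smooth(cur, b3, step)
    details[[j]] <- cur - sm
    cur <- sm
  }
  attr(details, "smooth") <- cur
  details
}

# separable convolution with a holed kernel, mirror boundary
atrous_smooth <- function(m, k, step) {
  off <- (seq_along(k) - (length(k) + 1) / 2) * step
  h <- nrow(m); w <- ncol(m)
  reflect <- function(i, n) {
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1L, 2 * n - i)
  }
  tmp <- matrix(0, h, w)
  for (a in seq_along(k)) tmp <- tmp + k[a] * m[reflect(seq_len(h) + off[a], h), ]
  out <- matrix(0, h, w)
  for (a in seq_along(k)) out <- out + k[a] * tmp[, reflect(seq_len(w) + off[a], w)]
  out
}

#' Detect diffraction-limited spots by multiscale wavelet thresholding
#'
#' Each detail plane is hard-thresholded at `k` times its MAD (scaled to sd);
#' the detection mask is the support of the product of the thresholded planes
#' (scales 2..levels by default, skipping the single-pixel-noise plane).
#' Connected regions of the mask are the spots; each spot's integrated
#' intensity is the sum of the (input) pixel values over its region, and its
#' position the intensity-weighted centroid.
#'
#' @param frame preprocessed numeric matrix (background/illumination
#'   corrected).
#' @param levels wavelet depth (default 3).
#' @param k MAD multiplier (default 3).
#' @param min_px minimum region size in pixels.
#' @param scales which detail planes enter the product (default `2:levels`).
#' @return data.frame with columns row, col (centroid), intensity (mask sum),
#'   n_px; zero rows when nothing is found.
#' @export
detect_spots <- function(frame, levels = 3L, k = 3, min_px = 3L,
                         scales = NULL) {
  det <- atrous_decompose(frame, levels)
  if (is.null(scales)) scales <- if (levels >= 2L) 2:levels else 1L
  mask <- matrix(TRUE, nrow(frame), ncol(frame))
  for (j in scales) {
    w <- det[[j]]
    thr <- k * stats::mad(w)
    mask <- mask & (w > thr)
  }
  if (!any(mask)) return(empty_spots())
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_px) next
    wts <- frame[idx]
    wts <- pmax(wts, 0)
    if (sum(wts) == 0) wts <- rep(1, length(wts))
    out[[i]] <- data.frame(row = sum(idx[, 1] * wts) / sum(wts),
                           col = sum(idx[, 2] * wts) / sum(wts),
                           intensity = sum(frame[idx]), n_px = nrow(idx))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) empty_spots() else out
}

empty_spots <- function()
  data.frame(row = numeric(0), col = numeric(0), intensity = numeric(0),
             n_px = integer(0))

#' Aperture photometry of spots
#'
#' Integrated, background-subtracted intensity in a square box around each
#' position; the local background per pixel is the mean over an annulus
#' between the box and `bg_radius`. The mean is unbiased under shot noise
#' (a median sits ~1/3 count below the Poisson mean, which would bias every
#' spot upward by a third of the box area), and the wide annulus keeps the
#' background term from dominating the photometric variance.
#'
#' @param frame numeric matrix.
#' @param centers matrix/data.frame with columns row, col.
#' @param radius half-width of the integration box (default 4, ~3 sigma for
#'   a 1.3 px PSF).
#' @param bg_radius half-width of the background annulus outer box.
#' @return numeric vector of integrated intensities.
#' @export
spot_photometry <- function(frame, centers, radius = 4L, bg_radius = 8L) {
  centers <- as.matrix(centers[, c("row", "col"), drop = FALSE])
  h <- nrow(frame); w <- ncol(frame)
  vapply(seq_len(nrow(centers)), function(i) {
    r <- round(centers[i, 1]); c <- round(centers[i, 2])
    rr <- max(1, r - radius):min(h, r + radius)
    cc <- max(1, c - radius):min(w, c + radius)
    rr2 <- max(1, r - bg_radius):min(h, r + bg_radius)
    cc2 <- max(1, c - bg_radius):min(w, c + bg_radius)
    inner <- matrix(FALSE, length(rr2), length(cc2))
    inner[rr2 %in% rr, cc2 %in% cc] <- TRUE
    ring <- frame[rr2, cc2][!inner]
    sum(frame[rr, cc]) - mean(ring) * length(rr) * length(cc)
  }, 0)
}

#' Follow detected spots through a PALM movie
#'
#' Detects spots frame by frame (frame 1 is treated as the pre-activation
#' frame and skipped), associates detections to traces by nearest position
#' within a gate radius, rejects spots outside cells, and ends a trace after
#' `gap` consecutive missed frames. Intensities along a trace are measured by
#' aperture photometry at the locked (first-detection) position.
#'
#' @param stack movie array (row x col x frame).
#' @param cell_mask integer label matrix (0 = outside all cells); spots on
#'   label 0 are rejected.
#' @param frame_interval frame spacing, s.
#' @param gate_radius association gate, px.
#' @param gap consecutive missed detections that terminate a trace.
#' @param k,levels detection parameters (see [detect_spots()]).
#' @param preprocess function applied to every frame before detection
#'   (default: rolling-ball background subtraction).
#' @return list of `spot_trace` objects: position, first/last visible frame
#'   (1-based, counting the pre-activation frame), per-frame intensities,
#'   on-time (s), censoring flag, in-cell flag; rejected out-of-cell
#'   detections are counted in attribute `n_rejected_outside`.
#' @export
build_traces <- function(stack, cell_mask, frame_interval,
                         gate_radius = 2.5, gap = 2L, k = 3, levels = 3L,
                         preprocess = function(f) subtract_background(f, 8)) {
  d <- dim(stack)
  traces <- list()
  open <- list()   # active traces: pos, first, last_seen, id
  n_out <- 0L
  for (fi in 2:d[3]) {
    fr <- preprocess(stack[, , fi])
    sp <- detect_spots(fr, levels = levels, k = k)
    used <- rep(FALSE, nrow(sp))
    closed <- rep(FALSE, length(open))
    for (oi in seq_along(open)) {
      tr <- open[[oi]]
      if (nrow(sp)) {
        dd <- sqrt((sp$row - tr$pos[1])^2 + (sp$col - tr$pos[2])^2)
        dd[used] <- Inf
        j <- which.min(dd)
      } else j <- integer(0)
      if (length(j) && nrow(sp) && dd[j] <= gate_radius) {
        used[j] <- TRUE
        tr$last_seen <- fi
        tr$miss <- 0L
      } else {
        tr$miss <- tr$miss + 1L
        if (tr$miss >= gap) {
          traces[[length(traces) + 1L]] <- tr
          closed[oi] <- TRUE
        }
      }
      open[[oi]] <- tr
    }
    open <- open[!closed]
    if (nrow(sp)) for (j in which(!used)) {
      pos <- c(sp$row[j], sp$col[j])
      lab <- cell_mask[min(max(round(pos[1]), 1), d[1]),
                       min(max(round(pos[2]), 1), d[2])]
      if (lab == 0L) { n_out <- n_out + 1L; next }
      open[[length(open) + 1L]] <- list(pos = pos, cell = lab,
                                        first = fi, last_seen = fi,
                                        miss = 0L)
    }
  }
  for (tr in open) traces[[length(traces) + 1L]] <- tr
  out <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    frames <- tr$first:tr$last_seen
    ints <- vapply(frames, function(fi)
      spot_photometry(stack[, , fi],
                      data.frame(row = tr$pos[1], col = tr$pos[2])), 0)
    censored <- tr$last_seen >= d[3] - (gap - 1L)
    structure(list(id = i, cell = tr$cell, pos = tr$pos,
                   first_frame = tr$first, last_frame = tr$last_seen,
                   intensity = ints,
                   on_time_s = length(frames) * frame_interval,
                   censored = censored),
              class = "spot_trace")
  })
  attr(out, "n_rejected_outside") <- n_out
  out
}

#' Single-step trace filter
#'
#' Accepts traces whose intensity is flat then drops once to near background:
#' 1-step and 2-step piecewise-constant models are fitted by least squares
#' over all changepoints; the trace is accepted iff the 2-step model does not
#' improve the residual variance beyond an F-ratio threshold and the single
#' fitted step is downward, to below `floor_frac` of the plateau.
#'
#' The supplied intensities should extend a little past the disappearance
#' (e.g. the trace's aperture photometry continued for the `gap` frames), so
#' the post-step level is observable.
#'
#' @param intensity numeric vector (length >= 3).
#' @param f_max maximal variance ratio var1/var2 to still call it one step.
#' @param floor_frac post-step level must be below this fraction of the
#'   plateau.
#' @return TRUE/FALSE with attributes `step_at`, `plateau`, `floor`.
#' @export
filter_single_step <- function(intensity, f_max = 2.5, floor_frac = 0.25) {
  n <- length(intensity)
  if (n < 3L) stop("trace shorter than 3 frames")
  sse1 <- Inf; cp1 <- NA
  for (cpt in 1:(n - 1)) {
    m1 <- mean(intensity[1:cpt]); m2 <- mean(intensity[(cpt + 1):n])
    sse <- sum((intensity[1:cpt] - m1)^2) +
      sum((intensity[(cpt + 1):n] - m2)^2)
    if (sse < sse1) { sse1 <- sse; cp1 <- cpt }
  }
  sse2 <- sse1
  if (n >= 4) for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) {
    m1 <- mean(intensity[1:a]); m2 <- mean(intensity[(a + 1):b])
    m3 <- mean(intensity[(b + 1):n])
    sse <- sum((intensity[1:a] - m1)^2) +
      sum((intensity[(a + 1):b] - m2)^2) +
      sum((intensity[(b + 1):n] - m3)^2)
    if (sse < sse2) sse2 <- sse
  }
  plateau <- mean(intensity[1:cp1])
  floorv <- mean(intensity[(cp1 + 1):n])
  ratio <- if (sse2 > 0) (sse1 / max(n - 3, 1)) / (sse2 / max(n - 5, 1))
           else Inf
  ok <- is.finite(ratio) && ratio <= f_max &&
    plateau > 0 && floorv < floor_frac * plateau
  structure(ok, step_at = cp1, plateau = plateau, floor = floorv)
}

#' Construct a set of single-molecule on-times
#'
#' @param on_times observed on-times, s (multiples of the frame interval).
#' @param frame_interval frame spacing, s.
#' @param exposure exposure per frame, s.
#' @param censored logical vector; censored observations equal the movie
#'   length.
#' @param movie_length movie duration, s.
#' @return object of class `on_time_set`.
#' @export
on_time_set <- function(on_times, frame_interval, exposure,
                        censored = rep(FALSE, length(on_times)),
                        movie_length = max(on_times)) {
  stopifnot(length(censored) == length(on_times), frame_interval > 0,
            exposure > 0, exposure <= frame_interval)
  if (any(on_times <= 0)) stop("on-times must be positive")
  structure(list(on_times = on_times, frame_interval = frame_interval,
                 exposure = exposure, censored = censored,
                 movie_length = movie_length),
            class = "on_time_set")
}

#' @export
print.on_time_set <- function(x, ...) {
  cat(sprintf(
    "On-time set: n = %d (%d censored), frames of %.3g s, movie %.4g s\n",
    length(x$on_times), sum(x$censored), x$frame_interval, x$movie_length))
  cat(sprintf("  mean observed on-time %.4g s\n", mean(x$on_times)))
  invisible(x)
}

# log-likelihood of an interval/right-censored exponential with constant tau;
# an uncensored on-time m*dt means the event fell in ((m-1) dt, m dt]
on_time_loglik <- function(tau, set) {
  dt <- set$frame_interval
  t_obs <- set$on_times
  cens <- set$censored
  ll <- 0
  if (any(!cens)) {
    m <- t_obs[!cens] / dt
    ll <- ll + sum(-(m - 1) * dt / tau + log(-expm1(-dt / tau)))
  }
  if (any(cens)) ll <- ll - sum(t_obs[cens]) / tau
  ll
}

#' Fit the observed disappearance time constant
#'
#' Maximum-likelihood exponential time constant for interval-censored
#' observations (each on-time known to within one frame) with right
#' censoring at the movie end. Because every event interval has the same
#' width (the frame interval `d`), the MLE is closed-form: with
#' `S = sum over uncensored of (m_i - 1) d + sum over censored of T_i` and
#' `n` uncensored observations, `tau = d / log(1 + n d / S)`. In the
#' fine-frame, uncensored limit this reduces to the sample mean.
#'
#' @param set an [on_time_set()].
#' @return fitted time constant `t_obs` in seconds, with the log-likelihood
#'   as attribute.
#' @export
fit_on_times <- function(set) {
  stopifnot(inherits(set, "on_time_set"))
  n_unc <- sum(!set$censored)
  if (n_unc == 0) stop("all observations censored; cannot fit")
  if (n_unc < 10)
    warning("fewer than 10 uncensored observations; fit unstable")
  d <- set$frame_interval
  m <- set$on_times[!set$censored] / d
  s <- sum((m - 1) * d) + sum(set$on_times[set$censored])
  tau <- if (s <= 0) d / log(1 + n_unc)  # all events in the first frame
         else d / log1p(n_unc * d / s)
  structure(tau, loglik = on_time_loglik(tau, set))
}

#' Wall-clock photobleaching time constant from a fast bleaching movie
#'
#' Fits the observed disappearance constant of a fast-frame-rate movie in
#' which unloading is negligible, converts it to the illumination (exposure)
#' domain using the fast movie's duty cycle, and rescales to the wall clock
#' of the slow unloading movie via its duty cycle
#' (`t_bleach_wall = t_bleach_exposure / duty`).
#'
#' @param fast_set an [on_time_set()] from the fast movie.
#' @param duty duty cycle of the slow movie (exposure / frame interval),
#'   in (0, 1].
#' @return list with `t_bleach_exposure` (s of illumination),
#'   `t_bleach_wall` (s, slow movie), `t_obs_fast`.
#' @export
bleach_time <- function(fast_set, duty) {
  if (!is.numeric(duty) || duty <= 0 || duty > 1)
    stop("duty must be in (0, 1]")
  t_fast <- as.numeric(fit_on_times(fast_set))
  duty_fast <- fast_set$exposure / fast_set$frame_interval
  t_exp <- t_fast * duty_fast
  list(t_bleach_exposure = t_exp, t_bleach_wall = t_exp / duty,
       t_obs_fast = t_fast)
}

#' Bleach-corrected unloading time with bootstrap confidence interval
#'
#' Disappearance is the first of two independent exponential processes
#' (unloading and photobleaching), so the rates add:
#' `1/t_obs = 1/t_unload + 1/t_bleach_wall`. The unloading time is obtained
#' by rate subtraction and its confidence interval by case-resampling the
#' on-time set, refitting, and applying the same correction.
#'
#' @param t_obs fitted observed time constant, s (from [fit_on_times()]).
#' @param t_bleach_wall wall-clock bleaching constant, s (may be `Inf`).
#' @param set the [on_time_set()] behind `t_obs` (for the bootstrap).
#' @param B number of bootstrap replicates (default 10000).
#' @param seed RNG seed (recorded).
#' @param conf confidence level (default 0.95, percentile CI).
#' @return object of class `unload_estimate`.
#' @export
unloading_time <- function(t_obs, t_bleach_wall, set, B = 10000L, seed = 1L,
                           conf = 0.95) {
  t_obs <- as.numeric(t_obs)
  if (t_obs >= t_bleach_wall)
    stop("bleaching-dominated: t_obs >= t_bleach_wall, unloading unresolvable")
  invert <- function(tob) 1 / (1 / tob - 1 / t_bleach_wall)
  t_unload <- invert(t_obs)
  set.seed(seed)
  n <- length(set$on_times)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bset <- on_time_set(set$on_times[idx], set$frame_interval, set$exposure,
                        set$censored[idx], set$movie_length)
    if (all(bset$censored)) next
    tb <- suppressWarnings(as.numeric(fit_on_times(bset)))
    boot[b] <- if (tb < t_bleach_wall) invert(tb) else NA_real_
  }
  ok <- boot[is.finite(boot)]
  a <- (1 - conf) / 2
  ci <- stats::quantile(ok, c(a, 1 - a), names = FALSE)
  structure(list(t_obs = t_obs, t_bleach_wall = t_bleach_wall,
                 t_unload = t_unload, ci = ci, conf = conf,
                 boot = boot, n_obs = n, B = B, seed = seed),
            class = "unload_estimate")
}

#' @export
print.unload_estimate <- function(x, ...) {
  cat("Clamp unloading-time estimate (bleach-corrected)\n")
  cat(sprintf("  observed disappearance constant : %.4g s (n = %d)\n",
              x$t_obs, x$n_obs))
  cat(sprintf("  wall-clock bleaching constant   : %.4g s\n",
              x$t_bleach_wall))
  cat(sprintf("  unloading time t_unload         : %.4g s\n", x$t_unload))
  cat(sprintf("  %d%% bootstrap CI               : [%.4g, %.4g] s (B = %d)\n",
              round(100 * x$conf), x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' @export
plot.unload_estimate <- function(x, ...) {
  ok <- x$boot[is.finite(x$boot)]
  graphics::hist(ok, breaks = 50, main = "Bootstrap unloading times",
                 xlab = "t_unload (s)", ...)
  graphics::abline(v = x$t_unload, col = 2, lwd = 2)
  graphics::abline(v = x$ci, col = 4, lty = 2)
  invisible(x)
}

#' Write an unloading estimate as JSON
#'
#' @param est an `unload_estimate`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_estimate_json <- function(est, path) {
  stopifnot(inherits(est, "unload_estimate"))
  jsonlite::write_json(list(
    t_obs_s = est$t_obs, t_bleach_wall_s = est$t_bleach_wall,
    t_unload_s = est$t_unload,
    ci = as.numeric(est$ci), conf = est$conf,
    n = est$n_obs, bootstrap = est$B, seed = est$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
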