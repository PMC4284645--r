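#' Configuration of the synthetic mother-machine scene
#'
#' Describes everything the synthetic time-lapse generator needs: channel and
#' cell geometry, the cell-cycle timing model, the bound-clamp kinetics, the
#' total-content curve, optics, photometry, background, illumination, drift,
#' noise and photobleaching. Defaults emulate slow-growth conditions for rod
#' shaped bacteria in dead-end growth channels imaged every 2.5 min at 80 ms
#' exposure on an EMCCD with 160 nm pixels.
#'
#' Counts are kept in clamp (dimer) units: each clamp carries two fluorophore
#' fusions, so a total-content curve running from `total_start = 60` to
#' `total_end = 120` clamps corresponds to 120 to 240 fluorophores. The
#' bound-clamp dynamics follow the birth-death model of [kinetic_params()]
#' with loading rate `k_p` and unloading time `t_unload`; per-cell replication
#' durations and the flanking birth-to-initiation (B) and termination-to-
#' division (D) periods are drawn from truncated normal distributions, so the
#' configured mean doubling time is `b_mean + t_rep_mean + d_mean`.
#'
#' @param n_cycles number of consecutive mother-cell cycles to simulate.
#' @param height_px,width_px image dimensions; the growth channel runs along
#'   rows (row 1 is the closed end).
#' @param pixel_nm pixel size in nm.
#' @param frame_interval_s,exposure_s acquisition timing, seconds.
#' @param cell_width_px width of the cell (and channel) footprint in columns.
#' @param birth_length_px cell length at birth, pixels.
#' @param t_rep_mean_min,t_rep_sd_min per-cell replication duration (minutes),
#'   normal truncated to `t_rep_range_min`.
#' @param t_rep_range_min truncation range for the replication duration (min).
#' @param b_mean_min,d_mean_min,bd_sd_min B and D period means and common sd
#'   (minutes), truncated at `bd_min_min`.
#' @param bd_min_min lower truncation for B and D periods (minutes).
#' @param k_p effective clamp loading rate during replication, events/s.
#' @param t_unload per-clamp unloading time constant, s.
#' @param total_start,total_end total clamp content at birth and division.
#' @param sister_sep_frac fraction of the replication phase after which the
#'   single focus splits into two sister-replisome foci.
#' @param psf_sigma_px Gaussian PSF sigma, pixels.
#' @param unit_intensity camera counts per fluorophore per frame.
#' @param bg_offset,bg_gradient additive background: constant offset plus a
#'   smooth diagonal gradient of the given amplitude (counts).
#' @param beam_sigma_px sigma of the 2-D Gaussian illumination profile;
#'   `Inf` gives flat illumination.
#' @param drift_per_frame per-frame stage drift, c(rows, cols), pixels.
#' @param fiducial_pos c(row, col) of the fiducial marker (outside the
#'   channel); `fiducial_brightness` its counts per frame.
#' @param poisson_noise logical, apply shot noise.
#' @param read_sd Gaussian read-noise sd, counts.
#' @param bleach_survival per-fluorophore survival probability per exposure.
#' @param seed RNG seed.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(n_cycles = 4L,
                         height_px = 48L, width_px = 20L,
                         pixel_nm = 160,
                         frame_interval_s = 150, exposure_s = 0.08,
                         cell_width_px = 7L, birth_length_px = 16,
                         t_rep_mean_min = 68, t_rep_sd_min = 10,
                         t_rep_range_min = c(40, 95),
                         b_mean_min = 9, d_mean_min = 7, bd_sd_min = 2.5,
                         bd_min_min = 5,
                         k_p = 46 / 195, t_unload = 195,
                         total_start = 60, total_end = 120,
                         sister_sep_frac = 0.35,
                         psf_sigma_px = 1.3,
                         unit_intensity = 350,
                         bg_offset = 100, bg_gradient = 10,
                         beam_sigma_px = 60,
                         drift_per_frame = c(0.015, 0.005),
                         fiducial_pos = c(5L, 3L),
                         fiducial_brightness = 4000,
                         poisson_noise = TRUE, read_sd = 3,
                         bleach_survival = 0.998,
                         seed = 1L) {
  stopifnot(n_cycles >= 1, height_px >= 8, width_px >= 8,
            cell_width_px >= 2, birth_length_px >= 4,
            psf_sigma_px > 0, unit_intensity >= 0,
            t_unload > 0, k_p >= 0, total_end >= total_start,
            total_start > 0, sister_sep_frac > 0, sister_sep_frac < 1,
            read_sd >= 0)
  if (frame_interval_s < exposure_s)
    stop("frame interval must be at least the exposure time")
  if (bleach_survival <= 0 || bleach_survival > 1)
    stop("bleach_survival must be in (0, 1]")
  # the cell must fit the channel even at division length, with margins
  if (2 * birth_length_px + 8 > height_px)
    stop("channel too short: a dividing cell of length ",
         2 * birth_length_px, " px does not fit height ", height_px)
  band <- channel_band(width_px, cell_width_px)
  if (fiducial_pos[2] >= band[1] - 2)
    stop("fiducial must sit clear of the growth channel columns")
  structure(as.list(environment()), class = "scene_config")
}

# columns occupied by the growth channel (centered band)
channel_band <- function(width_px, cell_width_px) {
  c0 <- floor((width_px - cell_width_px) / 2) + 1L
  c(c0, c0 + cell_width_px - 1L)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic mother-machine scene configuration\n")
  cat(sprintf("  %d cycles, %dx%d px, %.3g s frames (%.3g s exposure)\n",
              x$n_cycles, x$height_px, x$width_px, x$frame_interval_s,
              x$exposure_s))
  cat(sprintf("  kinetics: k_p = %.4g /s, t_unload = %.4g s (plateau %.3g)\n",
              x$k_p, x$t_unload, x$k_p * x$t_unload))
  cat(sprintf("  cycle: t_rep %.3g +/- %.3g min, doubling mean %.3g min\n",
              x$t_rep_mean_min, x$t_rep_sd_min,
              x$b_mean_min + x$t_rep_mean_min + x$d_mean_min))
  cat(sprintf("  totals %g -> %g clamps; unit %.3g counts/fluorophore\n",
              x$total_start, x$total_end, x$unit_intensity))
  invisible(x)
}

# truncated-normal draw by rejection (vectorized)
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# normalized Gaussian blur kernel; EBImage::filter2 is used so that the
# convolution conserves total flux exactly (circular boundary)
psf_kernel <- function(sigma) {
  k <- EBImage::makeBrush(2L * ceiling(4 * sigma) + 1L, shape = "gaussian",
                          sigma = sigma)
  k / sum(k)
}

beam_image <- function(h, w, sigma, center = c(h / 2, w / 2)) {
  if (!is.finite(sigma)) return(matrix(1, h, w))
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  b <- exp(-((r - center[1])^2 + (c - center[2])^2) / (2 * sigma^2))
  b / max(b)
}

background_image <- function(h, w, offset, gradient) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  offset + gradient * ((r - 1) / max(h - 1, 1) + (c - 1) / max(w - 1, 1)) / 2
}

add_noise <- function(frame, poisson, read_sd) {
  if (poisson) frame <- matrix(stats::rpois(length(frame), pmax(frame, 0)),
                               nrow(frame), ncol(frame))
  if (read_sd > 0) frame <- frame + matrix(stats::rnorm(length(frame),
                                                        0, read_sd),
                                           nrow(frame), ncol(frame))
  frame
}

# draw the cycle-timing table: per-cycle B, replication, D periods (seconds)
draw_cycle_times <- function(cfg) {
  n <- cfg$n_cycles
  t_rep <- 60 * rnorm_trunc(n, cfg$t_rep_mean_min, cfg$t_rep_sd_min,
                            cfg$t_rep_range_min[1], cfg$t_rep_range_min[2])
  b <- 60 * rnorm_trunc(n, cfg$b_mean_min, cfg$bd_sd_min, lo = cfg$bd_min_min)
  d <- 60 * rnorm_trunc(n, cfg$d_mean_min, cfg$bd_sd_min, lo = cfg$bd_min_min)
  t_double <- b + t_rep + d
  birth <- c(0, cumsum(t_double))[seq_len(n)]
  data.frame(cycle = seq_len(n), birth_s = birth,
             init_s = birth + b, term_s = birth + b + t_rep,
             division_s = birth + t_double,
             b_s = b, t_rep_s = t_rep, d_s = d, t_double_s = t_double)
}

#' Generate a synthetic mother-machine fluorescence time-lapse
#'
#' Simulates consecutive cycles of a mother cell held at the closed end of a
#' growth channel (the daughter above it is flushed out instantly at
#' division), renders a fluorescence stack and a brightfield-proxy stack, and
#' returns them together with the exact ground truth.
#'
#' Per frame, the cell contributes (i) diffuse cytoplasmic signal spread
#' uniformly over its footprint, (ii) focal signal from the DNA-bound clamps
#' split over one focus before sister-replisome separation and two after
#' (binomial split), both convolved with the Gaussian PSF, (iii) the
#' multiplicative illumination profile, (iv) additive smooth background,
#' (v) integer-rounded stage drift applied to all content including a
#' fiducial marker, and (vi) Poisson shot noise plus Gaussian read noise.
#' Photobleaching applies per-exposure Bernoulli survival to each fluorophore;
#' newly synthesized fluorophores enter intact, and residual bound clamps at
#' division are inherited binomially by the daughter.
#'
#' @param config a [scene_config()].
#' @return an object of class `scene`: list with `fluor` and `bf` arrays
#'   (row x col x frame), and `truth` (per-frame cell table, per-cycle timing
#'   table, applied drift, beam profile, fiducial track, config).
#' @export
generate_timelapse <- function(config) {
  if (!inherits(config, "scene_config")) stop("config must be a scene_config")
  cfg <- config
  set.seed(cfg$seed)
  cyc <- draw_cycle_times(cfg)
  total_time <- cyc$division_s[nrow(cyc)]
  n_frames <- floor(total_time / cfg$frame_interval_s) + 1L
  t_frames <- (seq_len(n_frames) - 1L) * cfg$frame_interval_s

  h <- cfg$height_px; w <- cfg$width_px
  band <- channel_band(w, cfg$cell_width_px)
  beam <- beam_image(h, w, cfg$beam_sigma_px)
  bg <- background_image(h, w, cfg$bg_offset, cfg$bg_gradient)
  kern <- psf_kernel(cfg$psf_sigma_px)
  kern_bf <- psf_kernel(1)

  # ---- per-cycle bound-clamp trajectories (event-driven, exact) ----
  n_carry <- 0L        # clamps inherited at birth
  f_carry <- 1         # intact fluorophore fraction inherited at birth
  cell_rows <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  fid_track <- matrix(0L, n_frames, 2)
  drift_applied <- matrix(0L, n_frames, 2)
  frames_f <- vector("list", n_frames)
  frames_b <- vector("list", n_frames)

  for (ci in seq_len(nrow(cyc))) {
    bs <- cyc$birth_s[ci]; b_len <- cyc$b_s[ci]
    trep <- cyc$t_rep_s[ci]; d_len <- cyc$d_s[ci]
    tdbl <- cyc$t_double_s[ci]
    # decay of inherited clamps during the B period
    pre <- simulate_exact(kinetic_params(0, cfg$t_unload, t_rep = b_len + 1,
                                         n_init = n_carry),
                          duration = b_len,
                          seed = sample.int(.Machine$integer.max, 1L))
    n_at_init <- pre$counts[length(pre$counts)]
    # replication + termination decay
    rep_tr <- simulate_exact(kinetic_params(cfg$k_p, cfg$t_unload,
                                            t_rep = trep,
                                            n_init = n_at_init),
                             duration = trep + d_len,
                             seed = sample.int(.Machine$integer.max, 1L))
    n_end <- rep_tr$counts[length(rep_tr$counts)]
    n_next <- stats::rbinom(1L, n_end, 0.5)

    fr_idx <- which(t_frames >= bs & t_frames < cyc$division_s[ci])
    if (ci == nrow(cyc)) fr_idx <- which(t_frames >= bs)
    tau <- t_frames[fr_idx] - bs  # cell age at each frame
    bound <- integer(length(tau))
    in_b <- tau < b_len
    if (any(in_b)) bound[in_b] <- trajectory_at(pre, tau[in_b])
    if (any(!in_b)) bound[!in_b] <- trajectory_at(rep_tr, tau[!in_b] - b_len)

    # deterministic total content (clamp units), exponential growth
    rate <- log(cfg$total_end / cfg$total_start) / tdbl
    total_clamps <- cfg$total_start * exp(rate * tau)
    n_fluor <- round(2 * total_clamps)

    # intact (unbleached) fluorophores: Bernoulli survival per exposure,
    # synthesis enters intact
    intact <- integer(length(tau))
    intact[1] <- round(n_fluor[1] * f_carry)
    if (length(tau) > 1) {
      for (k in 2:length(tau)) {
        surv <- stats::rbinom(1L, intact[k - 1], cfg$bleach_survival)
        intact[k] <- surv + max(0L, n_fluor[k] - n_fluor[k - 1])
      }
    }
    f_carry <- intact[length(intact)] / n_fluor[length(intact)]

    # cell geometry and foci
    L <- cfg$birth_length_px * 2^(tau / tdbl)
    phase <- (tau - b_len) / trep   # replication phase, <0 pre, >1 post
    n_foci <- ifelse(bound == 0, 0L,
                     ifelse(phase >= cfg$sister_sep_frac, 2L, 1L))
    split1 <- ifelse(n_foci == 2L,
                     stats::rbinom(length(bound), bound, 0.5), bound)
    cell_top <- 4L   # rows below the closed end margin

    truth[[ci]] <- data.frame(
      cycle = ci, frame = fr_idx, time_s = t_frames[fr_idx], age_s = tau,
      row0 = cell_top, row1 = cell_top + round(L) - 1L, length_px = round(L),
      bound_clamps = bound, n_foci = n_foci,
      f1_clamps = ifelse(n_foci > 0, split1, 0L),
      f2_clamps = ifelse(n_foci == 2L, bound - split1, 0L),
      total_clamps = total_clamps, n_fluor = n_fluor, intact_fluor = intact,
      phase = phase,
      phase_label = ifelse(phase < 0, "pre-initiation",
                           ifelse(phase <= 1, "replicating",
                                  "post-termination")))
    n_carry <- n_next
  }
  cells <- do.call(rbind, truth)
  cells <- cells[order(cells$frame), ]
  rownames(cells) <- NULL

  # foci positions (fractional along the cell) and emitting counts
  rel1 <- ifelse(cells$n_foci == 2L, 0.35, 0.5)
  cells$f1_row <- cells$row0 + rel1 * (cells$length_px - 1)
  cells$f2_row <- ifelse(cells$n_foci == 2L,
                         cells$row0 + 0.65 * (cells$length_px - 1), NA)
  f_intact <- cells$intact_fluor / cells$n_fluor
  cells$bound_fluor_emit <- pmin(2 * cells$bound_clamps * f_intact,
                                 cells$intact_fluor)

  # ---- render ----
  drift_true <- outer(seq_len(n_frames) - 1L, cfg$drift_per_frame)
  for (fi in seq_len(n_frames)) {
    dr <- round(drift_true[fi, 1]); dc <- round(drift_true[fi, 2])
    drift_applied[fi, ] <- c(dr, dc)
    row_cells <- cells[cells$frame == fi, ]
    lay <- matrix(0, h, w)
    bf_lay <- matrix(0, h, w)
    if (nrow(row_cells) == 1L) {
      rc <- row_cells
      r0 <- rc$row0 + dr; r1 <- rc$row1 + dr
      c0 <- band[1] + dc; c1 <- band[2] + dc
      rr <- max(1L, r0):min(h, r1); cc <- max(1L, c0):min(w, c1)
      npx <- length(rr) * length(cc)
      cyto <- max(rc$intact_fluor - rc$bound_fluor_emit, 0) *
        cfg$unit_intensity
      lay[rr, cc] <- lay[rr, cc] + cyto / npx
      bf_lay[rr, cc] <- 500
      if (rc$n_foci >= 1L && rc$bound_fluor_emit > 0) {
        w1 <- if (rc$bound_clamps > 0) rc$f1_clamps / rc$bound_clamps else 0
        fr1 <- min(max(round(rc$f1_row) + dr, 1L), h)
        fc <- min(max(round((band[1] + band[2]) / 2) + dc, 1L), w)
        lay[fr1, fc] <- lay[fr1, fc] +
          rc$bound_fluor_emit * w1 * cfg$unit_intensity
        if (rc$n_foci == 2L) {
          fr2 <- min(max(round(rc$f2_row) + dr, 1L), h)
          lay[fr2, fc] <- lay[fr2, fc] +
            rc$bound_fluor_emit * (1 - w1) * cfg$unit_intensity
        }
      }
    }
    fr_fid <- min(max(cfg$fiducial_pos[1] + dr, 1L), h)
    fc_fid <- min(max(cfg$fiducial_pos[2] + dc, 1L), w)
    fid_track[fi, ] <- c(fr_fid, fc_fid)
    lay[fr_fid, fc_fid] <- lay[fr_fid, fc_fid] + cfg$fiducial_brightness
    bf_lay[fr_fid, fc_fid] <- bf_lay[fr_fid, fc_fid] + 800

    sig <- EBImage::filter2(lay, psf_kernel(cfg$psf_sigma_px)) * beam + bg
    frames_f[[fi]] <- add_noise(sig, cfg$poisson_noise, cfg$read_sd)
    bf <- EBImage::filter2(bf_lay, kern_bf) + 50
    frames_b[[fi]] <- add_noise(bf, FALSE, if (cfg$read_sd > 0) 3 else 0)
  }
  fluor <- array(unlist(frames_f), dim = c(h, w, n_frames))
  bfs <- array(unlist(frames_b), dim = c(h, w, n_frames))
  structure(list(
    fluor = fluor, bf = bfs,
    truth = list(cells = cells, cycles = cyc,
                 drift_true = drift_true, drift_applied = drift_applied,
                 fiducial = fid_track, beam = beam, background = bg,
                 band = band, config = cfg)),
    class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$fluor)
  cat(sprintf("Synthetic time-lapse scene: %d frames of %dx%d px, %d cycles\n",
              d[3], d[1], d[2], nrow(x$truth$cycles)))
  cat(sprintf("  frame interval %.3g s; plateau (analytic) %.3g bound clamps\n",
              x$truth$config$frame_interval_s,
              x$truth$config$k_p * x$truth$config$t_unload))
  invisible(x)
}

#' Draw censored single-molecule on-times
#'
#' Latent unloading and photobleaching times are independent exponentials
#' (wall-clock constants `t_unload` and `t_bleach_wall`); the observed on-time
#' is their minimum quantized up to the frame grid and right-censored at the
#' movie length.
#'
#' @param n number of molecules.
#' @param t_unload unloading time constant, s.
#' @param t_bleach_wall wall-clock bleaching time constant, s (`Inf` for no
#'   bleaching).
#' @param frame_interval frame spacing, s.
#' @param movie_length movie duration, s.
#' @param exposure exposure per frame, s (metadata).
#' @param seed RNG seed.
#' @return an [on_time_set()] with attribute `truth` (latent times).
#' @export
simulate_on_times <- function(n, t_unload, t_bleach_wall, frame_interval,
                              movie_length, exposure = 0.4, seed = 1L) {
  stopifnot(n >= 1, t_unload > 0, t_bleach_wall > 0, frame_interval > 0,
            movie_length >= frame_interval)
  set.seed(seed)
  u <- stats::rexp(n, 1 / t_unload)
  b <- if (is.finite(t_bleach_wall)) stats::rexp(n, 1 / t_bleach_wall)
       else rep(Inf, n)
  t_true <- pmin(u, b)
  censored <- t_true >= movie_length
  obs <- pmin(ceiling(t_true / frame_interval) * frame_interval, movie_length)
  obs[censored] <- movie_length
  set <- on_time_set(obs, frame_interval = frame_interval,
                     exposure = exposure, censored = censored,
                     movie_length = movie_length)
  attr(set, "truth") <- data.frame(t_unload_latent = u, t_bleach_latent = b,
                                   t_true = t_true)
  set
}

#' Generate a synthetic PALM movie of single activated molecules
#'
#' Each molecule sits at a fixed position inside its own cell (one activated
#' molecule per cell at most, as in sparse photoactivation), appears from the
#' first post-activation frame, and disappears at the minimum of an
#' exponential unloading time and an exponential wall-clock bleaching time.
#' Frame 1 is a pre-activation frame with no spots.
#'
#' @param config a [scene_config()]; supplies PSF, background, noise and beam.
#' @param t_unload unloading time constant, s.
#' @param n_spots number of activated molecules (= occupied cells).
#' @param t_bleach_wall wall-clock bleach constant, s.
#' @param frame_interval,exposure PALM timing, s (defaults 5 and 0.4).
#' @param n_frames number of post-activation frames.
#' @param spot_intensity integrated counts per spot per frame.
#' @param n_outside additional spots placed outside any cell (false positives
#'   for rejection tests).
#' @param seed RNG seed.
#' @return list with `stack` (row x col x frame, frame 1 pre-activation),
#'   `cell_mask` (integer label matrix), `truth` (per-spot table incl. the
#'   latent times and observed on-frames), and acquisition metadata.
#' @export
generate_palm_movie <- function(config, t_unload, n_spots,
                                t_bleach_wall = 500,
                                frame_interval = 5, exposure = 0.4,
                                n_frames = 120L,
                                spot_intensity = 1500,
                                n_outside = 0L,
                                seed = 1L) {
  if (!inherits(config, "scene_config")) stop("config must be a scene_config")
  stopifnot(n_spots >= 1)
  set.seed(seed)
  tile_h <- 18L; tile_w <- 14L
  n_tiles <- n_spots
  n_col <- ceiling(sqrt(n_tiles))
  n_row <- ceiling(n_tiles / n_col)
  h <- n_row * tile_h; w <- n_col * tile_w
  on <- simulate_on_times(n_spots, t_unload, t_bleach_wall, frame_interval,
                          movie_length = n_frames * frame_interval,
                          exposure = exposure,
                          seed = sample.int(.Machine$integer.max, 1L))
  m_frames <- round(on$on_times / frame_interval)  # emitting frames per spot

  cell_mask <- matrix(0L, h, w)
  spot_pos <- matrix(0, n_spots, 2)
  for (i in seq_len(n_spots)) {
    tr <- (i - 1) %/% n_col; tc <- (i - 1) %% n_col
    r0 <- tr * tile_h; c0 <- tc * tile_w
    rows <- (r0 + 4):(r0 + tile_h - 4)       # rod along rows
    cols <- (c0 + 5):(c0 + tile_w - 5)
    cell_mask[rows, cols] <- i
    spot_pos[i, ] <- c(sample(rows[2:(length(rows) - 1)], 1),
                       sample(cols, 1))
  }
  out_pos <- NULL
  if (n_outside > 0) {
    out_pos <- cbind(sample.int(n_row, n_outside, replace = TRUE) * tile_h -
                       tile_h + 2L,
                     sample.int(n_col, n_outside, replace = TRUE) * tile_w -
                       tile_w + 2L)
  }
  beam <- beam_image(h, w, config$beam_sigma_px * 4)
  bg <- background_image(h, w, config$bg_offset, config$bg_gradient)
  kern <- psf_kernel(config$psf_sigma_px)
  auto <- 40  # faint cellular autofluorescence counts per cell per frame
  stack <- array(0, dim = c(h, w, n_frames + 1L))
  for (fi in 0:n_frames) {
    lay <- matrix(0, h, w)
    lay[cell_mask > 0] <- auto / sum(cell_mask == 1L)
    if (fi >= 1) {
      live <- which(m_frames >= fi)
      for (i in live)
        lay[spot_pos[i, 1], spot_pos[i, 2]] <-
          lay[spot_pos[i, 1], spot_pos[i, 2]] + spot_intensity
      if (!is.null(out_pos) && fi <= 3)
        for (j in seq_len(nrow(out_pos)))
          lay[out_pos[j, 1], out_pos[j, 2]] <-
            lay[out_pos[j, 1], out_pos[j, 2]] + spot_intensity
    }
    sig <- EBImage::filter2(lay, kern) * beam + bg
    stack[, , fi + 1L] <- add_noise(sig, config$poisson_noise, config$read_sd)
  }
  truth <- cbind(data.frame(spot = seq_len(n_spots),
                            row = spot_pos[, 1], col = spot_pos[, 2],
                            on_frames = m_frames,
                            on_time_s = on$on_times,
                            censored = on$censored),
                 attr(on, "truth"))
  list(stack = stack, cell_mask = cell_mask, truth = truth,
       on_times = on, frame_interval = frame_interval, exposure = exposure,
       outside_pos = out_pos)
}

#' Generate a single-fluorophore calibration field
#'
#' Isolated PSF spots of known unit intensity on a uniform background, used
#' to build the intensity-to-molecule calibration standard. Spots are laid on
#' a jittered grid with guaranteed separation. The multi-frame variant
#' applies per-frame Bernoulli survival so traces bleach in single downward
#' steps of one unit intensity.
#'
#' @param unit_intensity integrated counts per fluorophore per frame.
#' @param n_molecules number of molecules (0 gives a pure-noise field).
#' @param psf_sigma_px Gaussian PSF sigma, pixels.
#' @param bg_offset additive background counts.
#' @param read_sd Gaussian read-noise sd; Poisson shot noise always applies
#'   when `noise` is TRUE.
#' @param noise logical, apply noise.
#' @param n_frames number of frames (1 = single calibration field).
#' @param survival per-frame survival probability (stack variant).
#' @param min_sep minimum center-to-center separation, px.
#' @param exposure_s exposure metadata, s.
#' @param seed RNG seed.
#' @return list with `stack` (row x col x frame), `truth` (positions and, for
#'   stacks, bleach frames), `exposure_s`, `unit_intensity`.
#' @export
generate_calibration_field <- function(unit_intensity, n_molecules,
                                       psf_sigma_px = 1.3,
                                       bg_offset = 30, read_sd = 3,
                                       noise = TRUE,
                                       n_frames = 1L, survival = 1,
                                       min_sep = 12L, exposure_s = 0.08,
                                       seed = 1L) {
  stopifnot(unit_intensity >= 0, n_molecules >= 0, min_sep >= 6)
  if (survival <= 0 || survival > 1) stop("survival must be in (0, 1]")
  set.seed(seed)
  n_grid <- max(1L, ceiling(sqrt(n_molecules)))
  pitch <- min_sep + 4L
  margin <- 8L
  side <- n_grid * pitch + 2L * margin
  if (n_molecules > 0) {
    idx <- sample.int(n_grid^2, n_molecules)
    gr <- (idx - 1L) %/% n_grid; gc <- (idx - 1L) %% n_grid
    jit <- matrix(stats::runif(2 * n_molecules, -1.5, 1.5), ncol = 2)
    pos <- cbind(margin + gr * pitch + pitch / 2 + jit[, 1],
                 margin + gc * pitch + pitch / 2 + jit[, 2])
    pos <- round(pos)
    if (min(stats::dist(pos)) < min_sep)
      stop("spot density too high to guarantee isolation")
  } else pos <- matrix(numeric(0), 0, 2)
  kern <- psf_kernel(psf_sigma_px)
  alive <- rep(TRUE, n_molecules)
  bleach_frame <- rep(NA_integer_, n_molecules)
  stack <- array(0, dim = c(side, side, n_frames))
  for (fi in seq_len(n_frames)) {
    lay <- matrix(0, side, side)
    for (i in which(alive)) lay[pos[i, 1], pos[i, 2]] <-
        lay[pos[i, 1], pos[i, 2]] + unit_intensity
    sig <- EBImage::filter2(lay, kern) + bg_offset
    stack[, , fi] <- if (noise) add_noise(sig, TRUE, read_sd) else sig
    if (survival < 1 && n_molecules > 0) {
      died <- alive & stats::runif(n_molecules) > survival
      bleach_frame[died] <- fi
      alive <- alive & !died
    }
  }
  truth <- if (n_molecules > 0)
    data.frame(molecule = seq_len(n_molecules), row = pos[, 1],
               col = pos[, 2], bleach_frame = bleach_frame)
  else data.frame(molecule = integer(0), row = numeric(0), col = numeric(0),
                  bleach_frame = integer(0))
  list(stack = stack, truth = truth, exposure_s = exposure_s,
       unit_intensity = unit_intensity)
}

#' Write a synthetic scene to disk
#'
#' Writes the fluorescence and brightfield stacks as 16-bit multi-page TIFFs
#' together with the ground truth (per-frame cell table as CSV, the rest as
#' JSON).
#'
#' @param scene a `scene` from [generate_timelapse()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- 65535
  to_pages <- function(a) lapply(seq_len(dim(a)[3]), function(i)
    pmin(pmax(a[, , i] / scale, 0), 1))
  p1 <- file.path(dir, "fluorescence.tif")
  p2 <- file.path(dir, "brightfield.tif")
  tiff::writeTIFF(to_pages(scene$fluor), p1, bits.per.sample = 16L)
  tiff::writeTIFF(to_pages(scene$bf), p2, bits.per.sample = 16L)
  p3 <- file.path(dir, "truth_cells.csv")
  utils::write.csv(scene$truth$cells, p3, row.names = FALSE)
  p4 <- file.path(dir, "truth.json")
  cfg <- scene$truth$config
  jsonlite::write_json(list(
    cycles = scene$truth$cycles,
    drift_applied = scene$truth$drift_applied,
    fiducial = scene$truth$fiducial,
    band = scene$truth$band,
    config = unclass(cfg),
    intensity_scale = scale), p4, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4))
}

#' Read a multi-page TIFF stack into an array
#'
#' @param path TIFF file.
#' @param scale multiply pixel values by this factor (use the
#'   `intensity_scale` recorded by [write_scene()], default 65535).
#' @return numeric array (row x col x frame).
#' @export
read_stack <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                               length(pages))) * scale
}
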