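# Shared fixtures: small, fast configurations used across test files.

# quiet scene: no noise, flat beam, no drift, no fiducial, no gradient --
# isolates the photometric bookkeeping
quiet_config <- function(...) {
  scene_config(n_cycles = 2L, seed = 7L, poisson_noise = FALSE, read_sd = 0,
               drift_per_frame = c(0, 0), beam_sigma_px = Inf,
               bg_gradient = 0, fiducial_brightness = 0, ...)
}

# default-physics scene, kept short
small_config <- function(...) {
  scene_config(n_cycles = 3L, seed = 5L, ...)
}

# analysis regions for a scene
scene_regions <- function(scene) {
  cfg <- scene$truth$config
  band <- scene$truth$band
  list(channel = list(rows = seq_len(cfg$height_px),
                      cols = band[1]:band[2]),
       fiducial = list(rows = pmax(1, cfg$fiducial_pos[1] + (-2:2)),
                       cols = pmax(1, cfg$fiducial_pos[2] + (-2:2))))
}

# chi-square goodness of fit of integer samples against a Poisson law,
# pooling tail bins to expected counts >= 5
poisson_gof_pvalue <- function(x, lambda) {
  kmax <- max(x, ceiling(lambda + 6 * sqrt(lambda)))
  p <- stats::dpois(0:kmax, lambda)
  p[length(p)] <- p[length(p)] + stats::ppois(kmax, lambda, lower.tail = FALSE)
  obs <- tabulate(x + 1L, nbins = kmax + 1L)
  n <- length(x)
  # pool bins from both ends until expected >= 5
  keep <- which(n * p >= 5)
  if (length(keep) < 3) stop("too few well-populated bins")
  lo <- min(keep); hi <- max(keep)
  obs2 <- c(sum(obs[seq_len(lo - 1)]), obs[lo:hi],
            sum(obs[-seq_len(hi)]))
  p2 <- c(sum(p[seq_len(lo - 1)]), p[lo:hi], sum(p[-seq_len(hi)]))
  obs2 <- obs2[p2 > 0]; p2 <- p2[p2 > 0]
  suppressWarnings(stats::chisq.test(obs2, p = p2 / sum(p2))$p.value)
}

# chi-square homogeneity of two integer samples on pooled bins
two_sample_count_pvalue <- function(x, y) {
  kmax <- max(x, y)
  tx <- tabulate(x + 1L, nbins = kmax + 1L)
  ty <- tabulate(y + 1L, nbins = kmax + 1L)
  tot <- tx + ty
  # pool sparse bins into neighbours
  grp <- cumsum(c(TRUE, tot[-1] > 0)) # placeholder grouping
  m <- cbind(tx, ty)
  keep <- tot >= 10
  m2 <- rbind(colSums(m[!keep, , drop = FALSE]), m[keep, , drop = FALSE])
  m2 <- m2[rowSums(m2) > 0, , drop = FALSE]
  suppressWarnings(stats::chisq.test(m2)$p.value)
}

# hand-built quantified cell-cycle trace for calibration-layer tests
fake_trace <- function(bound, total, init, term, frames = seq_along(bound)) {
  structure(list(
    cell_id = 1L,
    frames = data.frame(frame = frames),
    molecules = data.frame(frame = frames, bound = bound, total = total,
                           bound_fraction = bound / total),
    initiation_frame = init, termination_frame = term,
    birth_frame = frames[1], division_frame = frames[length(frames)],
    complete = TRUE, replication_min = (term - init) * 2.5,
    doubling_min = length(frames) * 2.5,
    frame_interval_s = 150, present = rep(FALSE, length(frames)),
    flags = list(selected = TRUE)), class = "cell_cycle_trace")
}
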