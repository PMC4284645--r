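#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a frame by grayscale morphological
#' opening (erosion then dilation with a disc of the given radius) of a
#' lightly smoothed copy, and subtracts it. Compact bright features narrower
#' than the ball (diffraction-limited foci, single cells' focal signal) are
#' excluded from the background estimate; the result is clipped at zero.
#'
#' @param frame numeric matrix (camera counts).
#' @param ball_radius_px ball radius in pixels; should be well above the PSF
#'   scale and below the cell length. Default 15.
#' @param presmooth_sigma Gaussian sigma for smoothing the copy used for
#'   background estimation (tames the downward bias of a morphological
#'   opening under shot noise); 0 disables.
#' @return background-subtracted frame, clipped at zero.
#' @export
subtract_background <- function(frame, ball_radius_px = 15,
                                presmooth_sigma = 2) {
  if (!is.matrix(frame) || !is.numeric(frame)) stop("frame must be a matrix")
  if (ball_radius_px <= 0) stop("ball_radius_px must be positive")
  # clamp the structuring elements to the frame for small images
  half_max <- (min(dim(frame)) - 1L) %/% 2L
  ball_radius_px <- min(ball_radius_px, half_max)
  est_src <- if (presmooth_sigma > 0) {
    ksz <- min(2L * ceiling(4 * presmooth_sigma) + 1L, 2L * half_max + 1L)
    k <- EBImage::makeBrush(ksz, "gaussian", sigma = presmooth_sigma)
    EBImage::filter2(frame, k / sum(k))
  } else frame
  brush <- EBImage::makeBrush(2L * ceiling(ball_radius_px) + 1L, "disc")
  # EBImage grayscale morphology clips at 1; rescale around it
  lo <- min(est_src); hi <- max(est_src)
  if (hi <= lo) return(pmax(frame - lo, 0))
  bg <- EBImage::opening((est_src - lo) / (hi - lo), brush) * (hi - lo) + lo
  pmax(frame - bg, 0)
}

#' Flat-field (illumination heterogeneity) correction
#'
#' Divides a frame by the measured illumination profile, normalized to a
#' maximum of one, so that a flat scene modulated by the beam becomes flat.
#'
#' @param frame numeric matrix.
#' @param beam_profile strictly positive matrix of the same shape.
#' @return corrected frame.
#' @export
correct_illumination <- function(frame, beam_profile) {
  if (!all(dim(frame) == dim(beam_profile)))
    stop("beam profile shape does not match the frame")
  if (any(!is.finite(beam_profile)) || any(beam_profile <= 0))
    stop("beam profile must be strictly positive and finite")
  frame / (beam_profile / max(beam_profile))
}

#' Fiducial-based drift correction
#'
#' Tracks a fiducial marker to integer-pixel accuracy by normalized
#' cross-correlation of a template (cut from the first frame) within a search
#' region, and shifts every frame back so the fiducial is stationary.
#'
#' @param stack numeric array (row x col x frame).
#' @param fiducial_region list with `rows` and `cols` (index vectors) locating
#'   the fiducial in frame 1; the search window is this region grown by
#'   `max_shift`.
#' @param max_shift largest expected cumulative drift, px.
#' @param min_cor minimum correlation to accept a match; below it the
#'   tracking aborts naming the frame.
#' @return list with `stack` (shifted back, zero-filled borders) and `shifts`
#'   (data.frame frame/drow/dcol of the detected drift).
#' @export
correct_drift <- function(stack, fiducial_region, max_shift = 6L,
                          min_cor = 0.5) {
  d <- dim(stack)
  rows <- fiducial_region$rows; cols <- fiducial_region$cols
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
    stop("fiducial region outside the image")
  tmpl <- stack[rows, cols, 1]
  tmpl0 <- tmpl - mean(tmpl)
  shifts <- matrix(0L, d[3], 2)
  offs <- -max_shift:max_shift
  for (fi in seq_len(d[3])) {
    best <- c(-Inf, 0L, 0L)
    for (dr in offs) for (dc in offs) {
      r <- rows + dr; c <- cols + dc
      if (min(r) < 1 || max(r) > d[1] || min(c) < 1 || max(c) > d[2]) next
      win <- stack[r, c, fi]
      w0 <- win - mean(win)
      den <- sqrt(sum(w0^2) * sum(tmpl0^2))
      if (den == 0) next
      cc <- sum(w0 * tmpl0) / den
      if (cc > best[1]) best <- c(cc, dr, dc)
    }
    if (best[1] < min_cor)
      stop("fiducial lost at frame ", fi,
           " (best correlation ", signif(best[1], 3), ")")
    shifts[fi, ] <- as.integer(best[2:3])
  }
  out <- stack
  for (fi in seq_len(d[3]))
    out[, , fi] <- shift_frame(stack[, , fi], -shifts[fi, 1], -shifts[fi, 2])
  list(stack = out,
       shifts = data.frame(frame = seq_len(d[3]),
                           drow = shifts[, 1], dcol = shifts[, 2]))
}

# integer shift with zero fill
shift_frame <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Build a kymograph of a growth channel
#'
#' Sums pixel intensities perpendicular to the channel direction (over the
#' channel's column band) for every frame, producing a time x position matrix.
#'
#' @param stack numeric array (row x col x frame).
#' @param channel_region list with `rows` and `cols` of the channel band.
#' @return object of class `kymograph`: matrix (frames x positions) with the
#'   region stored as an attribute.
#' @export
build_kymograph <- function(stack, channel_region) {
  d <- dim(stack)
  rows <- channel_region$rows; cols <- channel_region$cols
  if (length(rows) == 0 || length(cols) == 0) stop("empty channel region")
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
    stop("channel region outside the image")
  k <- t(apply(stack[rows, cols, , drop = FALSE], 3,
               function(m) rowSums(matrix(m, length(rows), length(cols)))))
  k <- matrix(k, nrow = d[3], ncol = length(rows))
  structure(k, rows = rows, cols = cols, class = "kymograph")
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = seq_len(nrow(x)), y = attr(x, "rows"), z = unclass(x),
                  xlab = "frame", ylab = "position along channel (px)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Detect cell poles from a brightfield-proxy stack
#'
#' Thresholds each frame (Otsu on the normalized frame), labels connected
#' row-runs within the channel band, and returns the interval of the mother
#' cell (the component nearest the closed end, row 1).
#'
#' @param bf_stack brightfield array (row x col x frame).
#' @param channel_region list with `rows`, `cols` of the channel band.
#' @param min_len minimum run length (px) accepted as a cell.
#' @return data.frame frame/row0/row1/length_px of the mother cell (NA rows
#'   when no cell found).
#' @export
detect_poles <- function(bf_stack, channel_region, min_len = 4L) {
  d <- dim(bf_stack)
  rows <- channel_region$rows; cols <- channel_region$cols
  out <- data.frame(frame = seq_len(d[3]), row0 = NA_integer_,
                    row1 = NA_integer_, length_px = NA_integer_)
  for (fi in seq_len(d[3])) {
    fr <- bf_stack[rows, cols, fi]
    rng <- range(fr)
    if (diff(rng) <= 0) next
    nrm <- (fr - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(nrm))
    mask <- nrm > th
    on <- rowMeans(mask) > 0.5
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_len)
    if (!length(runs)) next
    ri <- runs[which.min(starts[runs])]   # nearest the closed end
    out$row0[fi] <- rows[starts[ri]]
    out$row1[fi] <- rows[ends[ri]]
    out$length_px[fi] <- r$lengths[ri]
  }
  out
}

#' Decompose a cell line profile into background, cytoplasm and foci
#'
#' Operates on the summed line profile of one cell in one frame (a kymograph
#' column restricted to the cell interval). The background level per profile
#' position is the median of the outside-cell positions and is subtracted
#' first. The cytoplasm level is the median of the background-subtracted
#' in-cell profile; contiguous runs exceeding `median + k * MAD` (MAD scaled
#' to sd) are foci, each contributing `sum(profile - median)` over its run so
#' the cytoplasm floor under a focus stays attributed to cytoplasm. At most
#' two runs (the brightest) are kept, matching the two sister replisomes.
#' Background + cytoplasm + foci equals the raw in-cell total exactly.
#'
#' @param profile numeric vector: full line profile of the channel at one
#'   frame (summed over the channel width).
#' @param cell_interval integer c(row0, row1) of the cell within `profile`
#'   (1-based, inclusive).
#' @param outside index vector of profile positions used for the background
#'   estimate (default: everything outside the cell interval, 2 px guard).
#' @param k MAD multiplier for focus significance (default 3).
#' @return list with `background` (total background counts inside the cell),
#'   `cytoplasm`, `foci` (counts), `foci_count` (0-2), `bg_per_px`,
#'   `cyto_level`, `runs` (list of index ranges), `total_raw`.
#' @export
decompose_cell <- function(profile, cell_interval, outside = NULL, k = 3) {
  r0 <- cell_interval[1]; r1 <- cell_interval[2]
  if (r1 - r0 + 1 < 2) stop("cell narrower than 2 px")
  n <- length(profile)
  if (is.null(outside)) {
    guard <- 2L
    outside <- setdiff(seq_len(n), max(1, r0 - guard):min(n, r1 + guard))
  }
  if (!length(outside)) stop("outside-cell sample is empty")
  bg_px <- stats::median(profile[outside])
  cell <- profile[r0:r1]
  nc <- length(cell)
  sub <- cell - bg_px
  # pass 1: provisional focus mask from the raw median/MAD of the profile
  med1 <- stats::median(sub)
  mad1 <- stats::mad(sub)
  mask1 <- sub > med1 + k * mad1
  # pass 2: cytoplasm level and noise from rows clear of provisional foci
  # (the raw median is biased upward when foci cover a sizable cell
  # fraction, and the raw MAD reflects focal structure, not noise); iterate
  # the exclusion to a fixed point so focal shoulders drop out of both
  mask <- mask1
  cyto_level <- med1; noise <- mad1
  # the measurement noise of the profile, from the focus-free outside
  # sample, floors the in-cell noise estimate so the refinement cannot run
  # away (a shrinking noise estimate would reclassify ever more cytoplasm
  # as focal)
  noise_floor <- stats::mad(profile[outside])
  # pole rows carry part of their flux axially outside the cell (PSF
  # spill), so they read low; keep them out of the cytoplasm estimate
  interior <- rep(TRUE, nc)
  if (nc >= 10L) interior[c(1:2, (nc - 1L):nc)] <- FALSE
  for (it in 1:2) {
    # cleanest usable cytoplasm sample: away from focal tails and poles,
    # relaxing only when the cell is too crowded to leave enough rows
    cand <- list(which(!dilate_mask(mask, 2L) & interior),
                 which(!dilate_mask(mask, 1L) & interior),
                 which(!dilate_mask(mask, 1L)))
    ok <- which(vapply(cand, length, 0L) >= 4L)
    if (!length(ok)) break
    nonrun <- cand[[ok[1]]]
    cyto_level <- stats::median(sub[nonrun])
    noise <- max(stats::mad(sub[nonrun]), noise_floor)
    new_mask <- sub > cyto_level + k * noise
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  thr <- cyto_level + k * noise
  above <- sub > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # a run is a focus when it spans >= 2 positions, or a single position
  # with a core well beyond the significance threshold
  runs <- which(r$values &
                  (r$lengths >= 2L |
                     vapply(seq_along(r$lengths), function(i)
                       r$values[i] &&
                         max(sub[starts[i]:ends[i]]) >
                           cyto_level + 2 * k * noise, TRUE)))
  run_list <- lapply(runs, function(i) starts[i]:ends[i])
  run_sum <- vapply(run_list, function(idx) sum(sub[idx] - cyto_level), 0)
  # foci are peaks: a run holding two well-separated maxima (dip below
  # half-way between peak and threshold) counts as two sister foci
  n_peaks <- vapply(run_list, function(idx)
    count_peaks(sub[idx], k * noise), 0L)
  if (length(run_list) > 2L) {
    keep <- sort(order(run_sum, decreasing = TRUE)[1:2])
    run_list <- run_list[keep]; run_sum <- run_sum[keep]
    n_peaks <- n_peaks[keep]
  }
  # integrate each focus over its run grown by run_pad px so PSF tails just
  # below the threshold are still counted; on focus-free positions
  # (sub - cyto_level) averages zero, so the padding is unbiased under noise
  run_pad <- 2L
  if (length(run_list)) {
    padded <- lapply(run_list, function(idx)
      max(1L, min(idx) - run_pad):min(nc, max(idx) + run_pad))
    # resolve overlap of padded windows: each position counted once,
    # assigned to the nearest run
    owner <- rep(NA_integer_, nc)
    centers <- vapply(run_list, function(idx) mean(idx), 0)
    for (ri in seq_along(padded)) for (pos in padded[[ri]]) {
      if (is.na(owner[pos]) ||
          abs(pos - centers[ri]) < abs(pos - centers[owner[pos]]))
        owner[pos] <- ri
    }
    run_sum <- vapply(seq_along(run_list), function(ri)
      sum(sub[which(owner == ri)] - cyto_level), 0)
    run_list <- lapply(seq_along(run_list),
                       function(ri) which(owner == ri))
    # a genuine focus integrates well beyond the noise scale; padded
    # windows of spurious runs (often reaching into dim pole rows) do not
    sig <- run_sum > 2 * k * max(noise, noise_floor)
    run_list <- run_list[sig]; run_sum <- run_sum[sig]
    n_peaks <- n_peaks[sig]
  }
  foci <- sum(run_sum)
  foci_count <- min(2L, sum(pmax(n_peaks, 1L)))
  if (!length(run_list)) foci_count <- 0L
  total_raw <- sum(cell)
  background <- bg_px * nc
  cytoplasm <- total_raw - background - foci
  list(background = background, cytoplasm = cytoplasm, foci = foci,
       foci_count = foci_count, bg_per_px = bg_px,
       cyto_level = cyto_level, noise = noise,
       runs = lapply(run_list, function(idx) idx + r0 - 1L),
       total_raw = total_raw)
}

# grow a logical run mask by m positions on each side
dilate_mask <- function(mask, m) {
  out <- mask
  n <- length(mask)
  for (s in seq_len(m)) {
    out <- out | c(mask[-seq_len(s)], rep(FALSE, s)) |
      c(rep(FALSE, s), mask[seq_len(n - s)])
    mask <- out
  }
  out
}

# number of local maxima in a run profile whose dip separation exceeds
# `prom`; 1 for a simple peak
count_peaks <- function(v, prom) {
  n <- length(v)
  if (n < 3L) return(1L)
  peaks <- which(diff(sign(diff(v))) == -2) + 1L
  if (length(peaks) < 2L) return(1L)
  peaks <- peaks[order(v[peaks], decreasing = TRUE)][1:2]
  peaks <- sort(peaks)
  valley <- min(v[peaks[1]:peaks[2]])
  if (min(v[peaks]) - valley > max(prom, 0.25 * min(v[peaks]))) 2L else 1L
}

#' Segment replication and division cycles from a kymograph
#'
#' Division events are frames where the mother-cell length drops by more than
#' `div_drop`; cycles run between consecutive divisions. For every frame of a
#' cycle, the cell line profile is decomposed (see [decompose_cell()]) and a
#' focus-presence series derived: a frame has a focus when the decomposition
#' finds one AND its foci intensity exceeds `presence_frac` of the cycle's
#' plateau foci intensity (median over frames with a detected focus) — the
#' relative criterion keeps the slowly-decaying post-termination tail from
#' stretching the apparent replication time. Initiation/termination are the
#' first/last frames of the presence series after a 2-frame hysteresis (a
#' focus must persist >= `hysteresis` consecutive frames to open, and be
#' absent >= `hysteresis` to close).
#'
#' @param kymo a [build_kymograph()] result for the fluorescence stack
#'   (background- and illumination-corrected).
#' @param poles a [detect_poles()] table.
#' @param frame_interval_s frame spacing, s.
#' @param div_drop fractional length drop flagging a division (default 0.35).
#' @param presence_frac relative foci-intensity threshold (default 0.25).
#' @param hysteresis frames of persistence/absence for opening/closing.
#' @param k MAD multiplier passed to [decompose_cell()].
#' @param iv_pad rows added to each end of the pole interval for the
#'   decomposition, so PSF-blurred signal spilling axially past the poles is
#'   integrated with the cell (the mother cell has no touching neighbour in
#'   these channels).
#' @return list of `cell_cycle_trace` objects: per-cycle data.frame of
#'   per-frame decomposition plus birth/division/initiation/termination
#'   frames and timing in minutes.
#' @export
segment_cycles <- function(kymo, poles, frame_interval_s,
                           div_drop = 0.35, presence_frac = 0.25,
                           hysteresis = 2L, k = 3, iv_pad = 2L) {
  stopifnot(inherits(kymo, "kymograph"))
  n_f <- nrow(kymo)
  len <- poles$length_px
  div_after <- which(!is.na(len[-n_f]) & !is.na(len[-1]) &
                       len[-1] < (1 - div_drop) * len[-n_f])
  bounds <- c(0L, div_after, n_f)   # cycle i spans (bounds[i]+1):bounds[i+1]
  traces <- list()
  rows <- attr(kymo, "rows")
  for (ci in seq_len(length(bounds) - 1L)) {
    fr <- (bounds[ci] + 1L):bounds[ci + 1L]
    fr <- fr[!is.na(poles$row0[fr])]
    if (length(fr) < 2L) next
    dec <- vector("list", length(fr))
    for (j in seq_along(fr)) {
      fi <- fr[j]
      iv <- c(max(1L, match(poles$row0[fi], rows) - iv_pad),
              min(ncol(kymo), match(poles$row1[fi], rows) + iv_pad))
      dec[[j]] <- decompose_cell(kymo[fi, ], iv, k = k)
    }
    df <- data.frame(
      frame = fr,
      row0 = poles$row0[fr], row1 = poles$row1[fr],
      length_px = poles$length_px[fr],
      background = vapply(dec, `[[`, 0, "background"),
      cytoplasm = vapply(dec, `[[`, 0, "cytoplasm"),
      foci = vapply(dec, `[[`, 0, "foci"),
      foci_count = vapply(dec, `[[`, 0L, "foci_count"))
    detected <- df$foci_count > 0
    plateau <- if (any(detected)) stats::median(df$foci[detected]) else 0
    present <- detected & df$foci >= presence_frac * plateau
    io <- presence_window(present, hysteresis)
    complete_start <- bounds[ci] > 0L          # preceded by an observed division
    complete_end <- bounds[ci + 1L] < n_f      # followed by one
    traces[[length(traces) + 1L]] <- structure(list(
      cell_id = length(traces) + 1L,
      frames = df, present = present,
      birth_frame = fr[1], division_frame = fr[length(fr)],
      initiation_frame = if (is.na(io[1])) NA_integer_ else fr[io[1]],
      termination_frame = if (is.na(io[2])) NA_integer_ else fr[io[2]],
      complete = complete_start && complete_end,
      doubling_min = (length(fr)) * frame_interval_s / 60,
      replication_min = if (anyNA(io)) NA_real_ else
        (io[2] - io[1]) * frame_interval_s / 60,
      frame_interval_s = frame_interval_s,
      flags = NULL), class = "cell_cycle_trace")
  }
  traces
}

# first/last index of the focus-presence series under hysteresis;
# c(NA, NA) when no run of >= hyst consecutive TRUE exists
presence_window <- function(present, hyst = 2L) {
  r <- rle(present)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  open <- which(r$values & r$lengths >= hyst)
  if (!length(open)) return(c(NA_integer_, NA_integer_))
  first <- starts[open[1]]
  # close only after >= hyst consecutive absent frames (or series end)
  last <- ends[open[length(open)]]
  # merge runs separated by short gaps
  if (length(open) > 1L) {
    gaps <- which(!r$values & r$lengths < hyst)
    # last detected frame of the final qualifying run
    last <- ends[open[length(open)]]
  }
  c(first, last)
}

#' @export
print.cell_cycle_trace <- function(x, ...) {
  cat(sprintf("Cell cycle %d: frames %d-%d (%.3g min doubling)%s\n",
              x$cell_id, x$birth_frame, x$division_frame, x$doubling_min,
              if (isTRUE(x$complete)) "" else " [incomplete]"))
  if (!is.na(x$initiation_frame))
    cat(sprintf("  replication: frames %d-%d (%.3g min)\n",
                x$initiation_frame, x$termination_frame, x$replication_min))
  else cat("  non-replicating (no focus window)\n")
  invisible(x)
}

#' Apply selection criteria to segmented cell-cycle traces
#'
#' Flags each trace on four criteria: cell length within a band, minimal
#' relative elongation over the cycle, observation of a complete cycle
#' (bounded by divisions on both sides), and a fluorescence signal that both
#' starts and ends in a diffuse (focus-free) state. Only all-pass traces are
#' marked selected.
#'
#' @param traces list of `cell_cycle_trace` (from [segment_cycles()]).
#' @param birth_length_px nominal birth length; the accepted length band is
#'   `length_band * birth_length_px`.
#' @param length_band multiplicative band, default c(0.5, 2).
#' @param min_elongation minimal end/start length ratio, default 1.5.
#' @param diffuse_margin frames at each end that must be focus-free.
#' @return the traces with a `flags` list (length_ok, growth_ok, complete,
#'   diffuse_ends, selected) set on each, plus an attribute
#'   `selection_report` counting rejections per criterion.
#' @export
select_cells <- function(traces, birth_length_px,
                         length_band = c(0.5, 2), min_elongation = 1.5,
                         diffuse_margin = 1L) {
  rej <- c(length_ok = 0L, growth_ok = 0L, complete = 0L, diffuse_ends = 0L)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    len <- tr$frames$length_px
    f <- list(
      length_ok = all(len >= length_band[1] * birth_length_px &
                        len <= length_band[2] * birth_length_px),
      growth_ok = len[length(len)] / len[1] >= min_elongation,
      complete = isTRUE(tr$complete),
      diffuse_ends = {
        n <- length(tr$present)
        m <- min(diffuse_margin, n)
        !any(tr$present[seq_len(m)]) && !any(tr$present[n - seq_len(m) + 1L])
      })
    f$selected <- all(unlist(f[1:4]))
    for (nm in names(rej)) if (!f[[nm]]) rej[nm] <- rej[nm] + 1L
    traces[[i]]$flags <- f
  }
  attr(traces, "selection_report") <-
    list(n = length(traces),
         n_selected = sum(vapply(traces, function(t) t$flags$selected, TRUE)),
         rejections = as.list(rej))
  traces
}

#' Analyze a time-lapse scene end to end
#'
#' Runs the full preprocessing and segmentation chain: fiducial drift
#' correction, per-frame rolling-ball background subtraction and flat-field
#' correction, kymograph construction, pole detection, cycle segmentation and
#' selection.
#'
#' @param fluor,bf fluorescence and brightfield stacks (row x col x frame).
#' @param beam_profile measured illumination profile (matrix).
#' @param channel_region list with `rows`, `cols` of the channel band.
#' @param fiducial_region list with `rows`, `cols` around the fiducial in
#'   frame 1.
#' @param frame_interval_s frame spacing, s.
#' @param birth_length_px nominal birth length for the selection band.
#' @param ball_radius_px rolling-ball radius.
#' @param kymo_pad columns added on each side of the channel band for the
#'   kymograph, so PSF-blurred cell signal spilling past the channel walls is
#'   still integrated (default 3).
#' @param ... passed to [segment_cycles()].
#' @return object of class `timelapse_analysis`: traces, kymograph, poles,
#'   drift shifts, selection report.
#' @export
analyze_timelapse <- function(fluor, bf, beam_profile, channel_region,
                              fiducial_region, frame_interval_s,
                              birth_length_px = 16, ball_radius_px = 15,
                              kymo_pad = 3L, ...) {
  dr <- correct_drift(fluor, fiducial_region)
  fluor_c <- dr$stack
  bf_c <- bf
  for (fi in seq_len(dim(bf)[3]))
    bf_c[, , fi] <- shift_frame(bf[, , fi], -dr$shifts$drow[fi],
                                -dr$shifts$dcol[fi])
  for (fi in seq_len(dim(fluor_c)[3])) {
    fr <- subtract_background(fluor_c[, , fi], ball_radius_px)
    fluor_c[, , fi] <- correct_illumination(fr, beam_profile)
  }
  poles <- detect_poles(bf_c, channel_region)
  wide <- list(rows = channel_region$rows,
               cols = max(1, min(channel_region$cols) - kymo_pad):
                 min(dim(fluor_c)[2], max(channel_region$cols) + kymo_pad))
  kymo <- build_kymograph(fluor_c, wide)
  traces <- segment_cycles(kymo, poles, frame_interval_s, ...)
  traces <- select_cells(traces, birth_length_px)
  structure(list(traces = traces, kymograph = kymo, poles = poles,
                 shifts = dr$shifts,
                 selection_report = attr(traces, "selection_report"),
                 frame_interval_s = frame_interval_s),
            class = "timelapse_analysis")
}

#' @export
print.timelapse_analysis <- function(x, ...) {
  rep_ok <- vapply(x$traces, function(t) !is.na(t$replication_min), TRUE)
  sel <- vapply(x$traces, function(t) isTRUE(t$flags$selected), TRUE)
  cat(sprintf("Time-lapse analysis: %d cycles segmented, %d selected\n",
              length(x$traces), sum(sel)))
  if (any(rep_ok & sel))
    cat(sprintf("  mean replication %.3g min, mean doubling %.3g min (selected)\n",
                mean(vapply(x$traces[sel & rep_ok], `[[`, 0,
                            "replication_min")),
                mean(vapply(x$traces[sel], `[[`, 0, "doubling_min"))))
  invisible(x)
}
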