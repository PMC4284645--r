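#' Run the full synthetic study: generate, analyze, calibrate, average
#'
#' Convenience driver reproducing the complete experiment in silico:
#' generates `n_channels` independent growth-channel movies, runs the
#' time-lapse pipeline on each (drift correction, background and flat-field
#' correction, kymograph, cycle segmentation, selection), builds a
#' single-fluorophore standard from a calibration field at the scene's unit
#' intensity, converts the selected traces to molecule counts and aligns
#' them on replication phase.
#'
#' @param n_channels number of independent channel movies.
#' @param cycles_per_channel complete, division-bounded mother-cell cycles
#'   per movie (two extra cycles are simulated: the movie edges truncate the
#'   first and last).
#' @param seed master RNG seed; per-channel seeds are derived from it.
#' @param config_args named list of overrides passed to [scene_config()].
#' @param n_cal_spots molecules in the calibration field.
#' @param use_truth_beam use the generator's beam profile for the flat-field
#'   step (the experimentally "previously measured" profile).
#' @return list with `curves` ([align_and_average()] result), `traces`
#'   (selected, quantified), `timing` (data.frame of recovered replication
#'   and doubling times, minutes), `standard`, `analyses`, `selection`.
#' @export
run_study <- function(n_channels = 4L, cycles_per_channel = 4L, seed = 1L,
                      config_args = list(), n_cal_spots = 200L,
                      use_truth_beam = TRUE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_channels + 1L)
  cfg0 <- do.call(scene_config, c(list(n_cycles = cycles_per_channel + 2L,
                                       seed = seeds[1]), config_args))
  cal <- generate_calibration_field(cfg0$unit_intensity, n_cal_spots,
                                    psf_sigma_px = cfg0$psf_sigma_px,
                                    bg_offset = cfg0$bg_offset,
                                    read_sd = cfg0$read_sd,
                                    exposure_s = cfg0$exposure_s,
                                    seed = seeds[n_channels + 1L])
  standard <- unit_intensity(cal$stack[, , 1], exposure_s = cal$exposure_s)

  all_traces <- list()
  analyses <- vector("list", n_channels)
  n_seg <- 0L; n_sel <- 0L
  for (ch in seq_len(n_channels)) {
    cfg <- do.call(scene_config, c(list(n_cycles = cycles_per_channel + 2L,
                                        seed = seeds[ch]), config_args))
    sc <- generate_timelapse(cfg)
    band <- sc$truth$band
    region <- list(rows = seq_len(cfg$height_px), cols = band[1]:band[2])
    fid <- list(rows = pmax(1, cfg$fiducial_pos[1] + (-2:2)),
                cols = pmax(1, cfg$fiducial_pos[2] + (-2:2)))
    an <- analyze_timelapse(sc$fluor, sc$bf,
                            beam_profile = if (use_truth_beam) sc$truth$beam
                                           else matrix(1, cfg$height_px,
                                                       cfg$width_px),
                            channel_region = region, fiducial_region = fid,
                            frame_interval_s = cfg$frame_interval_s,
                            birth_length_px = cfg$birth_length_px)
    analyses[[ch]] <- an
    n_seg <- n_seg + length(an$traces)
    for (tr in an$traces) {
      if (!isTRUE(tr$flags$selected)) next
      n_sel <- n_sel + 1L
      tr$channel <- ch
      all_traces[[length(all_traces) + 1L]] <-
        quantify_trace(tr, standard, survival = cfg$bleach_survival)
    }
  }
  timing <- data.frame(
    replication_min = vapply(all_traces, `[[`, 0, "replication_min"),
    doubling_min = vapply(all_traces, `[[`, 0, "doubling_min"))
  curves <- align_and_average(all_traces)
  list(curves = curves, traces = all_traces, timing = timing,
       standard = standard, analyses = analyses,
       selection = list(n_segmented = n_seg, n_selected = n_sel))
}

#' End-of-cycle total content of quantified traces
#'
#' Mean total molecule count at the final pre-division frame across traces.
#'
#' @param traces quantified traces (see [quantify_trace()]).
#' @param n_last number of final frames averaged per trace (default 1).
#' @return list with `mean`, `per_cell`, `n`.
#' @export
end_of_cycle_total <- function(traces, n_last = 1L) {
  per <- vapply(traces, function(tr) {
    m <- tr$molecules$total
    mean(utils::tail(m, n_last))
  }, 0)
  list(mean = mean(per), per_cell = per, n = length(per))
}

#' Analyze a synthetic PALM experiment end to end
#'
#' Builds traces from the movie, keeps in-cell single-step traces, fits the
#' censored-exponential disappearance constant and applies the bleach
#' correction with bootstrap confidence interval.
#'
#' @param movie result of [generate_palm_movie()].
#' @param t_bleach_wall wall-clock bleaching constant, s (e.g. from
#'   [bleach_time()] on a fast movie).
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param apply_single_step_filter run [filter_single_step()] on each trace.
#' @return list with `estimate` ([unloading_time()] result), `set`
#'   (the on-time set), `traces`, `n_rejected_outside`.
#' @export
analyze_palm <- function(movie, t_bleach_wall, B = 2000L, seed = 1L,
                         apply_single_step_filter = TRUE) {
  traces <- build_traces(movie$stack, movie$cell_mask,
                         movie$frame_interval)
  keep <- traces
  if (apply_single_step_filter) {
    keep <- Filter(function(tr) {
      if (tr$censored) return(TRUE)
      # extend the intensity series past the drop so the step is observable
      fr <- tr$first_frame:min(tr$last_frame + 3L, dim(movie$stack)[3])
      ints <- vapply(fr, function(fi)
        spot_photometry(movie$stack[, , fi],
                        data.frame(row = tr$pos[1], col = tr$pos[2])), 0)
      if (length(ints) < 3L) return(TRUE)
      isTRUE(as.logical(filter_single_step(ints)))
    }, traces)
  }
  if (!length(keep)) stop("no traces survived filtering")
  set <- on_time_set(vapply(keep, `[[`, 0, "on_time_s"),
                     frame_interval = movie$frame_interval,
                     exposure = movie$exposure,
                     censored = vapply(keep, `[[`, TRUE, "censored"),
                     movie_length = (dim(movie$stack)[3] - 1L) *
                       movie$frame_interval)
  t_obs <- fit_on_times(set)
  est <- unloading_time(t_obs, t_bleach_wall, set, B = B, seed = seed)
  list(estimate = est, set = set, traces = keep,
       n_rejected_outside = attr(traces, "n_rejected_outside"))
}
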