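#' Kinetic parameters of the clamp loading/unloading birth-death model
#'
#' The number of DNA-bound sliding clamps during chromosomal replication is
#' modelled as a birth-death chain: clamps are loaded at a constant effective
#' rate `k_p` (set by primer formation, each new primer-template junction
#' consuming one clamp) while each bound clamp is independently unloaded with
#' time constant `t_unload`. Loading is switched off at the replication
#' (termination) time `t_rep`; unloading continues unchanged afterwards.
#'
#' @param k_p effective loading (primer formation) rate, events per second.
#' @param t_unload per-clamp unloading time constant, seconds.
#' @param t_rep replication duration, seconds; loading stops at this time.
#' @param dt fixed simulation step in seconds for [simulate_fixed_dt()].
#'   Defaults to `min(1/k_p, t_unload)/1000`. Steps for which the one-step
#'   event probabilities `dt*k_p` or `n*dt/t_unload` could reach 0.1 are
#'   refused outright rather than clipped.
#' @param n_init initial number of bound clamps (non-negative integer).
#'
#' @return an object of class `kinetic_params`.
#' @seealso [steady_state_mean()], [mean_trajectory()], [simulate_fixed_dt()],
#'   [simulate_exact()]
#' @export
kinetic_params <- function(k_p, t_unload, t_rep, dt = NULL, n_init = 0L) {
  stopifnot(is.numeric(k_p), length(k_p) == 1L,
            is.numeric(t_unload), length(t_unload) == 1L,
            is.numeric(t_rep), length(t_rep) == 1L)
  if (!is.finite(k_p) || k_p < 0)
    stop("k_p must be a finite non-negative rate (events/s)")
  if (!is.finite(t_unload) || t_unload <= 0)
    stop("t_unload must be a positive time constant (s)")
  if (!is.finite(t_rep) || t_rep <= 0)
    stop("t_rep must be a positive duration (s)")
  if (length(n_init) != 1L || !is.finite(n_init) || n_init < 0 ||
      n_init != round(n_init))
    stop("n_init must be a non-negative integer")
  n_init <- as.integer(n_init)
  if (is.null(dt)) {
    dt <- if (k_p > 0) min(1 / k_p, t_unload) / 1000 else t_unload / 1000
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive step (s)")
  if (dt * k_p >= 0.1)
    stop("dt too large: dt * k_p = ", signif(dt * k_p, 3),
         " violates the step-probability bound (< 0.1)")
  # conservative bound on the reachable count: stationary mean + 10 sd,
  # or the initial count if larger
  n_max <- max(n_init, ceiling(k_p * t_unload + 10 * sqrt(k_p * t_unload + 1)))
  if (dt * n_max / t_unload >= 0.1)
    stop("dt too large: dt * N_max / t_unload = ",
         signif(dt * n_max / t_unload, 3),
         " violates the step-probability bound (< 0.1) for reachable N_max = ",
         n_max)
  structure(list(k_p = k_p, t_unload = t_unload, t_rep = t_rep,
                 dt = dt, n_init = n_init, n_max = n_max),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Clamp birth-death kinetics\n")
  cat(sprintf("  loading rate k_p     : %.4g /s (one every %.3g s)\n",
              x$k_p, if (x$k_p > 0) 1 / x$k_p else Inf))
  cat(sprintf("  unloading time       : %.4g s per clamp\n", x$t_unload))
  cat(sprintf("  replication duration : %.4g s\n", x$t_rep))
  cat(sprintf("  simulation step dt   : %.4g s; initial count %d\n",
              x$dt, x$n_init))
  cat(sprintf("  stationary mean      : %.4g bound clamps\n",
              x$k_p * x$t_unload))
  invisible(x)
}

#' Stationary mean number of DNA-bound clamps
#'
#' The birth-death chain with constant loading rate `k_p` and per-capita
#' unloading rate `1/t_unload` has a Poisson stationary law with mean
#' `k_p * t_unload`; this is the plateau reached during steady-state
#' replication.
#'
#' @param params a [kinetic_params()] object.
#' @return the stationary mean bound count (numeric scalar).
#' @export
steady_state_mean <- function(params) {
  if (!inherits(params, "kinetic_params"))
    stop("params must be a kinetic_params object")
  params$k_p * params$t_unload
}

#' Effective loading interval from the steady-state balance
#'
#' At plateau the total unloading flux `n_ss / t_unload` is balanced by the
#' loading flux `1 / t_load_eff`, so the effective time between consecutive
#' clamp loading events is `t_unload / n_ss`.
#'
#' @param n_ss steady-state mean number of bound clamps (> 0).
#' @param t_unload per-clamp unloading time constant, seconds (> 0).
#' @return an object of class `effective_loading` with fields `t_load_eff`
#'   (seconds per loaded clamp) and `n_ss`.
#' @export
effective_loading_time <- function(n_ss, t_unload) {
  stopifnot(is.numeric(n_ss), length(n_ss) == 1L,
            is.numeric(t_unload), length(t_unload) == 1L)
  if (!is.finite(n_ss) || n_ss <= 0) stop("n_ss must be positive")
  if (!is.finite(t_unload) || t_unload <= 0) stop("t_unload must be positive")
  structure(list(t_load_eff = t_unload / n_ss, n_ss = n_ss,
                 t_unload = t_unload),
            class = "effective_loading")
}

#' @export
print.effective_loading <- function(x, ...) {
  cat(sprintf(
    "Steady-state balance: %.4g bound clamps, unloaded once every %.4g s\n",
    x$n_ss, x$t_unload))
  cat(sprintf("  => one clamp loaded every %.4g s (~%d s)\n",
              x$t_load_eff, round(x$t_load_eff)))
  invisible(x)
}

#' Analytic mean of the bound-clamp count over time
#'
#' Closed-form solution of the mean of the birth-death chain. While loading is
#' on (`t <= t_rep`):
#' `N(t) = k_p * t_unload * (1 - exp(-t/t_unload)) + n_init * exp(-t/t_unload)`.
#' After termination loading stops and the mean decays exponentially from its
#' value at `t_rep` with time constant `t_unload`.
#'
#' @param params a [kinetic_params()] object.
#' @param t time(s) in seconds, `>= 0`; vectorized.
#' @return mean bound count at each `t`.
#' @export
mean_trajectory <- function(params, t) {
  if (!inherits(params, "kinetic_params"))
    stop("params must be a kinetic_params object")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative")
  nss <- params$k_p * params$t_unload
  rise <- function(tt)
    nss * (1 - exp(-tt / params$t_unload)) +
      params$n_init * exp(-tt / params$t_unload)
  out <- numeric(length(t))
  pre <- t <= params$t_rep
  out[pre] <- rise(t[pre])
  if (any(!pre)) {
    n_rep <- rise(params$t_rep)
    out[!pre] <- n_rep * exp(-(t[!pre] - params$t_rep) / params$t_unload)
  }
  out
}

#' Time for the analytic mean to first reach a fraction of its plateau
#'
#' Solves `N(t) = frac * n_ss` for the rising phase, starting from
#' `n_init = 0`: `t = -t_unload * log(1 - frac)`.
#'
#' @param params a [kinetic_params()] object (with `k_p > 0`).
#' @param frac plateau fraction in (0, 1); default 0.95.
#' @return time in seconds.
#' @export
rise_time <- function(params, frac = 0.95) {
  if (!inherits(params, "kinetic_params"))
    stop("params must be a kinetic_params object")
  if (params$k_p <= 0) stop("rise time undefined for k_p = 0")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  -params$t_unload * log(1 - frac)
}

new_clamp_trajectory <- function(times, counts, seed, method) {
  structure(list(times = times, counts = as.integer(counts),
                 seed = seed, method = method),
            class = "clamp_trajectory")
}

#' @export
print.clamp_trajectory <- function(x, ...) {
  cat(sprintf(
    "Clamp trajectory (%s sampler): %d time points over %.4g s, seed %s\n",
    x$method, length(x$times), max(x$times), format(x$seed)))
  cat(sprintf("  counts: start %d, end %d, max %d\n",
              x$counts[1], x$counts[length(x$counts)], max(x$counts)))
  invisible(x)
}

#' @export
plot.clamp_trajectory <- function(x, ...) {
  graphics::plot(x$times / 60, x$counts, type = "s",
                 xlab = "time (min)", ylab = "DNA-bound clamps", ...)
  invisible(x)
}

#' Fixed-step Monte Carlo simulation of the bound-clamp count
#'
#' In each step `dt` a loading event fires with probability `dt * k_p`
#' (only while elapsed time is at most `t_rep`) and an unloading event with
#' probability `count * dt / t_unload`; the two draws are independent, so both
#' may fire in one step (net change zero). Steps whose event probabilities
#' could reach 0.1 are refused at construction of the parameter object.
#'
#' @param params a [kinetic_params()] object.
#' @param duration total simulated time, seconds.
#' @param seed integer RNG seed; recorded in the output.
#' @return a `clamp_trajectory` with times `0, dt, 2*dt, ...` and counts.
#' @export
simulate_fixed_dt <- function(params, duration, seed) {
  ens <- simulate_fixed_dt_ensemble(params, duration, n_rep = 1L, seed = seed)
  new_clamp_trajectory(ens$times, ens$counts[, 1L], seed, "fixed-dt")
}

#' Ensemble of fixed-step simulations
#'
#' Same chain as [simulate_fixed_dt()], advanced for `n_rep` independent
#' replicates simultaneously (one uniform pair per replicate per step).
#'
#' @inheritParams simulate_fixed_dt
#' @param n_rep number of independent replicates.
#' @param record_times optional increasing vector of times (s) at which to
#'   record counts; defaults to every step. Recording at a time captures the
#'   state after the last step at or before it.
#' @return list with `times` and an integer matrix `counts`
#'   (`length(times)` x `n_rep`).
#' @export
simulate_fixed_dt_ensemble <- function(params, duration, n_rep, seed,
                                       record_times = NULL) {
  if (!inherits(params, "kinetic_params"))
    stop("params must be a kinetic_params object")
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  dt <- params$dt
  n_steps <- ceiling(duration / dt)
  if (is.null(record_times)) {
    rec_steps <- 0:n_steps
  } else {
    if (any(record_times < 0) || any(record_times > n_steps * dt))
      stop("record_times outside simulated range")
    rec_steps <- floor(record_times / dt)
  }
  set.seed(seed)
  counts <- rep.int(params$n_init, n_rep)
  out <- matrix(0L, nrow = length(rec_steps), ncol = n_rep)
  rec_i <- 1L
  if (rec_steps[1L] == 0L) { out[1L, ] <- counts; rec_i <- 2L }
  p_birth <- dt * params$k_p
  lim <- 0.1 * params$t_unload / dt  # count at which p_death would hit 0.1
  for (s in seq_len(n_steps)) {
    # loading is on while the elapsed time at the start of the step <= t_rep
    loading_on <- (s - 1L) * dt <= params$t_rep
    births <- if (loading_on) stats::runif(n_rep) < p_birth else FALSE
    deaths <- stats::runif(n_rep) < counts * dt / params$t_unload
    counts <- counts + as.integer(births) - as.integer(deaths)
    if (any(counts >= lim))
      stop("dt step-probability bound violated at count ", max(counts),
           "; choose a smaller dt")
    while (rec_i <= length(rec_steps) && rec_steps[rec_i] == s) {
      out[rec_i, ] <- counts
      rec_i <- rec_i + 1L
    }
  }
  list(times = rec_steps * dt, counts = out)
}

#' Event-driven (exact) simulation of the bound-clamp count
#'
#' Samples the same birth-death chain by exact next-event (Gillespie)
#' simulation: while `t < t_rep` the total event rate is
#' `k_p + n/t_unload`; after `t_rep` only unloading remains. Crossing of
#' `t_rep` is handled by restarting the (memoryless) waiting time at `t_rep`
#' with the post-termination rates.
#'
#' @inheritParams simulate_fixed_dt
#' @return a `clamp_trajectory` with event times (prepended 0, appended
#'   `duration`) and right-continuous counts.
#' @export
simulate_exact <- function(params, duration, seed) {
  if (!inherits(params, "kinetic_params"))
    stop("params must be a kinetic_params object")
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  set.seed(seed)
  t_cur <- 0
  n <- params$n_init
  # generous preallocation: expected number of events + slack
  n_exp <- ceiling(2 * (params$k_p * min(duration, params$t_rep) +
                          params$n_init) + 10 * sqrt(params$k_p * duration + 4) +
                     100)
  times <- numeric(n_exp); counts <- integer(n_exp)
  times[1L] <- 0; counts[1L] <- n; i <- 1L
  grow <- function(v) c(v, vector(mode = mode(v), length = length(v)))
  repeat {
    b <- if (t_cur < params$t_rep) params$k_p else 0
    d <- n / params$t_unload
    rate <- b + d
    if (rate <= 0) {
      if (t_cur < params$t_rep && params$k_p > 0) stop("internal: zero rate")
      break
    }
    tau <- stats::rexp(1L, rate)
    if (t_cur < params$t_rep && t_cur + tau > params$t_rep) {
      # birth channel closes at t_rep; memorylessness lets us resample there
      t_cur <- params$t_rep
      next
    }
    t_cur <- t_cur + tau
    if (t_cur > duration) break
    n <- if (stats::runif(1L) < b / rate) n + 1L else n - 1L
    i <- i + 1L
    if (i > length(times)) { times <- grow(times); counts <- grow(counts) }
    times[i] <- t_cur; counts[i] <- n
  }
  if (times[i] < duration) {
    i <- i + 1L
    if (i > length(times)) { times <- grow(times); counts <- grow(counts) }
    times[i] <- duration; counts[i] <- n
  }
  new_clamp_trajectory(times[seq_len(i)], counts[seq_len(i)], seed, "exact")
}

#' Evaluate a trajectory at arbitrary times
#'
#' Right-continuous step interpolation of a `clamp_trajectory`.
#'
#' @param traj a `clamp_trajectory`.
#' @param t times (s) within the simulated range.
#' @return integer counts at `t`.
#' @export
trajectory_at <- function(traj, t) {
  stopifnot(inherits(traj, "clamp_trajectory"))
  idx <- findInterval(t, traj$times)
  if (any(idx < 1L)) stop("t before trajectory start")
  traj$counts[idx]
}

#' Exact stationary law of the fixed-dt chain
#'
#' Enumerates the stationary distribution of the discretized birth-death chain
#' used by [simulate_fixed_dt()] (independent birth/death draws per step) via
#' detailed balance on 0..n_max. Used to quantify the discretization error of
#' the fixed-step scheme against the Poisson law of the continuous-time chain.
#'
#' @param params a [kinetic_params()] object (loading phase, `t <= t_rep`).
#' @param n_max upper state bound; defaults to the parameter object's bound.
#' @return numeric vector of probabilities for counts `0..n_max`.
#' @export
fixed_dt_stationary <- function(params, n_max = params$n_max) {
  stopifnot(inherits(params, "kinetic_params"))
  dt <- params$dt
  pb <- dt * params$k_p
  n <- 0:(n_max - 1L)
  pd <- (n + 1L) * dt / params$t_unload
  if (any(pd >= 1)) stop("n_max too large for this dt")
  # detailed balance: pi(n+1)/pi(n) = P(up at n) / P(down at n+1)
  up <- pb * (1 - n * dt / params$t_unload)
  down <- pd * (1 - pb)
  logpi <- c(0, cumsum(log(up) - log(down)))
  pi <- exp(logpi - max(logpi))
  pi / sum(pi)
}
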