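# clampdyn

Quantification of DNA sliding-clamp dynamics from live-cell fluorescence
microscopy.

During chromosomal replication in *E. coli*, the β₂ sliding clamp (DnaN) is
loaded onto every new primer–template junction and unloaded again much more
slowly, so DNA-bound clamps accumulate behind the replication forks.
`clampdyn` implements the quantitative machinery needed to measure this in
single cells growing in mother-machine microfluidic channels:

* **Kinetics** — the bound-clamp count N(t) is a birth–death chain with
  constant loading rate *k*ₚ and per-capita unloading rate 1/*t*ᵤ. Its
  stationary law is Poisson with mean *N*ₛₛ = *k*ₚ·*t*ᵤ, and at plateau the
  unloading flux balances loading: *t*_load = *t*ᵤ/*N*ₛₛ. With the measured
  *t*ᵤ = 195 s and *N*ₛₛ = 46, one clamp is loaded every ~4 s. The package
  provides the closed-form mean trajectory, a fixed-step Monte Carlo sampler
  and an exact event-driven sampler.
* **Synthetic microscopy** — a generator that renders mother-machine
  time-lapse stacks (growing, dividing cells with replication-cycle focal
  dynamics, uneven illumination, stage drift with a fiducial marker,
  photobleaching, Poisson + read noise), PALM movies of single activated
  molecules, and single-fluorophore calibration fields — each with exact
  ground truth, so every pipeline stage is testable without any microscope.
* **Time-lapse quantification** — rolling-ball background subtraction,
  flat-field correction, integer-pixel fiducial drift correction, kymograph
  construction, division/replication cycle segmentation, cell selection,
  and per-frame decomposition of each cell's line profile into background,
  cytoplasm and foci (conserving total intensity exactly).
* **Calibration** — a single-fluorophore intensity standard (trimmed mean of
  isolated-spot photometry), photobleaching correction (geometric for fixed
  cohorts; a balanced-growth equilibrium correction for growing cells),
  dimer accounting (two fluorophore fusions per clamp), and phase-aligned
  population averaging.
* **PALM dwell times** — à-trous B3-spline wavelet spot detection,
  single-molecule trace building with a gap rule, single-step filtering,
  an interval/right-censored exponential MLE of the observed disappearance
  constant, duty-cycle-scaled bleaching correction by rate subtraction
  (1/*t*_obs = 1/*t*ᵤ + 1/*t*_bleach), and bootstrap confidence intervals.

## Worked example

```r
library(clampdyn)

## the birth-death model at the measured parameters
p <- kinetic_params(k_p = 46/195, t_unload = 195, t_rep = 68*60)
p
#> Clamp birth-death kinetics
#>   loading rate k_p     : 0.2359 /s (one every 4.24 s)
#>   unloading time       : 195 s per clamp
#>   replication duration : 4080 s
#>   simulation step dt   : 0.004239 s; initial count 0
#>   stationary mean      : 46 bound clamps
effective_loading_time(46, 195)
#> Steady-state balance: 46 bound clamps, unloaded once every 195 s
#>   => one clamp loaded every 4.239 s (~4 s)
rise_time(p) / 60        # minutes to reach 95% of the plateau
#> [1] 9.73613

## a complete in-silico experiment: 6 growth channels, 5 cycles each
res <- run_study(n_channels = 6, cycles_per_channel = 5, seed = 7)
res$standard
#> Single-fluorophore standard: I1 = 351 +/- 8.6 counts/frame (n = 194, 0.08 s exposure)
res$curves
#> Population curves from 27 aligned traces (0 excluded)
#>   plateau (phase 0.3-0.9): 48.24 bound clamps (s.d. 7.41, s.e.m. 1.43)
#>   bound fraction at mid-replication: 0.529
mean(res$timing$replication_min)   # 68.6 min  (generator truth: 68)
mean(res$timing$doubling_min)      # 84.6 min  (generator truth: 84)
end_of_cycle_total(res$traces)$mean  # 118.1 dimers (generator truth: 120)

## PALM: 84 censored on-times at a 195 s dwell with 500 s wall-clock bleach
s <- simulate_on_times(84, t_unload = 195, t_bleach_wall = 500,
                       frame_interval = 5, movie_length = 600, seed = 11)
unloading_time(fit_on_times(s), 500, s, B = 2000, seed = 1)
#> Clamp unloading-time estimate (bleach-corrected)
#>   observed disappearance constant : 158 s (n = 84)
#>   wall-clock bleaching constant   : 500 s
#>   unloading time t_unload         : 231.1 s
#>   95% bootstrap CI               : [171.6, 306.8] s (B = 2000)
```

A single draw of 84 molecules is noisy (the 95% CI above spans ~135 s);
averaged over replicate experiments the estimator centres on the true
195 s — that average is what the acceptance script reports.

The interpretation: the plateau of ~46 DNA-bound clamp dimers, sustained
while one clamp is loaded every ~4 s but each takes ~195 s to leave,
means dozens of clamps remain on the DNA behind the forks — a docking
platform for ligase, mismatch repair and other clamp-binding proteins.

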