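---
title: "Measuring sliding-clamp loading and unloading in single cells"
author: "clampdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sliding-clamp loading and unloading in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampdyn)
```

# The model

The number of DNA-bound β₂ sliding clamps during replication is modelled as
a birth–death chain. Clamps are loaded at a constant effective rate $k_p$ —
"effective" because what is measured is the total loading flux onto DNA,
rate-limited by primer formation on the lagging strand, with the loading
reaction itself assumed fast so no queue of free primers builds up. Each
bound clamp is unloaded independently with time constant $t_u$. While
loading is on ($t \le t_{rep}$) the mean obeys

$$N(t) = k_p t_u\,(1 - e^{-t/t_u}) + N_0\,e^{-t/t_u},$$

and the stationary law is Poisson with mean $N_{ss} = k_p t_u$. At
termination the loading rate switches to zero and the bound count decays
with the same $t_u$ — the removal rate observed after termination matches
the one measured during steady state, so a single unloading constant is
used throughout. At plateau, the balance $N_{ss}/t_u = 1/t_{load}$ gives
the effective loading interval $t_{load} = t_u / N_{ss}$; with $t_u=195$ s
and $N_{ss}=46$ that is one clamp every ~4.2 s, and the mean reaches 95% of
plateau at $-t_u \ln 0.05 \approx 9.7$ min.

Two samplers implement the chain. `simulate_fixed_dt()` is the discrete
scheme: per step, a loading event fires with probability $k_p\,dt$ and an
unloading event with probability $n\,dt/t_u$, drawn independently (both may
fire; the net change is then zero — unbiased to $O(dt^2)$ and trivially
documented). Steps for which either probability could reach 0.1 are refused
at construction rather than clipped; the default is
$dt = \min(1/k_p, t_u)/1000$. `simulate_exact()` is the event-driven
(Gillespie) sampler of the same chain, used as the generator's workhorse
and as the fixed-step sampler's oracle: because the birth rate is constant
until $t_{rep}$, the crossing of $t_{rep}$ is handled by restarting the
memoryless waiting time there with the post-termination rates.
`fixed_dt_stationary()` enumerates the discrete chain's stationary law via
detailed balance, which lets the test suite show the discretization error
shrinking with $dt$ *deterministically* instead of by flaky two-sample
testing; distributional agreement between the samplers is checked with a
chi-square homogeneity test, since counts are small integers for which a
Kolmogorov–Smirnov test is ill-defined under ties.

# What the generator emulates — and what it does not

`generate_timelapse()` renders a dead-end growth channel holding a mother
cell imaged every 2.5 min at 80 ms exposure, 160 nm pixels, Gaussian PSF of
1.3 px. Per frame the cell contributes a uniform cytoplasmic layer and one
or two diffraction-limited foci (one before a configurable
sister-separation fraction of replication, 0.35 by default, two after, the
bound count split binomially), all convolved with the PSF, modulated by a
Gaussian illumination profile, plus a smooth additive background, a bright
fiducial marker drifting with the stage, and Poisson shot noise with
Gaussian read noise. The daughter cell is flushed from the channel
instantly at division, so exactly one cell is present — a deliberate
simplification that makes pole detection trivial while preserving
everything the analysis actually measures.

Cycle timing: per-cell replication durations are drawn from
$\mathcal N(68, 10^2)$ min truncated to [40, 95]; the flanking
birth-to-initiation (B) and termination-to-division (D) periods are
$\mathcal N(9, 2.5^2)$ and $\mathcal N(7, 2.5^2)$ min truncated at 5 min,
so the configured mean doubling time is $9+68+7 = 84$ min. The B/D split
is a modelling choice (only their sum is constrained by the replication
and doubling times); the truncation keeps every cycle able to start and
end in a diffuse state, at the cost of a doubling-time spread (~11 min
s.d.) smaller than real populations show (~17 min). Total clamp content
grows exponentially from 60 to 120 dimers per cycle, deterministically —
expression noise is not modelled. Counts are kept in clamp (dimer) units;
each clamp carries two fluorophores. Residual bound clamps at division are
inherited binomially and decay during the next B period.

Photobleaching applies Bernoulli per-exposure survival (default 0.998,
mild bleaching consistent with shuttered acquisition) to each fluorophore,
with newly synthesized fluorophores entering intact; the truth records
both synthesized and intact counts so the correction is testable. Not
emulated: vectorial PSF and EM-register physics (EM gain is folded into
the unit intensity, which is a free parameter — default 350 counts per
fluorophore per frame — not a physical photon count), phase-contrast
physics, cell-shape fluctuations, lineage structure beyond the mother
cell, and fluorophore maturation (the dark fraction is taken as
negligible; the generator could inject one to quantify the induced bias,
which would be a pure undercount of all molecule numbers).

Passing tests on these scenes therefore demonstrate correct *algorithmic*
recovery under realistic noise, drift, illumination and bleaching — not
robustness to segmentation-hostile real images, which is what
MicrobeTracker-class tools are for.

# The time-lapse pipeline

Preprocessing follows the standard order: rolling-ball background
subtraction, then flat-field division by the (max-normalized) measured
beam profile, then integer-pixel drift correction by normalized
cross-correlation on a fiducial template from frame 1 (residual ≤ 1 px;
tracking aborts naming the frame if the correlation drops below 0.5). The
rolling ball is implemented as grayscale morphological opening with a disc
(radius 15 px by default — an order of magnitude above the PSF sigma,
below a cell length) on a lightly smoothed copy; EBImage's grayscale
morphology saturates at 1, so frames are rescaled around the operation.
Under shot noise any morphological background estimate sits slightly below
the mean (the opening of a noisy field tracks its lower envelope), leaving
a small positive residual — harmless, because the decomposition estimates
the remaining background per frame from outside-cell pixels.

Kymographs sum the channel band perpendicular to the channel axis, with
the band padded by 3 columns so PSF-blurred signal spilling past the
channel walls is still integrated. Divisions are frames where the
mother-cell length (from Otsu-thresholded brightfield) drops by more than
35%; cycles run between consecutive divisions, so both observed timings
are differences of identically-detected events and frame quantization
cancels in the mean.

The per-frame decomposition works on the cell's line profile (the
kymograph column restricted to the pole interval, padded by 2 rows for
axial PSF spill — valid here because the mother cell has no touching
neighbour). Background per position is the median of outside-cell
positions; the cytoplasm level is the median of the background-subtracted
in-cell profile; positions exceeding the cytoplasm level by 3 MAD (scaled
to s.d.) in contiguous runs of ≥ 2 (or a single position at twice that
significance) are foci. Three refinements matter in practice, all visible
in the ground-truth comparisons of the test suite:

* the cytoplasm level and noise are re-estimated once from rows clear of
  provisionally-detected foci — with two foci in a short cell, the raw
  median is biased up and the raw MAD reflects structure, not noise —
  preferring rows away from both the focal tails (mask dilated by 2) and
  the pole rows (which read low from axial PSF spill), relaxing only when
  too few rows remain;
* the noise estimate is floored by the outside-cell noise, so the
  refinement cannot run away by reclassifying ever more cytoplasm as
  focal;
* each focus is integrated over its run grown by 2 positions (tails just
  below threshold), with overlap between padded runs resolved by
  proximity and runs whose integral is below 6 MAD discarded.

Foci intensity per run is $\sum(\text{profile} - \text{cytoplasm level})$,
so the cytoplasm floor under a focus stays attributed to cytoplasm, and
background + cytoplasm + foci equals the raw in-cell total exactly. A run
holding two maxima separated by a deep dip counts as two sister foci
(capped at two).

Initiation and termination are the first/last frames with a *present*
focus, with 2-frame hysteresis. Presence requires both a detected focus
and foci intensity ≥ 25% of the cycle's plateau (the median over detected
frames): with a 195 s unloading tail, a purely statistical criterion keeps
"seeing" the decaying focus for 3–4 frames past termination and would
stretch the apparent replication time by ~8 min; the relative criterion
bounds that bias at about half a frame net. Cell selection applies four
flags — length within [0.5, 2]× the birth length, elongation ≥ 1.5×, a
complete (division-bounded) cycle, and a diffuse first and last frame
(1-frame margin; a 2-frame margin rejects half the population because the
unloading tail eats into the short D period, and biases the selected
doubling times upward).

# Calibration

`unit_intensity()` builds the single-fluorophore standard: wavelet
detection on a background-subtracted calibration field, isolation
filtering, then aperture photometry — a 9×9 box with the local background
taken as the *mean* over a surrounding annulus (a median sits ~1/3 count
below the Poisson mean and would bias every spot up by a third of the box
area; the wide annulus keeps the background term from dominating the
photometric variance) — summarized by a 10% trimmed mean with its s.e.m.
Unit intensity scales linearly with exposure (`scale_standard()`).

Photobleaching correction: for a fixed cohort (the calibration stack, or
any constant-content trace) the correction is geometric,
$I_n \mapsto I_n p^{-n}$ with $n$ the exposures since the start
(`bleach_correction()`). For a *growing* cell this over-corrects ever more
strongly with time, because continuous synthesis keeps replacing bleached
fluorophores: writing $g$ for the growth rate and $b = -\ln p$ for the
per-frame bleach rate, the balance $I_{n+1} = pI_n + \Delta N_n$ at
generation-to-generation equilibrium (a daughter inherits its mother's
unbleached fraction) has the unbleached fraction *constant* across the
cycle, $f = g/(g+b)$ in the continuous limit (≈ 0.914 at the defaults).
`bleach_equilibrium_fractions()` computes the exact discrete fixed point
and `quantify_trace(mode = "equilibrium")` divides by it; the geometric
mode remains available and appropriate for fixed cohorts. The residual
bias of the equilibrium correction (the model is exact for the generator's
bookkeeping) is at the percent level. Molecule conversion divides by the
unit intensity and, for the homodimeric clamp labelled on both subunits,
by two; uncertainty from the standard's s.e.m. propagates to first order.

`align_and_average()` maps each selected trace onto a replication phase in
[0, 1] (0 = detected initiation, 1 = detected termination) by linear
interpolation, averages pointwise, and reports plateau statistics over the
phase window [0.3, 0.9] — steady state spans roughly the central two
thirds of replication, and the window keeps clear of the rise and the
termination decay even with the ~1-frame detection latency at both ends.
The plateau mean is the mean of per-cell plateau means; the s.d. is that
of the pooled window samples; the s.e.m. divides by the number of cells.
The bound fraction is computed per cell, then averaged.

# PALM dwell-time analysis

Spot detection is the à-trous undecimated B3-spline wavelet transform:
detail planes hard-thresholded at $k \cdot$MAD (default $k=3$), detection
mask from the product of planes 2..3 (plane 1 is single-pixel noise),
connected components as spots, integrated intensity as the sum over the
detection region. Traces are built by nearest-position association within
a 2.5 px gate; a trace ends after 2 consecutive missed detections (the gap
rule balances blinking against true disappearance), spots outside the cell
mask are rejected, and intensities along a trace come from aperture
photometry at the locked first-detection position. The single-step filter
fits 1- and 2-step piecewise-constant models by least squares over all
changepoints and accepts a trace only if the second step does not improve
the variance ratio beyond 2.5 and the single step is downward to below 25%
of the plateau — rejecting multi-molecule and late-activation traces.

On-times are fitted by the interval/right-censored exponential MLE: an
observed on-time $m\Delta$ means the disappearance fell in
$((m-1)\Delta, m\Delta]$, censored molecules contribute the survival term.
Since every event interval has the same width $\Delta$, the MLE is closed
form, $\tau = \Delta / \log(1 + n\Delta/S)$ with $S$ the summed left
endpoints plus censored times; in the fine-frame uncensored limit it
reduces to the sample mean (minus $\Delta/2$, vanishing with $\Delta$). A
brute-force grid maximization of the same likelihood, and an independent
fit through the survival package, serve as oracles in the tests.

Bleaching is treated as an independent exponential competing risk:
$1/t_{obs} = 1/t_u + 1/t_{bleach}$. The bleach constant is fitted on a
fast-frame-rate movie where unloading is negligible, converted to the
illumination domain by that movie's duty cycle, and rescaled to the slow
movie's wall clock by its duty cycle (0.4 s / 5 s = 0.08 at the defaults,
turning 40 s of illumination into a 500 s wall-clock constant). The
confidence interval case-resamples the on-time set, refits, and applies
the same correction (percentile CI, default B = 10⁴ in the estimator
interface; the paper-scale 10⁶ is configurable but unnecessary for a
stable 95% interval). The assumption of independent exponential risks is
stated in the estimate object; if the observed constant is not smaller
than the bleaching constant the estimator refuses
("bleaching-dominated") rather than extrapolate.

# Numerical choices and degenerate inputs

* Coordinates are 1-based R matrix indices, axis order (row, col, frame),
  with the channel along rows; intervals are inclusive.
* The fixed-step sampler refuses invalid $dt$ (including mid-run, should
  the count reach the bound) instead of warning.
* `decompose_cell()` errors on cells narrower than 2 px and on an empty
  outside sample; conservation holds to 1e-9 relative for arbitrary
  profiles.
* The drift corrector's search radius defaults to ±6 px; a lost fiducial
  is an error naming the frame, not a silent skip.
* All stochastic entry points take an explicit seed and record it in
  their output; identical configuration and seed give bit-identical
  stacks.

# Problem sizes

The test suite runs the samplers at reduced rates (stationary means of
2–10) where distributional properties are checked at $n = 10^4$, and the
imaging pipeline on cohorts of 30–60 cells; the acceptance script runs the
full in-silico study at ~140 analyzed cells (27 channels × 6 cycles),
100 seeded PALM replicates of 84 on-times each, and completes in about a
minute on one CPU. These sizes were chosen so each estimate's Monte Carlo
error is comfortably inside the tolerance it is checked against.

# Known limitations

* The decomposition's foci/cytoplasm split is accurate to a few percent
  once foci are well separated; in the frame or two around
  sister-separation the two foci may merge into one run (the intensity is
  still conserved, only the count saturates at one).
* The equilibrium bleach correction assumes balanced exponential growth
  with content doubling per cycle; strongly non-steady-state populations
  need the geometric mode plus explicit cohort modelling.
* Out-of-focus loss is not modelled and not corrected — in the imaging
  regime this package targets, essentially all cellular fluorescence is
  captured in the focal plane.
* The generator's selection rate (~85% of complete cycles) is higher than
  real mother-machine experiments achieve, because filamentation, lysis
  and focus-drift pathologies are not simulated.
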