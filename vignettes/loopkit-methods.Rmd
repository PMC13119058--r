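---
title: "Models and methods behind loopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loopkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopkit)
```

loopkit reimplements, as a tested and reusable package, the quantitative
machinery of a single-molecule study of the Rad51–Rad54 presynaptic
complex (PSC): a stochastic two-motor loop-extrusion model, magnetic
tweezer (MT) and optical-trap trace analyses, torque-plot stall
extrapolation, and in vivo D-loop capture (DLC) quantification from qPCR
crossing points. Because instrument data are not bundled, a seeded
synthetic-data module generates every input the pipeline consumes, with
ground truth attached, so the full analysis chain is testable end to end.

## The two-motor loop-formation-rate model

Rad54 translocates on duplex DNA as a dimer. Recruitment by the Rad51
filament activates one subunit, raising its velocity several-fold, and the
velocity asymmetry between the anchored and activated subunit extrudes a
DNA loop. The loop formation rate of one replicate is

$$\mathrm{LFR} = |v_1 - v_2|, \qquad
  v_1 \sim N(\mu, \sigma^2), \quad v_2 \sim N(A\mu, \sigma^2),$$

where $\mu$ is the mean unactivated velocity (default 65 bp/s, the
measured Rad54 translocation rate), $A \ge 1$ the activation fold, and
$\sigma$ the velocity spread. Negative velocity draws are unphysical and
are redrawn independently until non-negative (the count is reported), so
each simulation keeps exactly `n_samples` replicates (default 1000). The
redraw makes each velocity a zero-truncated normal; with the pair drawn
independently, this is equivalent to rejecting pairs containing a
negative value.

Two modelling choices deserve note:

* **$\sigma$ defaults to $\mu$.** The spread of single-motor velocities
  is not pinned down by bulk measurements; measured compaction-rate
  spreads (on the order of ±130 bp/s around ~200 bp/s) bracket
  $\sigma \approx \mu$. All quantitative tests state $\sigma$ explicitly,
  and the parameter is a plain argument.
* **Difference versus sum.** The loop could also grow at the combined
  rate of the two subunits. The difference form is the one with a fully
  stated sampling procedure, so it is the default; `mode = "sum"`
  exposes the other reading.

A consequence worth recording: with $\mu = \sigma = 65$ bp/s the expected
mean LFR at threefold activation is ≈119 bp/s (the zero-truncation lifts
$E[v_1]$ to ≈84 bp/s, and the folded-normal correction adds back part of
the overlap), and no admissible $\sigma$ pushes the difference-mode mean
above ≈130 bp/s at threefold. At fivefold the expectation is ≈241 bp/s.
`lfr_table()` runs a fold titration with one independently seeded
simulation per fold.

## Worm-like-chain mechanics

All force–extension work uses the extensible worm-like chain: the
Marko–Siggia interpolation with an enthalpic stretch term,

$$F = \frac{k_BT}{L_p}\left[\frac{1}{4(1-z)^2} - \frac14 + z\right],
  \qquad z = \frac{x}{L} - \frac{F}{K},$$

with $k_BT = 4.114$ pN·nm (25 °C). Defaults are a persistence length of
$L_p = 43.3$ nm, stretch modulus $K = 1205$ pN and helical rise
0.338 nm/bp — canonical values for λ-DNA in near-physiological buffer —
with a 48,502 bp contour (16.39 µm). Every parameter is configurable via
`wlc_params()`, and the downstream analyses depend on the defaults only
weakly: loop sizes are *differences* of effective contours, which cancels
most sensitivity to $L_p$ and $K$.

Both directions of the curve are solved by single-level monotone
root-finding on the closed-form residual (no nested inversion):
`wlc_force_to_extension()` solves for $z$ at fixed $F$;
`wlc_extension_to_force()` solves for $F$ at fixed $x$ with
$z = x/L - F/K$ substituted. The round trip is the identity to better
than $10^{-6}$ pN across (0, 60] pN, and extensions beyond the enthalpic
cap $L(1 + F_{\mathrm{cap}}/K)$ raise an error rather than extrapolate.

The empirical force→torque conversion for a plectonemic tether is the
power law $\tau = 12.7825\,F^{0.63447}$ pN·nm, and twist↔translocation
conversion uses 10.5 bp/turn (B-form DNA) with a coupling efficiency
$c \in (0, 1]$: `rate_bp_s = turn_rate × 10.5 / c`. The division is
deliberate: a motor that converts only a fraction of traveled helical
repeats into net turns must travel *more* base pairs per observed turn,
and the published rate chain (158 → 211 → 316 bp/s at $c$ = 1, 0.75, 0.5)
is reproduced only by division. Values are reported unrounded.

## Magnetic-tweezer trace analysis

The MT pipeline follows the standard smooth–baseline–threshold recipe:

* **Smoothing** (`smooth_trace()`): centered moving average, default 5 s
  window, truncated at the ends. Centering avoids a systematic shift of
  event onsets; the alignment is otherwise immaterial.
* **Baseline** (`baseline_stats()`): Gaussian fit to the extension
  histogram of the protein-free tether (Freedman–Diaconis bins,
  Levenberg–Marquardt); a residual-fraction check above 25% flags
  non-Gaussian baselines such as two-plateau traces. The baseline SD is
  taken from the *raw* trace — the threshold is meant in units of the
  tether's own fluctuation, not of the suppressed post-smoothing noise.
* **Event calling** (`detect_events()`): contiguous excursions of the
  smoothed trace above mean + 3 SD lasting more than 2.5 s. Per event,
  the peak amplitude is the smoothed maximum minus the baseline mean; the
  positive (negative) rate is the least-squares slope into (out of) the
  local maximum; the lifetime is the time above threshold. Events still
  above threshold at the trace end are kept but flagged right-censored.
  Thresholding the smoothed trace matches the stated smoothing-then-
  analysis order.
* **Lifetime fitting** (`fit_lifetimes()`): dwell times are fit as an
  exponential. The default estimator is the maximum-likelihood rate with
  the *exact* 95% CI from the gamma pivot of the mean (the sum of $n$
  exponential dwells is Gamma($n$, rate)); a least-squares fit of the
  empirical survival curve to $e^{-t\ln 2/t_{1/2}}$ is available because
  "fit to an exponential decay curve" is ambiguous between the two. On
  clean data they agree; the MLE has strictly better calibration, which
  the coverage test exercises (95% CI covers a programmed 20 s half-life
  in ≥ 90% of 100 cohorts of 300 dwells).
* **Hat curves** (`hat_slope()`): the buckling arm is summarized by the
  least-squares slope over a turn range (default −70 to −20). The model
  behind the generator is piecewise linear — plateau between the two
  buckling transitions, linear plectonemic arms, zero clamp — because
  only the arm slopes and apex are consumed downstream. A split-half
  slope comparison flags ranges that mix regimes (apex or melting arm).
* **Compaction screening** (`screen_compaction()`): traces are truncated
  at the first sample below the initial extension and flagged, even if
  they later recover.

## Optical-trap analyses

`compare_to_theory()` decomposes a measured re-extension curve into the
bare-DNA WLC plus compaction intermediates. Numerical choices:

* **Deviation threshold**: 0.5 pN of force excess sustained over 50 nm of
  extension (both configurable) — above the force noise of a stiff trap,
  below the smallest interesting sawtooth amplitudes.
* **bp conversion**: a point $(x, F)$ off theory implies an effective
  contour $L_{\mathrm{eff}} = x / \hat{x}_{\mathrm{rel}}(F)$, and the
  constrained DNA is the deficit
  $L - L_{\mathrm{eff}}$ in bp. The pre-rupture constraint is estimated
  from the upper force quartile of the pre-rupture segment (the deficit is
  best conditioned at high force), and loop sizes are contour *changes*
  across each drop, averaged over a few samples on either side.
* **Rupture detection**: the force channel is lightly pre-smoothed
  (7-sample running mean) and a running max/min tracker calls a rupture
  when the force falls ≥ 1 pN below the running maximum; apparent loops
  smaller than 250 bp are treated as noise. Rupture forces are reported
  from the raw channel at the detected peak so noiseless recovery is
  exact.
* **Final deviation** is measured where the curve last rejoins theory; a
  curve that never rejoins reports the residual deficit at the end of the
  pull, flagged as a lower bound.

`clamp_velocity()` converts the fitted extension slope of a constant-force
segment to bp/s via the helical rise and labels compaction versus
translocation by its sign. `max_force()` smooths the force channel,
segments excursions more than 1 pN above the pre-event baseline, and
reports per-event maxima; the 1 pN delimiter is a pragmatic rule where no
published rule exists.

The torque module assembles per-force mean rates (95% t-intervals) into a
torque plot, fits an unweighted ordinary least-squares line (a weighted
$1/\mathrm{CI}^2$ option exists), and reports *both* intercepts by name —
`rate_at_zero_torque` and `stall_torque_pn_nm` — because axis wording for
"X-intercept" is ambiguous in the field. Confidence bands come from the
OLS covariance. The linear extrapolation is a simplification of a
relationship that is not entirely linear, so the stall estimate may be
biased low; the fit warns accordingly. Force–velocity data can be fit
with a rectangular hyperbola $v = V_{\max}F/(K+F)$ or a single-phase
exponential decay $v = v_0e^{-F/\tau} + c$; constant input degenerates
the hyperbola ($K \to 0$) and is flagged rather than fitted.

## DLC quantification

qPCR template content follows the exponential amplification law
$\mathrm{content} = \mathrm{eff}^{-C_p}$; the DLC signal is the chimera
content divided by the intramolecular-ligation control content. With
equal channel efficiencies, the signal is invariant to a common shift of
both crossing points — a useful internal control that the tests exercise.
Strain summaries report the mean signal, SEM (≥ 3 replicates enforced)
and fold-change as reference mean over strain mean, computed on strain
means rather than per-replicate ratios to match strain-level reporting.
Amplification efficiencies are user inputs; standard-curve estimation is
out of scope.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its configuration plus an integer
seed (bit-identical reruns), and each pipeline stage derives a child seed
from the master seed and the stage name, so stage order cannot silently
change results.

* **MT traces**: baseline + white Gaussian noise with trapezoidal events
  (linear rise, exponential-dwell plateau, linear fall). The trapezoid
  follows the linear-slopes-between-extrema description of measured
  events. Defaults: 600 s at 50 Hz (a typical camera-based MT rate; all
  thresholds are expressed in seconds so results are rate-independent),
  1 µm mean amplitude over 0.1 µm noise, 20 s dwell half-life, and a
  0.5 µm/s rise rate chosen so the time above the 3 SD threshold tracks
  the plateau dwell to within one smoothing window.
* **FE curves**: the imposed-extension force is computed from the WLC of
  the effective contour; when it reaches the next programmed rupture
  force the exact crossing sample is emitted and the loop's base pairs
  are released, producing the sawtooth. Defaults mirror the published
  regime: ~15 kb initially constrained, four 2 kb loops, 0.25 pN force
  noise.
* **DLC tables**: ligation Cp drawn from 18–22 cycles, chimera Cp solved
  from the programmed signal, Gaussian cycle noise added to both.

Not emulated: Brownian bead dynamics, drift and creep, camera blur,
spectral (non-white) noise, multi-bead cross-talk, or kymograph imagery.
Passing the recovery suites therefore demonstrates that the estimators
are correct and well-calibrated *under the stated noise model*, not that
they are robust to every instrumental artifact of real traces.

## Problem sizes and determinism

The test suite runs at desk scale: 100-seed event-detection recovery
(600 s traces at 50 Hz), 100 cohorts of 300 dwells for CI coverage,
50-seed FE sawtooth recovery (1000-point curves), 50-seed stall-torque
recovery, and a 10^6-pair rejection-sampling oracle for the LFR
simulator — a few minutes in total on one CPU. These sizes were chosen as
the smallest at which the targeted tolerances are meaningfully tested.
All randomness flows through explicit integer seeds; `child_seed()`
implements a stable rolling-hash derivation.

## Known limitations

* The stall torque relies on a linear extrapolation well beyond the
  measured torque range.
* The difference-mode LFR model cannot reach some published read-off
  means at threefold activation for any $\sigma$ (see above); the
  package reports what the stated model produces.
* The hat-curve model is piecewise linear; it does not model the smooth
  apex or torque-melting transitions beyond a flat arm.
* No chromatin: all mechanics are for naked DNA.
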