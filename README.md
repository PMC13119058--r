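# loopkit

Quantitative toolkit for single-molecule studies of DNA loop extrusion by
the Rad51–Rad54 presynaptic complex (PSC) — the homology-search machine of
homologous recombination. The PSC compacts donor duplex DNA by extruding
loops, twists it while doing so, and stalls against torque; loopkit
provides the models and estimators needed to quantify that behaviour from
magnetic-tweezer (MT) traces, optical-trap force–extension curves, and
D-loop capture (DLC) qPCR tables, plus seeded synthetic-data generators so
the entire pipeline runs and is tested without any instrument data.

For whom: biophysicists analysing single-molecule motor/tether
experiments, and anyone who wants a reproducible reference implementation
of the analyses below.

## What is inside

* **Two-motor loop-formation-rate (LFR) simulator** — `sample_lfr()`,
  `lfr_table()`. One Rad54 subunit is activated `A`-fold by Rad51; loop
  growth is `LFR = |v1 − v2|` with `v1 ~ N(µ, σ²)`, `v2 ~ N(Aµ, σ²)`,
  negative draws redrawn.
* **DNA mechanics** — extensible worm-like chain (Marko–Siggia with
  stretch modulus): `wlc_params()`, `wlc_force_to_extension()`,
  `wlc_extension_to_force()`; the empirical plectoneme torque law
  `τ = 12.7825 F^0.63447` pN·nm (`force_to_torque()`); twist↔bp coupling
  at 10.5 bp/turn (`turns_rate_to_bp_rate()`); piecewise-linear hat-curve
  model (`hat_curve_model()`, `hat_extension()`).
* **MT trace pipeline** — `smooth_trace()`, `baseline_stats()`,
  `detect_events()` (3 SD / >2.5 s threshold calling),
  `fit_lifetimes()` (exponential MLE with exact CI), `hat_slope()`,
  `screen_compaction()`.
* **Optical-trap analyses** — `compare_to_theory()` (sawtooth
  decomposition into first/final deviation and per-loop sizes + rupture
  forces), `clamp_velocity()`, `max_force()`, `percent_extension()`.
* **Torque analysis** — `build_torque_plot()`, `fit_stall()` (linear
  stall-torque extrapolation with both intercepts and 95% bands),
  `convert_plot_units()`, `fit_force_velocity()` (rectangular hyperbola /
  single-phase exponential decay).
* **DLC quantification** — `dlc_content()` (`eff^(−Cp)`), `dlc_signal()`,
  `dlc_strain_summary()`.
* **Synthetic data** — `gen_mt_trace()`, `gen_hat_curve()`,
  `gen_fe_curve()`, `gen_dlc_table()`; all pure functions of config +
  seed, with ground truth attached.
* **Pipeline** — `run_pipeline()` executes
  generate → analyze → summarize from one master seed and writes TSV/JSON
  reports.

Everything is data-frame-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate the loop-formation-rate distribution at fivefold activation and
a fold titration:

```r
library(loopkit)

fit <- sample_lfr(mu = 65, sigma = 65, fold_activation = 5,
                  n_samples = 1000, seed = 7)
fit
#> <lfr_sim> difference mode: mu = 65, sigma = 65, A = 5, n = 1000 (seed 7)
#>   mean LFR 244.7 bp/s (sd 84.5), 173 negative draws redrawn

lfr_table(mu = 65, sigma = 65, folds = c(1, 2, 3, 5, 10), seed = 7)
#> # A tibble: 5 × 4
#>    fold mean_bp_s sd_bp_s n_discarded
#>   <dbl>     <dbl>   <dbl>       <int>
#> 1     1      57.4    43.2         389
#> 2     2      73.8    53.3         211
#> 3     3     113.     72.1         180
#> 4     5     237.     84.3         165
#> 5    10     566.     84.2         177
```

The mean LFR at fivefold stimulation is ~240 bp/s: the activated motor
outruns the anchored one by roughly `µ(A−1)`, broadened by the velocity
spread and lifted slightly by the non-negativity of each motor.

Decompose a synthetic sawtooth re-extension curve (15 kb initially
constrained, four 2 kb loops rupturing at 12–32 pN, 0.25 pN force noise)
against worm-like-chain theory:

```r
w <- wlc_params() # λ-DNA: 48,502 bp, Lp 43.3 nm, K 1205 pN
loops <- tibble::tibble(size_bp = rep(2000, 4),
                        rupture_force_pn = c(12, 18, 25, 32))
fe <- gen_fe_curve(w, loops, initial_constrained_bp = 15000, seed = 7)
dev <- compare_to_theory(fe$curve, w)
dev
#> <deviation_set> first deviation 15002 bp, final 7002 bp, 4 intermediate(s) [never rejoins theory]
tidy(dev)
#> # A tibble: 4 × 3
#>   loop_bp rupture_pn order
#>     <dbl>      <dbl> <int>
#> 1   2015.       12.0     1
#> 2   1998.       17.8     2
#> 3   2036.       25.1     3
#> 4   1988.       31.7     4
```

The analysis recovers the programmed 15 kb initial constraint, the four
~2 kb loops in rupture order with their rupture forces, and reports the
residual constrained DNA (15000 − 4×2000 = 7000 bp) as the final
deviation, flagged because the curve never fully rejoins theory.

Torque bookkeeping uses the plectoneme power law — at 0.3, 0.5, 1 and
2 pN the tether feels 5.95, 8.23, 12.78 and 19.84 pN·nm:

```r
force_to_torque(torque_model(), c(0.3, 0.5, 1, 2))
#> [1]  5.954769  8.234198 12.782500 19.843136
```

See `vignette("loopkit-methods")` for the models, parameter defaults and
numerical choices.

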