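# MT trace pipeline: smoothing, baseline, event calling, lifetimes,
# hat slopes, compaction screening.

test_that("sliding-window smoothing has the expected statistics", {
  flat <- tibble::tibble(time_s = seq(0, 100, by = 0.02),
                         extension_um = 2.5)
  expect_equal(smooth_trace(flat, 5)$extension_um, flat$extension_um)
  # white-noise SD shrinks by 1/sqrt(window * rate)
  set.seed(1)
  noisy <- tibble::tibble(time_s = seq(0, 600, by = 0.02),
                          extension_um = rnorm(30001, 0, 0.1))
  sm <- smooth_trace(noisy, 5)
  inner <- sm$extension_um[2000:28000] # full windows only
  expect_equal(sd(inner), 0.1 / sqrt(5 * 50), tolerance = 0.1)
  # single-sample impulse attenuates to h / (window * rate)
  imp <- flat
  imp$extension_um[2501] <- imp$extension_um[2501] + 1
  smi <- smooth_trace(imp, 5)
  expect_equal(max(smi$extension_um) - 2.5, 1 / (5 * 50), tolerance = 0.01)
  expect_error(smooth_trace(flat, 0), "positive")
  expect_error(smooth_trace(flat, 1000), "duration")
})

test_that("baseline statistics recover Gaussian parameters within 2%", {
  set.seed(42)
  tr <- tibble::tibble(time_s = seq(0, 200, by = 0.02),
                       extension_um = rnorm(10001, 4.0, 0.05))
  bl <- baseline_stats(tr)
  expect_equal(bl$mean, 4.0, tolerance = 0.02)
  expect_equal(bl$sd, 0.05, tolerance = 0.02)
  expect_false(bl$gof_warning)
  expect_error(baseline_stats(tibble::tibble(extension_um = rep(1, 200))),
               "zero variance")
  # bimodal baseline (two plateaus) trips the goodness-of-fit check
  bim <- tibble::tibble(extension_um = c(rnorm(5000, 3.5, 0.05),
                                         rnorm(5000, 4.5, 0.05)))
  expect_warning(blb <- baseline_stats(bim), "Gaussian")
  expect_true(blb$gof_warning)
})

test_that("a clean trapezoid event is called with correct properties", {
  tr <- make_trapezoid_trace(amp = 1.0, dwell = 20, noise_sd = 0.1, seed = 3)
  bl <- list(mean = 3.5, sd = 0.1)
  ev <- detect_events(tr, bl, event_config())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_amplitude_um, 1.0, tolerance = 0.05)
  # lifetime = time above mean + 3 SD: dwell plus the ramp above threshold
  expect_equal(ev$lifetime_s, 20, tolerance = 5 / 20)
  expect_gte(ev$positive_rate_um_s, 0)
  expect_false(ev$censored)
})

test_that("short excursions and sub-threshold events are rejected", {
  # 1.5 s above threshold: excluded by the > 2.5 s rule
  short <- make_trapezoid_trace(amp = 1.0, rise_rate = 4, dwell = 1.2,
                                noise_sd = 0.05, seed = 4)
  ev <- detect_events(short, list(mean = 3.5, sd = 0.1), event_config())
  expect_equal(nrow(ev), 0)
  # pure-noise trace yields no calls
  noise <- make_trapezoid_trace(amp = 0, dwell = 0, noise_sd = 0.1, seed = 5)
  ev2 <- detect_events(noise, list(mean = 3.5, sd = 0.1), event_config())
  expect_equal(nrow(ev2), 0)
  expect_error(detect_events(noise, list(mean = 3.5, sd = 0)), "positive")
})

test_that("event calls are invariant to a constant offset of the trace", {
  tr <- make_trapezoid_trace(amp = 1.0, dwell = 15, noise_sd = 0.1, seed = 6)
  ev <- detect_events(tr, list(mean = 3.5, sd = 0.1), event_config())
  shifted <- dplyr::mutate(tr, extension_um = extension_um + 2.2)
  ev2 <- detect_events(shifted, list(mean = 5.7, sd = 0.1), event_config())
  expect_equal(ev$start_s, ev2$start_s)
  expect_equal(ev$lifetime_s, ev2$lifetime_s)
  expect_equal(ev$peak_amplitude_um, ev2$peak_amplitude_um, tolerance = 1e-10)
})

test_that("exponential lifetime fit recovers and rescales correctly", {
  set.seed(77)
  dwells <- tibble::tibble(lifetime_s = rexp(300, rate = log(2) / 20))
  fit <- fit_lifetimes(dwells)
  expect_gt(fit$half_life, fit$ci95[1])
  expect_lt(fit$half_life, fit$ci95[2])
  expect_true(fit$ci95[1] < 20 && 20 < fit$ci95[2])
  # scale equivariance: doubling every dwell doubles the half-life
  fit2 <- fit_lifetimes(dplyr::mutate(dwells, lifetime_s = 2 * lifetime_s))
  expect_equal(fit2$half_life, 2 * fit$half_life, tolerance = 1e-12)
  # survival-curve least squares agrees with the MLE on clean data
  fit3 <- fit_lifetimes(dwells, method = "survival")
  expect_equal(fit3$half_life, fit$half_life, tolerance = 0.1)
  expect_error(fit_lifetimes(dwells[1:5, ]), ">= 10")
  expect_warning(
    fit_lifetimes(tibble::tibble(lifetime_s = rep(5, 20))), "degenerate")
})

test_that("hat slope is exact on a linear arm and flags mixed regimes", {
  h <- hat_curve_model()
  clean <- gen_hat_curve(h, noise_sd = 0, n_points = 141, seed = 1)
  hs <- hat_slope(clean, -70, -20)
  expect_equal(hs$slope, h$slope_neg, tolerance = 1e-10)
  expect_false(hs$mixed_regime)
  # a flat melted arm is distinguishable from a buckling arm
  flat_model <- hat_curve_model(slope_neg = 0, slope_pos = -0.045)
  flat <- gen_hat_curve(flat_model, noise_sd = 0.02, n_points = 141, seed = 2)
  expect_lt(abs(suppressWarnings(hat_slope(flat, -70, -20))$slope), 0.045 / 4)
  # range spanning the apex mixes plateau and arm
  expect_warning(mixed <- hat_slope(clean, -40, 10), "regime")
  expect_true(mixed$mixed_regime)
  expect_lt(abs(mixed$slope), abs(h$slope_neg))
  expect_error(hat_slope(clean, 100, 120), "fewer than 3")
})

test_that("compaction screening truncates at the first dip", {
  t <- seq(0, 300, by = 0.5)
  up <- tibble::tibble(time_s = t, extension_um = 3.5 + 0.001 * t)
  res <- screen_compaction(up)
  expect_false(res$censored)
  expect_equal(nrow(res$kept), length(t))
  # dips at t = 120 s and recovers: still truncated at the first dip
  dip <- tibble::tibble(
    time_s = t,
    extension_um = ifelse(t >= 120 & t < 150, 3.0, 3.6))
  dip$extension_um[1] <- 3.5
  res2 <- screen_compaction(dip)
  expect_true(res2$censored)
  expect_equal(max(res2$kept$time_s), 119.5)
})
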