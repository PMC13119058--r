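# Seeded generators: MT traces, hat curves, FE sawtooths, qPCR tables.

test_that("generators are pure functions of config and seed", {
  a <- gen_mt_trace(duration = 60, seed = 5)
  b <- gen_mt_trace(duration = 60, seed = 5)
  expect_identical(a, b)
  h1 <- gen_hat_curve(hat_curve_model(), seed = 3)
  h2 <- gen_hat_curve(hat_curve_model(), seed = 3)
  expect_identical(h1, h2)
  d1 <- gen_dlc_table(1e-2, seed = 2)
  d2 <- gen_dlc_table(1e-2, seed = 2)
  expect_identical(d1, d2)
})

test_that("MT trace ground truth is self-consistent", {
  g <- gen_mt_trace(duration = 300, event_count = 1,
                    event_amplitude_mean = 1.0, event_amplitude_sd = 0,
                    noise_sd = 0.1, seed = 8)
  expect_equal(nrow(g$truth$events), 1)
  expect_equal(g$truth$events$amplitude_um, 1.0)
  # the trace actually reaches baseline + amplitude at the plateau
  ev <- g$truth$events
  plateau <- g$trace$time_s > ev$start_s + 2.5 &
    g$trace$time_s < ev$start_s + 2 + ev$lifetime_s - 0.5
  if (any(plateau)) {
    expect_equal(mean(g$trace$extension_um[plateau]), 3.5 + 1.0,
                 tolerance = 0.05)
  }
  # event-free trace is pure baseline noise
  g0 <- gen_mt_trace(duration = 120, event_count = 0, seed = 9)
  expect_equal(mean(g0$trace$extension_um), 3.5, tolerance = 0.01)
  expect_equal(sd(g0$trace$extension_um), 0.1, tolerance = 0.05)
})

test_that("generated dwell times follow the configured exponential", {
  dwells <- numeric(0)
  s <- 0
  while (length(dwells) < 500) {
    s <- s + 1
    g <- gen_mt_trace(duration = 2000, sample_rate = 5, event_count = 12,
                      lifetime_half_life = 20, seed = s)
    dwells <- c(dwells, g$truth$events$lifetime_s)
  }
  ks <- suppressWarnings(
    stats::ks.test(dwells, "pexp", rate = log(2) / 20))
  expect_gt(ks$p.value, 0.01)
  expect_equal(median(dwells), 20, tolerance = 0.15)
})

test_that("hat-curve generator reduces to the model at zero noise", {
  h <- hat_curve_model()
  curve <- gen_hat_curve(h, noise_sd = 0, n_points = 141, seed = 1)
  expect_equal(curve$extension_um, hat_extension(h, curve$turns))
  # apex recovered within one grid step at moderate noise
  noisy <- gen_hat_curve(h, noise_sd = 0.02, n_points = 141, seed = 2)
  step <- diff(noisy$turns[1:2])
  apex_est <- noisy$turns[which.max(noisy$extension_um)]
  expect_lte(abs(apex_est - h$apex_turn),
             h$buckling_turn_pos - h$buckling_turn_neg)
  # arm slopes recovered within 5% at SNR ~20
  hs <- hat_slope(noisy, -70, -20)
  expect_equal(hs$slope, h$slope_neg, tolerance = 0.05)
})

test_that("FE generator with no loops matches WLC theory", {
  w <- wlc_params()
  fe <- gen_fe_curve(w, initial_constrained_bp = 0, noise_sd_force = 0.1,
                     n_points = 400, seed = 4)
  theory <- wlc_extension_to_force(w, fe$curve$extension_um, force_cap = 80)
  expect_lt(max(abs(fe$curve$force_pn - theory)), 5 * 0.1)
  dev <- compare_to_theory(fe$curve, w)
  expect_equal(dev$n_intermediates, 0L)
})

test_that("FE generator enforces its preconditions", {
  w <- wlc_params()
  expect_error(
    gen_fe_curve(w, tibble::tibble(size_bp = 2000, rupture_force_pn = 10),
                 initial_constrained_bp = 1000),
    "initial_constrained_bp")
  expect_error(
    gen_fe_curve(w, tibble::tibble(size_bp = 2000, rupture_force_pn = 60),
                 initial_constrained_bp = 5000, max_force = 45),
    "below max_force")
})

test_that("DLC generator encodes the programmed signal in the Cp values", {
  tab <- gen_dlc_table(3.3e-2, eff_dlc = 1.9, eff_lig = 1.85,
                       cp_noise_sd = 0, replicates = 3, seed = 6)
  expect_equal(nrow(tab), 3)
  sig <- dlc_signal(tab)
  expect_equal(sig$signal, rep(3.3e-2, 3), tolerance = 1e-12)
  # distinct noise per replicate when enabled
  noisy <- gen_dlc_table(3.3e-2, cp_noise_sd = 0.2, replicates = 3, seed = 6)
  expect_equal(length(unique(noisy$cp_dlc)), 3)
  expect_error(gen_dlc_table(0), "positive")
  expect_error(gen_dlc_table(1e-2, eff_dlc = 2.4), "1, 2")
})
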