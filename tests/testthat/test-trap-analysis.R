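# Optical-trap analyses: FE decomposition, clamp velocity, max force.

test_that("a theory-matching curve yields an empty deviation set", {
  w <- wlc_params()
  f <- seq(0.3, 40, length.out = 300)
  curve <- tibble::tibble(extension_um = wlc_force_to_extension(w, f),
                          force_pn = f)
  dev <- compare_to_theory(curve, w)
  expect_equal(dev$n_intermediates, 0L)
  expect_equal(dev$first_deviation_bp, 0)
  expect_equal(dev$final_deviation_bp, 0)
  expect_true(dev$rejoined)
  expect_error(
    compare_to_theory(dplyr::filter(curve, force_pn < 4), w), "5 pN")
})

test_that("noiseless single-loop rupture is recovered exactly", {
  w <- wlc_params()
  fe <- gen_fe_curve(w, tibble::tibble(size_bp = 3000, rupture_force_pn = 30),
                     initial_constrained_bp = 3000, noise_sd_force = 0,
                     seed = 1)
  dev <- compare_to_theory(fe$curve, w)
  expect_equal(dev$n_intermediates, 1L)
  expect_equal(dev$intermediates$rupture_pn, 30)
  expect_equal(dev$intermediates$loop_bp, 3000, tolerance = 0.01)
  expect_true(dev$rejoined)
  expect_equal(dev$final_deviation_bp, 0, tolerance = 0.02 * 3000)
})

test_that("sawtooth decomposition recovers programmed loops and mass balance", {
  w <- wlc_params()
  loops <- tibble::tibble(size_bp = c(2000, 2000, 2000, 2000),
                          rupture_force_pn = c(12, 18, 25, 32))
  for (s in 1:5) {
    fe <- gen_fe_curve(w, loops, initial_constrained_bp = 15000,
                       noise_sd_force = 0.25, seed = s)
    dev <- suppressWarnings(compare_to_theory(fe$curve, w))
    expect_equal(dev$n_intermediates, 4L)
    expect_equal(mean(dev$intermediates$loop_bp), 2000, tolerance = 0.1)
    expect_equal(dev$first_deviation_bp, 15000, tolerance = 0.1)
    # rupture forces in increasing-extension order match generator order
    expect_equal(dev$intermediates$order, 1:4)
    expect_equal(dev$intermediates$rupture_pn, c(12, 18, 25, 32),
                 tolerance = 0.1)
    # mass balance: released loops + residual = initial constraint
    expect_equal(sum(dev$intermediates$loop_bp) + dev$final_deviation_bp,
                 dev$first_deviation_bp, tolerance = 0.15)
  }
})

test_that("clamp velocity converts slope to bp/s and labels the mode", {
  w <- wlc_params()
  t <- seq(0, 60, by = 0.02)
  compaction <- tibble::tibble(
    time_s = t, extension_um = 5 - 202 * w$rise_per_bp / 1000 * t)
  res <- clamp_velocity(compaction, w)
  expect_equal(res$velocity_bp_s, 202, tolerance = 0.05)
  expect_equal(res$mode, "compaction")
  # flat trace: zero velocity
  flat <- tibble::tibble(time_s = t, extension_um = 5)
  expect_equal(clamp_velocity(flat, w)$velocity_bp_s, 0)
  # sign flip changes the mode label, not the magnitude
  rev <- dplyr::mutate(compaction, extension_um = 10 - extension_um)
  res2 <- clamp_velocity(rev, w)
  expect_equal(res2$mode, "translocation")
  expect_equal(res2$velocity_bp_s, res$velocity_bp_s)
  expect_error(clamp_velocity(compaction[1:10, ], w), "too short")
})

test_that("max force reports per-event maxima after smoothing", {
  t <- seq(0, 100, by = 0.02)
  const <- tibble::tibble(time_s = t, force_pn = 5)
  res <- max_force(const)
  expect_equal(nrow(res), 1)
  expect_equal(res$max_force_pn, 5)
  # a noisy ramp to 40 pN
  set.seed(8)
  ramp <- tibble::tibble(
    time_s = t,
    force_pn = 2 + approx(c(20, 50, 60, 80), c(0, 38, 38, 0), t,
                          yleft = 0, yright = 0)$y + rnorm(length(t), 0, 0.3))
  expect_equal(max_force(ramp)$max_force_pn, 40, tolerance = 0.05)
  # two excursions give two per-event maxima
  two <- tibble::tibble(
    time_s = t,
    force_pn = 5 + approx(c(10, 20, 25, 35), c(0, 15, 15, 0), t,
                          yleft = 0, yright = 0)$y +
      approx(c(60, 70, 75, 85), c(0, 30, 30, 0), t,
             yleft = 0, yright = 0)$y)
  res2 <- max_force(two)
  expect_equal(nrow(res2), 2)
  expect_equal(res2$max_force_pn, c(20, 35), tolerance = 0.02)
  expect_error(max_force(tibble::tibble(time_s = numeric(),
                                        force_pn = numeric())), "empty")
})
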