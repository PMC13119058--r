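# Polymer-mechanics primitives: contour conversions, extensible WLC,
# torque power law, coupling conversion, hat-curve model.

test_that("contour length converts bp to micrometres", {
  expect_equal(round(contour_length_um(48502), 1), 16.4)
  expect_equal(contour_length_um(0), 0)
  expect_equal(contour_length_um(12667), 12667 * 0.338 / 1000)
  expect_error(contour_length_um(-1), "non-negative")
  expect_error(contour_length_um(100, rise_per_bp = 0), "positive")
})

test_that("MT template length sums center and adapters", {
  expect_equal(template_total_bp(12667, 500), 13667)
  expect_error(template_total_bp(-1, 500), "non-negative")
})

test_that("WLC extension matches an independent bisection oracle", {
  w <- wlc_params()
  # independent oracle: bisection on the Marko-Siggia + stretch formula
  kbt <- 4.114
  ms_force <- function(z) {
    (kbt / w$persistence_length) * (1 / (4 * (1 - z)^2) - 0.25 + z)
  }
  bisect_ext <- function(force, tol = 1e-9) {
    lo <- 0; hi <- 1 - 1e-12
    while ((hi - lo) / max(hi, 1) > tol) {
      mid <- (lo + hi) / 2
      if (ms_force(mid) < force) lo <- mid else hi <- mid
    }
    w$contour_length_um * ((lo + hi) / 2 + force / w$stretch_modulus)
  }
  for (f in c(0.1, 1, 5, 30)) {
    expect_equal(wlc_force_to_extension(w, f), bisect_ext(f), tolerance = 1e-7)
  }
  expect_equal(wlc_force_to_extension(w, 0), 0)
  # enthalpic regime: extension exceeds the contour length
  expect_gt(wlc_force_to_extension(w, 10 * w$stretch_modulus) /
              w$contour_length_um, 1)
  expect_error(wlc_force_to_extension(w, -1), "non-negative")
})

test_that("WLC force-extension is strictly monotone and inverts exactly", {
  w <- wlc_params()
  forces <- seq(0.006, 60, length.out = 1e4)
  ext <- wlc_force_to_extension(w, forces)
  expect_true(all(diff(ext) > 0))
  back <- wlc_extension_to_force(w, ext[seq(1, 1e4, by = 97)])
  expect_lt(max(abs(back - forces[seq(1, 1e4, by = 97)])), 1e-6)
  expect_equal(wlc_extension_to_force(w, 0), 0)
  cap <- w$contour_length_um * (1 + 100 / w$stretch_modulus)
  expect_error(wlc_extension_to_force(w, 1.1 * cap), "enthalpic cap")
})

test_that("force-to-torque power law evaluates and scales correctly", {
  m <- torque_model()
  expect_identical(force_to_torque(m, 1), m$coefficient)
  expect_equal(force_to_torque(m, 0), 0)
  expect_equal(force_to_torque(m, 2), 12.7825 * 2^0.63447, tolerance = 1e-12)
  # log-log slope equals the exponent
  f <- c(0.5, 5)
  slope <- diff(log(force_to_torque(m, f))) / diff(log(f))
  expect_equal(slope, m$exponent, tolerance = 1e-9)
  expect_error(force_to_torque(m, -0.1), "non-negative")
  expect_error(torque_model(exponent = 1.5), "0, 1")
})

test_that("coupling conversion divides by the efficiency", {
  expect_identical(turns_rate_to_bp_rate(15.05, coupling_model()), 15.05 * 10.5)
  expect_equal(round(turns_rate_to_bp_rate(
    15.05, coupling_model(coupling_efficiency = 0.75))), 211)
  expect_equal(turns_rate_to_bp_rate(
    15.05, coupling_model(coupling_efficiency = 0.5)), 316.05)
  expect_error(coupling_model(coupling_efficiency = 0), "0, 1")
  expect_error(turns_rate_to_bp_rate(-1), "non-negative")
})

test_that("hat-curve model has a plateau apex, linear arms and a zero clamp", {
  h <- hat_curve_model(apex_turn = 0, apex_extension = 3.5,
                       buckling_turn_neg = -15, buckling_turn_pos = 15,
                       slope_neg = 0.045, slope_pos = -0.045)
  expect_equal(hat_extension(h, 0), 3.5)
  expect_equal(hat_extension(h, 1000), 0) # clamped far past buckling
  # symmetric model: equal extension at +/- k beyond both buckling turns
  k <- c(20, 40, 70)
  expect_equal(hat_extension(h, k), hat_extension(h, -k))
  # maximum attained at the apex on any grid containing it
  grid <- seq(-80, 80, by = 0.5)
  expect_equal(max(hat_extension(h, grid)), hat_extension(h, h$apex_turn))
  expect_true(all(diff(hat_extension(h, seq(0, 80, 1))) <= 0))
  expect_error(hat_curve_model(buckling_turn_neg = 5, buckling_turn_pos = 3),
               "bracket")
})

test_that("loading extensions convert to integer percentages", {
  expect_equal(percent_extension(c(8, 10), 16.4), c(49, 61))
  expect_equal(percent_extension(16.4, 16.4), 100)
  expect_error(percent_extension(8, 0), "positive")
})
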