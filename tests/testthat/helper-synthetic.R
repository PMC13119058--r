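# Shared fixtures built in code.

# A deterministic trapezoidal extension event on a flat baseline with
# optional white noise: linear rise at `rate` to `amp`, plateau of
# `dwell` seconds, linear fall.
make_trapezoid_trace <- function(duration = 300, rate_hz = 50,
                                 baseline = 3.5, amp = 1.0, rise_rate = 0.5,
                                 dwell = 20, start = 100, noise_sd = 0,
                                 seed = 1) {
  set.seed(seed)
  time_s <- seq(0, duration, by = 1 / rate_hz)
  if (amp > 0) {
    rise_t <- amp / rise_rate
    knots_x <- c(start, start + rise_t, start + rise_t + dwell,
                 start + 2 * rise_t + dwell)
    shape <- approx(knots_x, c(0, amp, amp, 0), xout = time_s,
                    yleft = 0, yright = 0)$y
  } else {
    shape <- 0
  }
  tibble::tibble(
    time_s = time_s,
    extension_um = baseline + shape + rnorm(length(time_s), 0, noise_sd))
}

# Match detected events to ground-truth events by time overlap; returns
# the truth table with matched call columns (NA when missed).
match_events <- function(calls, truth_events, rise_rate = 0.5) {
  purrr::pmap_dfr(truth_events, function(start_s, amplitude_um,
                                         rise_rate_um_s, lifetime_s, ...) {
    t_end <- start_s + 2 * amplitude_um / rise_rate_um_s + lifetime_s
    hit <- calls[calls$end_s > start_s & calls$start_s < t_end, ]
    tibble::tibble(
      start_s = start_s, amplitude_um = amplitude_um,
      lifetime_s = lifetime_s,
      called = nrow(hit) > 0,
      call_amplitude_um = if (nrow(hit) > 0) hit$peak_amplitude_um[1] else NA_real_,
      call_lifetime_s = if (nrow(hit) > 0) hit$lifetime_s[1] else NA_real_)
  })
}
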