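# Seeded synthetic-data generators for every input the pipeline consumes:
# magnetic-tweezer bead-height traces with ground-truth extension events,
# rotation-extension (hat) curves, sawtooth force-extension curves with
# programmed loop ruptures, and qPCR Cp tables with multiplicative
# amplification-efficiency structure. Each generator is a pure function of
# its arguments plus seed.

#' Generate a magnetic-tweezer extension trace with ground-truth events
#'
#' The trace is a constant baseline with white Gaussian noise plus
#' trapezoidal extension events: a linear rise at `event_rise_rate` to an
#' amplitude drawn from `N(event_amplitude_mean, event_amplitude_sd^2)`
#' (floored at zero), a plateau with exponentially distributed dwell
#' (`rate = ln 2 / lifetime_half_life`), and a linear return. Event starts
#' are placed uniformly; overlapping placements are dropped and counted in
#' the ground truth (`n_merged`).
#'
#' @param duration Trace duration, s (default 600, a 10 min monitor).
#' @param sample_rate Sampling rate, Hz (default 50).
#' @param baseline_extension Baseline bead extension, um.
#' @param noise_sd Baseline Gaussian noise SD, um.
#' @param event_count Number of events requested.
#' @param event_amplitude_mean,event_amplitude_sd Event amplitude
#'   distribution, um.
#' @param event_rise_rate Rise/fall slope magnitude, um/s.
#' @param lifetime_half_life Plateau dwell half-life, s.
#' @param seed Integer seed.
#' @return A list with `trace` (tibble `time_s`, `extension_um`) and
#'   `truth` (list with `events` tibble of `start_s`, `amplitude_um`,
#'   `rise_rate_um_s`, `lifetime_s`, and `n_merged`).
#' @export
gen_mt_trace <- function(duration = 600, sample_rate = 50,
                         baseline_extension = 3.5, noise_sd = 0.1,
                         event_count = 3, event_amplitude_mean = 1.0,
                         event_amplitude_sd = 0.2, event_rise_rate = 0.5,
                         lifetime_half_life = 20, seed = 1L) {
  if (duration <= 0 || sample_rate <= 0 || noise_sd <= 0) {
    abort("duration, sample_rate and noise_sd must be positive")
  }
  if (duration * sample_rate > 1e8) abort("requested trace exceeds 1e8 samples")
  if (event_count < 0 || event_amplitude_mean < 0 || event_amplitude_sd < 0 ||
      event_rise_rate < 0 || lifetime_half_life < 0) {
    abort("event parameters must be non-negative")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- floor(duration * sample_rate)
  time_s <- (seq_len(n) - 1) / sample_rate
  ext <- rep(baseline_extension, n)

  events <- tibble::tibble(start_s = numeric(), amplitude_um = numeric(),
                           rise_rate_um_s = numeric(), lifetime_s = numeric())
  n_merged <- 0L
  if (event_count > 0) {
    amp <- pmax(rnorm(event_count, event_amplitude_mean, event_amplitude_sd), 0)
    dwell <- rexp(event_count, rate = log(2) / lifetime_half_life)
    total_len <- 2 * amp / max(event_rise_rate, 1e-12) + dwell
    margin <- 2 * 5 # keep events clear of trace ends and of each other
    start <- runif(event_count, margin, pmax(duration - total_len - margin,
                                             margin))
    keep <- logical(event_count)
    last_end <- -Inf
    ord <- order(start)
    for (i in ord) {
      if (start[i] > last_end + margin) {
        keep[i] <- TRUE
        last_end <- start[i] + total_len[i]
      } else n_merged <- n_merged + 1L
    }
    for (i in which(keep)) {
      rise_t <- amp[i] / max(event_rise_rate, 1e-12)
      t0 <- start[i]; t1 <- t0 + rise_t; t2 <- t1 + dwell[i]; t3 <- t2 + rise_t
      shape <- approx(x = c(t0, t1, t2, t3), y = c(0, amp[i], amp[i], 0),
                      xout = time_s, yleft = 0, yright = 0)$y
      ext <- ext + shape
    }
    events <- dplyr::arrange(tibble::tibble(
      start_s = start[keep], amplitude_um = amp[keep],
      rise_rate_um_s = event_rise_rate, lifetime_s = dwell[keep]),
      .data$start_s)
  }
  ext <- ext + rnorm(n, 0, noise_sd)

  list(trace = tibble::tibble(time_s = time_s, extension_um = ext),
       truth = list(events = events, n_merged = n_merged))
}

#' Generate a noisy rotation-extension (hat) curve
#'
#' Evaluates [hat_extension()] on an even turn grid and adds white Gaussian
#' noise.
#'
#' @param model A [hat_curve_model()].
#' @param noise_sd Extension noise SD, um.
#' @param n_points Number of turn grid points (>= 5).
#' @param turn_range Length-2 numeric, grid limits in turns.
#' @param seed Integer seed.
#' @return A tibble with `turns`, `extension_um`.
#' @export
gen_hat_curve <- function(model, noise_sd = 0.02, n_points = 141,
                          turn_range = c(-70, 70), seed = 1L) {
  stopifnot(inherits(model, "hat_curve_model"))
  if (n_points < 5) abort("n_points must be >= 5")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  turns <- seq(turn_range[1], turn_range[2], length.out = n_points)
  tibble::tibble(
    turns = turns,
    extension_um = hat_extension(model, turns) + rnorm(n_points, 0, noise_sd)
  )
}

#' Generate a sawtooth force-extension curve with programmed loop ruptures
#'
#' Emulates re-extension of protein-compacted DNA: the tether initially
#' sequesters `initial_constrained_bp` of its contour, so the measured
#' force at each imposed extension follows the worm-like chain of the
#' reduced effective contour and exceeds the bare-DNA theory. Each time the
#' force reaches the next programmed rupture force, that loop's base pairs
#' are released into the effective contour and the force relaxes back
#' toward theory, producing a sawtooth. Residual constrained DNA
#' (`initial_constrained_bp - sum(loops$size_bp)`) never releases.
#'
#' @param wlc A [wlc_params()] describing the full tether.
#' @param loops A data frame with columns `size_bp` and `rupture_force_pn`
#'   (may have zero rows). Ruptures occur in order of increasing rupture
#'   force.
#' @param initial_constrained_bp Initially sequestered DNA, bp; must be at
#'   least `sum(loops$size_bp)`.
#' @param noise_sd_force Gaussian force noise SD, pN.
#' @param max_force Force at which the pull stops, pN (default 45).
#' @param n_points Number of extension grid points (default 1500).
#' @param seed Integer seed.
#' @return A list with `curve` (tibble `extension_um`, `force_pn`) and
#'   `truth` (tibble of loops in rupture order).
#' @export
gen_fe_curve <- function(wlc, loops = tibble::tibble(size_bp = numeric(),
                                                     rupture_force_pn = numeric()),
                         initial_constrained_bp = 0, noise_sd_force = 0.25,
                         max_force = 45, n_points = 1500, seed = 1L) {
  stopifnot(inherits(wlc, "wlc_params"))
  loops <- tibble::as_tibble(loops)
  .check_cols(loops, c("size_bp", "rupture_force_pn"), "loops table")
  if (initial_constrained_bp < sum(loops$size_bp)) {
    abort("initial_constrained_bp must be >= total loop size")
  }
  if (nrow(loops) > 0 && any(loops$rupture_force_pn >= max_force)) {
    abort("all rupture forces must lie below max_force")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  loops <- dplyr::arrange(loops, .data$rupture_force_pn)
  full_bp <- wlc$contour_length_bp
  eff_wlc <- function(constrained_bp) {
    wlc_params(contour_length_bp = full_bp - constrained_bp,
               rise_per_bp = wlc$rise_per_bp,
               persistence_length = wlc$persistence_length,
               stretch_modulus = wlc$stretch_modulus)
  }

  constrained <- initial_constrained_bp
  next_loop <- 1L
  final_constrained <- initial_constrained_bp - sum(loops$size_bp)
  x_max <- wlc_force_to_extension(eff_wlc(final_constrained), max_force)
  x_grid <- seq(0.2, x_max, length.out = n_points)
  cur <- eff_wlc(constrained)
  xs <- numeric(0)
  fs <- numeric(0)
  for (i in seq_len(n_points)) {
    f <- wlc_extension_to_force(cur, x_grid[i], force_cap = max_force * 1.5)
    while (next_loop <= nrow(loops) &&
           f >= loops$rupture_force_pn[next_loop]) {
      # record the exact crossing point before the loop releases
      f_rupt <- loops$rupture_force_pn[next_loop]
      xs <- c(xs, wlc_force_to_extension(cur, f_rupt))
      fs <- c(fs, f_rupt)
      constrained <- constrained - loops$size_bp[next_loop]
      next_loop <- next_loop + 1L
      cur <- eff_wlc(constrained)
      f <- wlc_extension_to_force(cur, x_grid[i], force_cap = max_force * 1.5)
    }
    xs <- c(xs, x_grid[i])
    fs <- c(fs, f)
  }
  fs <- fs + rnorm(length(fs), 0, noise_sd_force)

  list(curve = tibble::tibble(extension_um = xs, force_pn = fs),
       truth = dplyr::mutate(loops, order = dplyr::row_number()))
}

#' Generate a synthetic DLC qPCR crossing-point table
#'
#' Chooses ligation crossing points from a reference range, then sets the
#' chimera crossing point so that
#' `eff_dlc^(-cp_dlc) / eff_lig^(-cp_lig) = true_signal`, and finally adds
#' Gaussian cycle noise to both channels.
#'
#' @param true_signal Programmed DLC signal (chimera/ligation content
#'   ratio), positive.
#' @param eff_dlc,eff_lig Amplification efficiencies, fold/cycle in (1, 2].
#' @param cp_noise_sd Gaussian Cp noise SD, cycles.
#' @param replicates Number of replicate rows.
#' @param cp_lig_range Range from which ligation Cp values are drawn.
#' @param seed Integer seed.
#' @return A tibble with `replicate`, `eff_dlc`, `cp_dlc`, `eff_lig`,
#'   `cp_lig`.
#' @export
gen_dlc_table <- function(true_signal, eff_dlc = 1.9, eff_lig = 1.9,
                          cp_noise_sd = 0.1, replicates = 3L,
                          cp_lig_range = c(18, 22), seed = 1L) {
  if (true_signal <= 0) abort("true_signal must be positive")
  if (eff_dlc <= 1 || eff_dlc > 2 || eff_lig <= 1 || eff_lig > 2) {
    abort("amplification efficiencies must lie in (1, 2]")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  cp_lig <- runif(replicates, cp_lig_range[1], cp_lig_range[2])
  # eff_dlc^(-cp_dlc) = true_signal * eff_lig^(-cp_lig)
  cp_dlc <- -(log(true_signal) - cp_lig * log(eff_lig)) / log(eff_dlc)
  tibble::tibble(
    replicate = seq_len(replicates),
    eff_dlc = eff_dlc,
    cp_dlc = cp_dlc + rnorm(replicates, 0, cp_noise_sd),
    eff_lig = eff_lig,
    cp_lig = cp_lig + rnorm(replicates, 0, cp_noise_sd)
  )
}
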