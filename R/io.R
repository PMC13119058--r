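# File I/O, configuration and the end-to-end demo pipeline.
#
# All delimited files are tab-separated, UTF-8, "." decimal, header row
# mandatory, so results round-trip across locales. Every random stage of
# the pipeline consumes a child seed derived deterministically from the
# master seed and the stage name, so reordering stages cannot silently
# change results.

#' Derive a deterministic child seed from a master seed and a stage name
#'
#' A stable string hash (polynomial rolling hash mod 2^31 - 1) combined with
#' the master seed. Identical (seed, name) pairs always yield the same child
#' seed; distinct stage names decouple the random streams of pipeline
#' stages.
#'
#' @param seed Master integer seed.
#' @param name Stage name (character scalar).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, name) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1) + 1)
}

.check_cols <- function(df, required, what, path = NULL) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s%s is missing required column(s): %s",
                  what, if (is.null(path)) "" else paste0(" '", path, "'"),
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read a time-extension trace from a tab-separated file
#'
#' Expects columns `time_s` and `extension_um`, with optional `turns`,
#' `force_pn`, `condition` and `bead_id` in any order. Time must be
#' strictly increasing.
#'
#' @param path Path to a TSV file.
#' @return A trace tibble.
#' @export
read_trace <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_cols(df, c("time_s", "extension_um"), "trace file", path)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("trace file '%s': time_s not strictly increasing at data row %d",
                  path, bad[1] + 1L))
  }
  if (any(!is.finite(df$extension_um))) {
    abort(sprintf("trace file '%s': non-finite extension values", path))
  }
  tibble::as_tibble(df)
}

#' Read a force-extension curve from a tab-separated file
#'
#' Expects columns `extension_um` and `force_pn`.
#'
#' @param path Path to a TSV file.
#' @return An FE-curve tibble ordered by extension.
#' @export
read_fe_curve <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_cols(df, c("extension_um", "force_pn"), "FE-curve file", path)
  dplyr::arrange(tibble::as_tibble(df), .data$extension_um)
}

#' Read a DLC qPCR table from a comma-separated file
#'
#' Expects columns `strain`, `replicate`, `eff_dlc`, `cp_dlc`, `eff_lig`,
#' `cp_lig`; `timepoint_h` is optional.
#'
#' @param path Path to a CSV file.
#' @return A tibble of qPCR measurements.
#' @export
read_dlc_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_cols(df, c("strain", "replicate", "eff_dlc", "cp_dlc",
                    "eff_lig", "cp_lig"), "DLC table", path)
  tibble::as_tibble(df)
}

#' Write a tibble as a tab-separated file
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the full configuration of the demo pipeline as a nested list:
#' WLC, torque and coupling parameter blocks, event-detection settings, the
#' motor-model block and generator settings. Any subset can be overridden
#' by the corresponding entries of `overrides`; values are validated by the
#' constructors of each module on use.
#'
#' @param overrides Named list of blocks to override (merged shallowly per
#'   block).
#' @return A configuration list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    wlc = list(contour_bp = 48502L, rise_nm = 0.338, lp_nm = 43.3,
               k_pn = 1205),
    torque = list(coefficient = 12.7825, exponent = 0.63447),
    coupling = list(bp_per_turn = 10.5, efficiency = 1.0),
    events = list(window_s = 5, sd_multiplier = 3, min_duration_s = 2.5),
    motor = list(mu = 65, sigma = 65, folds = c(1, 2, 3, 5, 10), n = 1000L),
    trace = list(duration_s = 600, sample_rate_hz = 50,
                 baseline_um = 3.5, noise_sd_um = 0.1,
                 n_events = 3, amplitude_um = 1.0, amplitude_sd_um = 0,
                 rise_rate_um_s = 0.5, half_life_s = 20),
    fe = list(loops_bp = c(2000, 2000, 2000, 2000),
              rupture_pn = c(12, 18, 25, 32),
              initial_constrained_bp = 15000, noise_sd_pn = 0.25),
    dlc = list(strains = c(WT = 3.3e-2, rad54d = 1.7e-4),
               eff_dlc = 1.9, eff_lig = 1.9, cp_noise_sd = 0,
               replicates = 3L, reference = "WT")
  )
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys override blocks of
#'   [default_config()].
#' @return A configuration list.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' Run the full demo pipeline: generate, analyze, summarize
#'
#' Executes every stage of the package on synthetic data derived from one
#' master seed: the loop-formation-rate titration, magnetic-tweezer trace
#' generation and event calling with lifetime fitting, hat-curve slope
#' recovery, force-extension sawtooth decomposition, torque-plot
#' construction with stall extrapolation, and DLC qPCR quantification.
#' Each stage draws its own child seed, so stage order does not affect
#' results. If `output_dir` is given, per-stage TSV tables and a JSON
#' report of all fitted quantities are written there.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param seed Master integer seed.
#' @param output_dir Optional output directory (created if absent).
#' @return The report as a nested list (invisibly returns the same object
#'   that is serialized to JSON).
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         output_dir = NULL) {
  report <- list(seed = as.integer(seed))

  # Loop-formation-rate titration
  lfr <- lfr_table(mu = config$motor$mu, sigma = config$motor$sigma,
                   folds = config$motor$folds, n = config$motor$n,
                   seed = child_seed(seed, "lfr"))
  report$lfr <- lfr

  # MT trace: generate, baseline from a protein-free trace, detect, fit
  tcfg <- config$trace
  gen <- gen_mt_trace(
    duration = tcfg$duration_s, sample_rate = tcfg$sample_rate_hz,
    baseline_extension = tcfg$baseline_um, noise_sd = tcfg$noise_sd_um,
    event_count = tcfg$n_events, event_amplitude_mean = tcfg$amplitude_um,
    event_amplitude_sd = tcfg$amplitude_sd_um,
    event_rise_rate = tcfg$rise_rate_um_s,
    lifetime_half_life = tcfg$half_life_s,
    seed = child_seed(seed, "mt-trace"))
  naked <- gen_mt_trace(
    duration = tcfg$duration_s, sample_rate = tcfg$sample_rate_hz,
    baseline_extension = tcfg$baseline_um, noise_sd = tcfg$noise_sd_um,
    event_count = 0, seed = child_seed(seed, "mt-baseline"))
  ecfg <- event_config(window = config$events$window_s,
                       sd_multiplier = config$events$sd_multiplier,
                       min_duration = config$events$min_duration_s)
  bl <- baseline_stats(naked$trace)
  events <- detect_events(gen$trace, bl, ecfg)
  report$mt <- list(
    n_events_true = nrow(gen$truth$events),
    n_events_called = nrow(events),
    events = events
  )

  # Hat curve slope recovery
  hat_model <- hat_curve_model(apex_extension = tcfg$baseline_um,
                               buckling_turn_neg = -15, buckling_turn_pos = 15,
                               slope_neg = 0.045, slope_pos = -0.045)
  hat <- gen_hat_curve(hat_model, noise_sd = 0.02, n_points = 141,
                       turn_range = c(-70, 70),
                       seed = child_seed(seed, "hat"))
  hs <- hat_slope(hat, turn_lo = -70, turn_hi = -20)
  report$hat <- list(slope_um_turn = hs$slope, flagged_mixed = hs$mixed_regime)

  # Force-extension sawtooth
  wlc <- wlc_params(contour_length_bp = config$wlc$contour_bp,
                    rise_per_bp = config$wlc$rise_nm,
                    persistence_length = config$wlc$lp_nm,
                    stretch_modulus = config$wlc$k_pn)
  fe <- gen_fe_curve(wlc,
                     loops = tibble::tibble(size_bp = config$fe$loops_bp,
                                            rupture_force_pn = config$fe$rupture_pn),
                     initial_constrained_bp = config$fe$initial_constrained_bp,
                     noise_sd_force = config$fe$noise_sd_pn,
                     seed = child_seed(seed, "fe"))
  dev <- compare_to_theory(fe$curve, wlc)
  report$fe <- list(first_deviation_bp = dev$first_deviation_bp,
                    final_deviation_bp = dev$final_deviation_bp,
                    n_intermediates = dev$n_intermediates,
                    intermediates = dev$intermediates)

  # Torque plot and stall extrapolation from the simulated rate law
  tq <- torque_model(config$torque$coefficient, config$torque$exponent)
  forces <- c(0.3, 0.5, 1.0, 2.0)
  rate_seed <- child_seed(seed, "torque-rates")
  old <- .Random.seed_save(); set.seed(rate_seed)
  rates <- purrr::map_dfr(forces, function(f) {
    true_rate <- max(0.3 - 0.015 * force_to_torque(tq, f), 0.01)
    tibble::tibble(force_pn = f, rate = rnorm(25, true_rate, 0.03))
  })
  .Random.seed_restore(old)
  tp <- build_torque_plot(rates, tq)
  stall <- fit_stall(tp)
  report$torque <- c(glance(stall), list())

  # DLC quantification
  dcfg <- config$dlc
  dlc_tbl <- purrr::imap_dfr(as.list(dcfg$strains), function(sig, strain) {
    dplyr::mutate(
      gen_dlc_table(true_signal = sig, eff_dlc = dcfg$eff_dlc,
                    eff_lig = dcfg$eff_lig, cp_noise_sd = dcfg$cp_noise_sd,
                    replicates = dcfg$replicates,
                    seed = child_seed(seed, paste0("dlc-", strain))),
      strain = strain, .before = 1)
  })
  sig <- dlc_signal(dlc_tbl)
  summ <- dlc_strain_summary(sig, reference = dcfg$reference)
  report$dlc <- summ

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(lfr, file.path(output_dir, "lfr_table.tsv"))
    write_tsv_table(events, file.path(output_dir, "mt_events.tsv"))
    write_tsv_table(dev$intermediates, file.path(output_dir, "fe_loops.tsv"))
    write_tsv_table(summ, file.path(output_dir, "dlc_summary.tsv"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
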