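# Magnetic-tweezer trace pipeline: sliding-window smoothing, baseline
# statistics by Gaussian fit, threshold event calling (3 SD above baseline,
# > 2.5 s), per-event extension rates and lifetimes, exponential lifetime
# fitting, hat-curve buckling-arm slopes, and compaction screening.

#' Event-detection settings
#'
#' @param window Smoothing window, s (default 5).
#' @param sd_multiplier Threshold in baseline SD units (default 3).
#' @param min_duration Minimum time above threshold for a call, s
#'   (default 2.5).
#' @return An object of class `event_config`.
#' @export
event_config <- function(window = 5, sd_multiplier = 3, min_duration = 2.5) {
  if (window <= 0) abort("window must be positive")
  if (sd_multiplier <= 0) abort("sd_multiplier must be positive")
  if (min_duration < 0) abort("min_duration must be non-negative")
  structure(list(window = window, sd_multiplier = sd_multiplier,
                 min_duration = min_duration),
            class = "event_config")
}

.trace_rate <- function(trace) {
  dt <- diff(trace$time_s)
  if (any(dt <= 0)) abort("trace time must be strictly increasing")
  if (max(dt) > 1.01 * min(dt) * 1.01 && (max(dt) - min(dt)) / mean(dt) > 0.01) {
    warn("trace sampling is non-uniform beyond 1%; window sizes use the mean rate")
  }
  1 / mean(dt)
}

#' Smooth a trace with a centered sliding-window average
#'
#' Centered moving average over `window` seconds; the output grid equals
#' the input grid and the endpoints use truncated windows.
#'
#' @param trace A trace tibble with `time_s` and `extension_um`.
#' @param window Window length, s.
#' @return The trace with `extension_um` replaced by its smoothed value.
#' @export
smooth_trace <- function(trace, window = 5) {
  .check_cols(trace, c("time_s", "extension_um"), "trace")
  if (window <= 0) abort("window must be positive")
  rate <- .trace_rate(trace)
  if (window > (max(trace$time_s) - min(trace$time_s))) {
    abort("window exceeds the trace duration")
  }
  k <- max(1L, round(window * rate))
  half <- (k - 1) %/% 2
  x <- trace$extension_um
  n <- length(x)
  # truncated-window moving average via cumulative sums
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  dplyr::mutate(trace, extension_um = sm)
}

#' Baseline extension statistics of a protein-free trace
#'
#' Fits a Gaussian to the extension histogram of a torsionally constrained,
#' protein-free tether and returns the fitted mean and SD. A residual check
#' against the fitted density flags non-Gaussian (e.g. bimodal) baselines.
#'
#' @param dna_only A trace tibble of the bare tether (>= 100 samples).
#' @return A list with `mean`, `sd` (um) and `gof_warning` (logical).
#' @export
baseline_stats <- function(dna_only) {
  .check_cols(dna_only, "extension_um", "baseline trace")
  x <- dna_only$extension_um
  if (length(x) < 100) abort("baseline trace needs >= 100 samples")
  if (sd(x) == 0) abort("baseline trace has zero variance")
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids
  dens <- h$density
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ exp(-(mids - m)^2 / (2 * s^2)) / (s * sqrt(2 * pi)),
      start = list(m = mean(x), s = sd(x)),
      lower = c(-Inf, 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    m <- mean(x); s <- sd(x); resid_frac <- 1
  } else {
    m <- coef(fit)[["m"]]; s <- abs(coef(fit)[["s"]])
    resid_frac <- sum(abs(dens - predict(fit))) / sum(dens)
  }
  gof_warning <- resid_frac > 0.25
  if (gof_warning) {
    warn(sprintf(
      "baseline histogram deviates from a Gaussian (residual fraction %.2f); mean/SD may be unreliable",
      resid_frac))
  }
  list(mean = m, sd = s, gof_warning = gof_warning)
}

#' Detect extension events in a magnetic-tweezer trace
#'
#' Smooths the trace, thresholds it at
#' `baseline$mean + sd_multiplier * baseline$sd`, and calls every
#' contiguous excursion above threshold lasting more than `min_duration`
#' as an event. For each event the local maximum of the smoothed extension
#' locates the peak; the positive rate is the least-squares slope of the
#' rising segment into the peak, the negative rate the slope of the
#' falling segment out of it (stored signed), and the lifetime is the time
#' spent above threshold. Events still above threshold at the end of the
#' trace are kept and flagged right-censored.
#'
#' @param trace A trace tibble (`time_s`, `extension_um`), raw or smoothed.
#' @param baseline A list with `mean` and `sd` from [baseline_stats()].
#' @param config An [event_config()].
#' @param presmoothed Set `TRUE` if `trace` is already smoothed.
#' @return A tibble of event calls: `start_s`, `end_s`, `peak_amplitude_um`,
#'   `positive_rate_um_s`, `negative_rate_um_s`, `lifetime_s`, `censored`.
#' @export
detect_events <- function(trace, baseline, config = event_config(),
                          presmoothed = FALSE) {
  .check_cols(trace, c("time_s", "extension_um"), "trace")
  stopifnot(inherits(config, "event_config"))
  if (!is.numeric(baseline$sd) || baseline$sd <= 0) {
    abort("baseline SD must be positive")
  }
  sm <- if (presmoothed) trace else smooth_trace(trace, config$window)
  thr <- baseline$mean + config$sd_multiplier * baseline$sd
  above <- sm$extension_um > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          peak_amplitude_um = numeric(),
                          positive_rate_um_s = numeric(),
                          negative_rate_um_s = numeric(),
                          lifetime_s = numeric(), censored = logical())
  if (length(runs) == 0) return(empty)
  purrr::map_dfr(runs, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    t0 <- sm$time_s[i0]; t1 <- sm$time_s[i1]
    lifetime <- t1 - t0
    if (lifetime <= config$min_duration) return(empty)
    seg <- i0:i1
    ipk <- seg[which.max(sm$extension_um[seg])]
    amp <- sm$extension_um[ipk] - baseline$mean
    rise <- i0:ipk
    fall <- ipk:i1
    pos_rate <- if (length(rise) >= 2) {
      max(coef(lm(extension_um ~ time_s, data = sm[rise, ]))[[2]], 0)
    } else NA_real_
    neg_rate <- if (length(fall) >= 2) {
      coef(lm(extension_um ~ time_s, data = sm[fall, ]))[[2]]
    } else NA_real_
    tibble::tibble(start_s = t0, end_s = t1, peak_amplitude_um = amp,
                   positive_rate_um_s = pos_rate,
                   negative_rate_um_s = neg_rate,
                   lifetime_s = lifetime,
                   censored = i1 == nrow(sm))
  })
}

#' Fit an exponential lifetime distribution to event dwell times
#'
#' Maximum-likelihood exponential fit of event lifetimes with an exact
#' 95% confidence interval from the gamma pivot of the mean (the default);
#' or, with `method = "survival"`, a least-squares fit of the empirical
#' survival curve to `exp(-t * ln 2 / t_half)`.
#'
#' @param events An event tibble from [detect_events()], or any data frame
#'   with a `lifetime_s` column (>= 10 events).
#' @param method `"mle"` (default) or `"survival"`.
#' @return An object of class `lifetime_fit` with `half_life`, `ci95`
#'   (length-2), `n_events` and `method`. [tidy()] and [glance()] return
#'   one-row tibbles.
#' @export
fit_lifetimes <- function(events, method = c("mle", "survival")) {
  method <- match.arg(method)
  .check_cols(events, "lifetime_s", "event table")
  dwell <- events$lifetime_s
  n <- length(dwell)
  if (n < 10) {
    abort(sprintf("exponential lifetime fit needs >= 10 events, got %d", n))
  }
  degenerate <- sd(dwell) == 0
  if (degenerate) {
    warn("all dwell times are identical; the exponential fit is degenerate")
  }
  if (method == "mle") {
    m <- mean(dwell)
    s <- sum(dwell)
    # sum of n exponential dwell times ~ Gamma(n, rate): exact CI for the mean
    ci_mean <- c(2 * s / qchisq(0.975, 2 * n), 2 * s / qchisq(0.025, 2 * n))
    half_life <- log(2) * m
    ci <- log(2) * ci_mean
  } else {
    st <- sort(dwell)
    surv <- 1 - (seq_len(n) - 0.5) / n
    fit <- minpack.lm::nlsLM(surv ~ exp(-st * log(2) / th),
                             start = list(th = log(2) * mean(dwell)),
                             lower = 1e-9)
    half_life <- coef(fit)[["th"]]
    se <- tryCatch(summary(fit)$coefficients[1, 2], error = function(e) NA_real_)
    ci <- half_life + c(-1, 1) * qt(0.975, n - 1) * se
  }
  structure(list(half_life = half_life, ci95 = ci, n_events = n,
                 method = method, degenerate = degenerate),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit> half-life %.2f s (95%% CI %.2f-%.2f), n = %d [%s]\n",
              x$half_life, x$ci95[1], x$ci95[2], x$n_events, x$method))
  invisible(x)
}

#' @rdname fit_lifetimes
#' @param x A `lifetime_fit` object.
#' @param ... Unused.
#' @export
tidy.lifetime_fit <- function(x, ...) {
  tibble::tibble(term = "half_life_s", estimate = x$half_life,
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @rdname fit_lifetimes
#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble::tibble(half_life_s = x$half_life, ci95_lo = x$ci95[1],
                 ci95_hi = x$ci95[2], n_events = x$n_events,
                 method = x$method, degenerate = x$degenerate)
}

#' Buckling-arm slope of a hat curve
#'
#' Least-squares slope of extension versus turns restricted to
#' `[turn_lo, turn_hi]` (default -70 to -20 turns, the negative buckling
#' arm). If the two halves of the range disagree strongly the fit is
#' flagged mixed-regime (the range likely spans the apex or a melting
#' transition).
#'
#' @param hat A tibble with `turns` and `extension_um`.
#' @param turn_lo,turn_hi Range limits in turns.
#' @return A list with `slope` (um/turn), `n_points`, `mixed_regime`
#'   (logical) and `half_slopes`.
#' @export
hat_slope <- function(hat, turn_lo = -70, turn_hi = -20) {
  .check_cols(hat, c("turns", "extension_um"), "hat curve")
  sel <- hat$turns >= turn_lo & hat$turns <= turn_hi
  if (sum(sel) < 3) abort("fewer than 3 hat-curve points in the requested range")
  sub <- hat[sel, ]
  slope <- coef(lm(extension_um ~ turns, data = sub))[[2]]
  mid <- (turn_lo + turn_hi) / 2
  halves <- list(sub[sub$turns <= mid, ], sub[sub$turns > mid, ])
  half_slopes <- vapply(halves, function(h) {
    if (nrow(h) >= 3) coef(lm(extension_um ~ turns, data = h))[[2]] else NA_real_
  }, numeric(1))
  mixed <- FALSE
  if (all(is.finite(half_slopes))) {
    ref <- max(abs(half_slopes))
    mixed <- ref > 0 && (abs(diff(half_slopes)) > 0.5 * ref)
  }
  if (mixed) warn("hat-curve range spans more than one regime; slope is a mixture")
  list(slope = slope, n_points = sum(sel), mixed_regime = mixed,
       half_slopes = half_slopes)
}

#' Truncate a trace once the bead drops below its initial extension
#'
#' Compacting complexes pull the bead below the starting extension; data
#' beyond the first such sample are discarded even if the extension later
#' recovers. The returned flag records whether truncation occurred.
#'
#' @param trace A trace tibble.
#' @param baseline Optional baseline list; if given, its `mean` is used as
#'   the initial extension instead of the first sample.
#' @return A list with `kept` (truncated trace) and `censored` (logical).
#' @export
screen_compaction <- function(trace, baseline = NULL) {
  .check_cols(trace, c("time_s", "extension_um"), "trace")
  init <- if (!is.null(baseline)) baseline$mean else trace$extension_um[1]
  below <- which(trace$extension_um < init)
  below <- below[below > 1]
  if (length(below) == 0) {
    return(list(kept = trace, censored = FALSE))
  }
  list(kept = trace[seq_len(below[1] - 1L), ], censored = TRUE)
}
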