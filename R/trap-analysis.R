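# Optical-trap analyses: decomposition of measured force-extension curves
# into bare-DNA theory plus compaction intermediates (first/final
# deviation, per-loop sizes and rupture forces), constant-force clamp
# velocities, and maximum force output during translocation events.

# Constrained DNA (bp) implied by a measured (extension, force) point:
# the effective contour is the contour whose WLC passes through the point,
# and the deficit relative to the full tether is the sequestered DNA.
.constrained_bp <- function(wlc, extension_um, force_pn) {
  rel <- wlc_force_to_extension(wlc, force_pn) / wlc$contour_length_um
  l_eff_um <- extension_um / rel
  wlc$contour_length_bp - l_eff_um * 1000 / wlc$rise_per_bp
}

#' Decompose a force-extension curve into theory plus compaction intermediates
#'
#' Compares a measured re-extension curve with the extensible worm-like
#' chain of the bare tether. The first deviation is the point where the
#' measured force first exceeds theory by `dev_threshold` sustained over
#' `sustain_um` of extension; the sequestered DNA there is reported in bp
#' via the effective-contour deficit. Each rupture is a local force
#' maximum followed by a drop of at least `drop_threshold` back toward
#' theory; the loop size is the change in effective contour across the
#' drop, and ruptures are reported in increasing-extension order. The
#' final deviation is the residual constrained DNA where the curve last
#' rejoins (or, if it never rejoins, at the end of the pull, flagged as a
#' lower bound).
#'
#' @param curve An FE tibble (`extension_um`, `force_pn`), extension
#'   increasing.
#' @param wlc A [wlc_params()] for the full tether.
#' @param dev_threshold Force excess over theory that counts as deviation,
#'   pN (default 0.5).
#' @param sustain_um Extension span over which the excess must persist, um
#'   (default 0.05).
#' @param drop_threshold Force drop that counts as a rupture, pN
#'   (default 1).
#' @param min_loop_bp Smallest loop size reported as an intermediate, bp
#'   (default 250); smaller apparent ruptures are treated as noise.
#' @param smooth_k Running-mean half-width (samples) applied to the force
#'   channel before rupture tracking (default 3, i.e. a 7-sample window).
#' @return An object of class `deviation_set`: a list with
#'   `first_deviation_bp`, `final_deviation_bp`, `n_intermediates`,
#'   `intermediates` (tibble `loop_bp`, `rupture_pn`, `order`),
#'   `rejoined` (logical). [tidy()] returns the intermediates, [glance()]
#'   a one-row summary.
#' @export
compare_to_theory <- function(curve, wlc, dev_threshold = 0.5,
                              sustain_um = 0.05, drop_threshold = 1,
                              min_loop_bp = 250, smooth_k = 3L) {
  .check_cols(curve, c("extension_um", "force_pn"), "FE curve")
  stopifnot(inherits(wlc, "wlc_params"))
  curve <- dplyr::arrange(tibble::as_tibble(curve), .data$extension_um)
  if (max(curve$force_pn) < 5) {
    abort("FE curve must reach at least 5 pN for a deviation analysis")
  }
  x <- curve$extension_um
  f_raw <- curve$force_pn
  # light running-mean smoothing keeps white force noise from mimicking
  # ruptures while leaving the programmed drops (>= drop_threshold) intact
  f <- if (smooth_k > 0 && length(f_raw) > 2 * smooth_k + 1) {
    n <- length(f_raw)
    cs <- cumsum(c(0, f_raw))
    lo <- pmax(seq_len(n) - smooth_k, 1L)
    hi <- pmin(seq_len(n) + smooth_k, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else f_raw
  cap <- max(f) * 1.5 + 10
  x_cap <- wlc$contour_length_um * (1 + cap / wlc$stretch_modulus) * 0.999
  theory <- wlc_extension_to_force(wlc, pmin(x, x_cap), force_cap = cap)
  excess <- f - theory

  # first sustained crossing of the deviation threshold
  over <- excess > dev_threshold
  first_idx <- NA_integer_
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    if (x[ends[j]] - x[starts[j]] >= sustain_um) { first_idx <- starts[j]; break }
  }

  empty <- tibble::tibble(loop_bp = numeric(), rupture_pn = numeric(),
                          order = integer())
  if (is.na(first_idx)) {
    out <- list(first_deviation_bp = 0, final_deviation_bp = 0,
                n_intermediates = 0L, intermediates = empty, rejoined = TRUE)
    class(out) <- "deviation_set"
    return(out)
  }

  # rupture detection: track the running force maximum since the last
  # rupture; a drop of drop_threshold below it marks a rupture at the peak
  peaks <- integer()
  troughs <- integer()
  i_max <- first_idx
  f_max <- f[first_idx]
  in_drop <- FALSE
  i_min <- first_idx
  f_min <- f[first_idx]
  for (i in seq(first_idx, length(f))) {
    if (!in_drop) {
      if (f[i] >= f_max) { f_max <- f[i]; i_max <- i }
      if (f_max - f[i] >= drop_threshold) {
        in_drop <- TRUE; f_min <- f[i]; i_min <- i
      }
    } else {
      if (f[i] <= f_min) { f_min <- f[i]; i_min <- i }
      if (f[i] - f_min >= drop_threshold) {
        peaks <- c(peaks, i_max); troughs <- c(troughs, i_min)
        in_drop <- FALSE; f_max <- f[i]; i_max <- i
      }
    }
  }
  if (in_drop) { peaks <- c(peaks, i_max); troughs <- c(troughs, i_min) }

  # local averaging keeps the effective-contour estimates noise-robust
  avg_window <- function(i, side = c("before", "after"), k = 5L) {
    side <- match.arg(side)
    idx <- if (side == "before") max(1L, i - k + 1L):i
           else i:min(length(f), i + k - 1L)
    c(mean(x[idx]), mean(f[idx]))
  }
  bp_at <- function(i, side) {
    p <- avg_window(i, side)
    .constrained_bp(wlc, p[1], p[2])
  }

  # size every candidate rupture; sub-min_loop_bp drops are noise
  intermediates <- empty
  if (length(peaks) > 0) {
    loop_bp <- vapply(seq_along(peaks), function(k) {
      bp_at(peaks[k], "before") - bp_at(troughs[k], "after")
    }, numeric(1))
    keep <- loop_bp >= min_loop_bp
    peaks <- peaks[keep]
    troughs <- troughs[keep]
    if (any(keep)) {
      n_s <- length(f_raw)
      rupt <- vapply(peaks, function(p) {
        max(f_raw[max(1L, p - smooth_k):min(n_s, p + smooth_k)])
      }, numeric(1))
      intermediates <- tibble::tibble(
        loop_bp = loop_bp[keep],
        rupture_pn = rupt,
        order = seq_along(peaks))
    }
  }

  # constrained DNA before the first rupture: use the highest-force part
  # of the pre-rupture segment, where the bp deficit is best conditioned
  seg_end <- if (length(peaks) > 0) peaks[1] else length(f)
  seg <- first_idx:seg_end
  hi_f <- seg[f[seg] >= quantile(f[seg], 0.75)]
  first_dev_bp <- median(.constrained_bp(wlc, x[hi_f], f[hi_f]))

  # residual constrained DNA after the last rupture
  tail_start <- if (length(troughs) > 0) troughs[length(troughs)] else first_idx
  tail_seg <- tail_start:length(f)
  hi_t <- tail_seg[f[tail_seg] >= quantile(f[tail_seg], 0.75)]
  final_dev_bp <- max(median(.constrained_bp(wlc, x[hi_t], f[hi_t])), 0)
  tail_excess <- mean(excess[hi_t])
  rejoined <- tail_excess <= dev_threshold
  if (!rejoined && final_dev_bp > 0) {
    warn("curve never rejoins theory; final deviation is a lower bound")
  }

  out <- list(first_deviation_bp = first_dev_bp,
              final_deviation_bp = final_dev_bp,
              n_intermediates = nrow(intermediates),
              intermediates = intermediates,
              rejoined = rejoined)
  class(out) <- "deviation_set"
  out
}

#' @export
print.deviation_set <- function(x, ...) {
  cat(sprintf(
    "<deviation_set> first deviation %.0f bp, final %.0f bp, %d intermediate(s)%s\n",
    x$first_deviation_bp, x$final_deviation_bp, x$n_intermediates,
    if (x$rejoined) "" else " [never rejoins theory]"))
  invisible(x)
}

#' @rdname compare_to_theory
#' @param x A `deviation_set`.
#' @param ... Unused.
#' @export
tidy.deviation_set <- function(x, ...) x$intermediates

#' @rdname compare_to_theory
#' @export
glance.deviation_set <- function(x, ...) {
  tibble::tibble(first_deviation_bp = x$first_deviation_bp,
                 final_deviation_bp = x$final_deviation_bp,
                 n_intermediates = x$n_intermediates,
                 mean_loop_bp = if (x$n_intermediates > 0)
                   mean(x$intermediates$loop_bp) else NA_real_,
                 rejoined = x$rejoined)
}

#' Velocity of compaction or translocation under a force clamp
#'
#' Fits a line to bead separation versus time over the active segment of a
#' constant-force trace and converts the slope to bp/s via the helical
#' rise. The mode is `"compaction"` if the separation shortens and
#' `"translocation"` otherwise; the reported velocity is unsigned.
#'
#' @param trace A trace tibble (`time_s`, `extension_um`) at constant
#'   force, covering >= 2 s.
#' @param wlc A [wlc_params()] supplying the helical rise.
#' @return A tibble with `velocity_bp_s`, `velocity_um_s` (signed slope),
#'   `mode`, `duration_s`.
#' @export
clamp_velocity <- function(trace, wlc = wlc_params()) {
  .check_cols(trace, c("time_s", "extension_um"), "clamp trace")
  dur <- max(trace$time_s) - min(trace$time_s)
  if (dur < 2) abort(sprintf("clamp segment of %.2f s is too short (< 2 s)", dur))
  slope <- coef(lm(extension_um ~ time_s, data = trace))[[2]]
  tibble::tibble(
    velocity_bp_s = abs(slope) * 1000 / wlc$rise_per_bp,
    velocity_um_s = slope,
    mode = if (slope < 0) "compaction" else "translocation",
    duration_s = dur
  )
}

#' Maximum force output per translocation event
#'
#' Smooths the force channel with the standard sliding window, segments
#' translocation events as excursions more than `event_threshold` above
#' the pre-event baseline that end when the force returns to within
#' `event_threshold` of it, and reports the per-event force maxima. A
#' trace without excursions yields a single row with the overall maximum.
#'
#' @param trace A tibble with `time_s` and `force_pn`.
#' @param window Smoothing window, s (default 5).
#' @param event_threshold Excursion threshold above baseline, pN
#'   (default 1).
#' @return A tibble with `event`, `start_s`, `end_s`, `max_force_pn`.
#' @export
max_force <- function(trace, window = 5, event_threshold = 1) {
  .check_cols(trace, c("time_s", "force_pn"), "force trace")
  if (nrow(trace) == 0) abort("empty force trace")
  dur <- max(trace$time_s) - min(trace$time_s)
  sm <- if (dur > window) {
    tmp <- smooth_trace(
      tibble::tibble(time_s = trace$time_s, extension_um = trace$force_pn),
      window)
    tmp$extension_um
  } else trace$force_pn
  base <- median(sm[seq_len(max(1L, min(length(sm), ceiling(length(sm) / 20))))])
  above <- sm > base + event_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) {
    return(tibble::tibble(event = 1L, start_s = min(trace$time_s),
                          end_s = max(trace$time_s), max_force_pn = max(sm)))
  }
  purrr::imap_dfr(runs, function(j, k) {
    seg <- starts[j]:ends[j]
    tibble::tibble(event = as.integer(k),
                   start_s = trace$time_s[starts[j]],
                   end_s = trace$time_s[ends[j]],
                   max_force_pn = max(sm[seg]))
  })
}
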