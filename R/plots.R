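# ggplot2 visualizations for each result type.

#' @export
autoplot.lfr_sim <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$lfr)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(
      x = "loop formation rate (bp/s)", y = "replicates",
      title = sprintf("Two-motor LFR: %g-fold activation, mean %.0f bp/s",
                      object$fold_activation, object$mean)) +
    ggplot2::theme_minimal()
}

#' Plot a magnetic-tweezer trace with optional event calls
#'
#' @param trace A trace tibble (`time_s`, `extension_um`).
#' @param events Optional event tibble from [detect_events()].
#' @param baseline Optional baseline list; drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, baseline = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s,
                                           y = .data$extension_um)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "extension (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline$mean,
                                 linetype = "dashed", colour = "grey50")
  }
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "orange", alpha = 0.2)
  }
  p
}

#' Plot a measured force-extension curve against worm-like-chain theory
#'
#' @param curve An FE tibble (`extension_um`, `force_pn`).
#' @param wlc A [wlc_params()]; the theoretical curve of the bare tether.
#' @return A ggplot object.
#' @export
plot_fe_curve <- function(curve, wlc = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$extension_um,
                                           y = .data$force_pn)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "extension (µm)", y = "force (pN)") +
    ggplot2::theme_minimal()
  if (!is.null(wlc)) {
    fgrid <- seq(0.05, max(curve$force_pn), length.out = 300)
    theory <- tibble::tibble(extension_um = wlc_force_to_extension(wlc, fgrid),
                             force_pn = fgrid)
    p <- p + ggplot2::geom_line(data = theory, colour = "grey40",
                                linetype = "dashed")
  }
  p
}

#' Plot a hat curve with the fitted buckling-arm range highlighted
#'
#' @param hat A tibble with `turns`, `extension_um`.
#' @param turn_lo,turn_hi Optional fitted range to highlight.
#' @return A ggplot object.
#' @export
plot_hat_curve <- function(hat, turn_lo = NULL, turn_hi = NULL) {
  p <- ggplot2::ggplot(hat, ggplot2::aes(x = .data$turns,
                                         y = .data$extension_um)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::labs(x = "magnet turns", y = "extension (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(turn_lo) && !is.null(turn_hi)) {
    p <- p + ggplot2::annotate("rect", xmin = turn_lo, xmax = turn_hi,
                               ymin = -Inf, ymax = Inf,
                               fill = "orange", alpha = 0.15)
  }
  p
}

#' @export
autoplot.stall_fit <- function(object, ...) {
  pts <- object$points
  tq_max <- if (is.na(object$stall_torque_pn_nm)) max(pts$torque_pn_nm)
            else max(object$stall_torque_pn_nm * 1.05, max(pts$torque_pn_nm))
  grid <- seq(0, tq_max, length.out = 100)
  bands <- predict_bands(object, grid)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$torque_pn_nm,
                                    y = .data$mean_rate)) +
    ggplot2::geom_ribbon(data = bands, inherit.aes = FALSE,
                         ggplot2::aes(x = .data$torque_pn_nm,
                                      ymin = .data$ci95_lo,
                                      ymax = .data$ci95_hi),
                         alpha = 0.15) +
    ggplot2::geom_line(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$torque_pn_nm, y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci95_lo,
                                          ymax = .data$ci95_hi)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "torque (pN·nm)", y = "mean extension rate",
                  title = sprintf("Stall torque %s pN·nm (r² = %.2f)",
                                  if (is.na(object$stall_torque_pn_nm)) "undefined"
                                  else sprintf("%.1f", object$stall_torque_pn_nm),
                                  object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fv_fit <- function(object, ...) {
  dat <- object$data
  grid <- seq(min(dat$force_pn), max(dat$force_pn), length.out = 200)
  pred <- tibble::tibble(
    force_pn = grid,
    velocity_bp_s = predict(object$fit, newdata = list(f = grid)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$force_pn,
                                    y = .data$velocity_bp_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(x = "force (pN)", y = "velocity (bp/s)",
                  title = sprintf("%s fit (r² = %.2f)",
                                  object$model, object$r2)) +
    ggplot2::theme_minimal()
}
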