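# Torque-plot construction, linear stall-torque extrapolation,
# coupling-efficiency unit conversion, and force-velocity curve fits
# (rectangular hyperbola for the rising translocation branch, single-phase
# exponential decay for the falling loop-extrusion branch).

#' Build a torque plot from per-force rate measurements
#'
#' Groups rate measurements by force, computes the mean rate and its 95%
#' confidence interval (t distribution), and attaches the torque on the
#' DNA from the force-torque power law.
#'
#' @param per_force_rates A data frame with columns `force_pn` and `rate`
#'   (one row per measurement; any rate unit).
#' @param model A [torque_model()].
#' @return A tibble with `force_pn`, `torque_pn_nm`, `mean_rate`,
#'   `ci95_lo`, `ci95_hi`, `n`, ordered by torque.
#' @export
build_torque_plot <- function(per_force_rates, model = torque_model()) {
  .check_cols(per_force_rates, c("force_pn", "rate"), "rate table")
  stopifnot(inherits(model, "torque_model"))
  if (dplyr::n_distinct(per_force_rates$force_pn) < 2) {
    abort("a torque plot needs measurements at >= 2 distinct forces")
  }
  per_force_rates |>
    dplyr::group_by(.data$force_pn) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate),
      ci_half = ifelse(dplyr::n() > 1,
                       qt(0.975, dplyr::n() - 1) * sd(.data$rate) / sqrt(dplyr::n()),
                       NA_real_),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      torque_pn_nm = force_to_torque(model, .data$force_pn),
      ci95_lo = .data$mean_rate - .data$ci_half,
      ci95_hi = .data$mean_rate + .data$ci_half) |>
    dplyr::select("force_pn", "torque_pn_nm", "mean_rate",
                  "ci95_lo", "ci95_hi", "n") |>
    dplyr::arrange(.data$torque_pn_nm)
}

#' Linear stall-torque extrapolation from a torque plot
#'
#' Ordinary least squares of mean rate against torque. Both intercepts are
#' reported explicitly: the rate at zero torque (the "no torque" velocity)
#' and the torque at zero rate (the stall torque, defined only for a
#' negative slope). Extrapolating a stall torque assumes the
#' rate-torque relationship stays linear beyond the measured range, which
#' is a simplification; the fitted value may underestimate the true stall.
#'
#' @param points A torque-plot tibble from [build_torque_plot()] (>= 3
#'   points).
#' @param weighted If `TRUE`, weight points by `1/CI^2`.
#' @return An object of class `stall_fit` with `slope`,
#'   `rate_at_zero_torque`, `stall_torque_pn_nm` (NA and flagged when the
#'   slope is non-negative), `r2`, and the underlying `lm` fit.
#'   [tidy()]/[glance()] return tibbles; [predict_bands()] evaluates the
#'   95% confidence band.
#' @export
fit_stall <- function(points, weighted = FALSE) {
  .check_cols(points, c("torque_pn_nm", "mean_rate"), "torque plot")
  if (nrow(points) < 3) abort("stall extrapolation needs >= 3 torque points")
  if (sd(points$mean_rate) == 0) {
    warn("all mean rates are equal; slope is zero and the stall torque is undefined")
  }
  w <- NULL
  if (weighted) {
    half <- (points$ci95_hi - points$ci95_lo) / 2
    if (any(!is.finite(half)) || any(half <= 0)) {
      abort("weighted fit requires finite positive confidence intervals")
    }
    w <- 1 / half^2
  }
  fit <- lm(mean_rate ~ torque_pn_nm, data = points, weights = w)
  slope <- coef(fit)[[2]]
  icpt <- coef(fit)[[1]]
  stall <- if (slope < 0) -icpt / slope else NA_real_
  if (is.na(stall)) warn("non-negative slope: stall torque not defined")
  structure(list(slope = slope, rate_at_zero_torque = icpt,
                 stall_torque_pn_nm = stall,
                 r2 = summary(fit)$r.squared, fit = fit,
                 points = tibble::as_tibble(points)),
            class = "stall_fit")
}

#' @export
print.stall_fit <- function(x, ...) {
  cat(sprintf(
    "<stall_fit> rate = %.4g %+.4g * torque (r2 = %.3f)\n  zero-torque rate %.4g, stall torque %s pN*nm\n",
    x$rate_at_zero_torque, x$slope, x$r2,
    x$rate_at_zero_torque,
    if (is.na(x$stall_torque_pn_nm)) "undefined"
    else sprintf("%.2f", x$stall_torque_pn_nm)))
  invisible(x)
}

#' @rdname fit_stall
#' @param x A `stall_fit`.
#' @param ... Unused.
#' @export
tidy.stall_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("rate_at_zero_torque", "slope"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_stall
#' @export
glance.stall_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope,
                 rate_at_zero_torque = x$rate_at_zero_torque,
                 stall_torque_pn_nm = x$stall_torque_pn_nm,
                 r2 = x$r2, n = nrow(x$points))
}

#' 95% confidence band of a stall fit at requested torques
#'
#' @param object A `stall_fit`.
#' @param torque Torques (pN*nm) at which to evaluate the band.
#' @return A tibble with `torque_pn_nm`, `fit`, `ci95_lo`, `ci95_hi`.
#' @export
predict_bands <- function(object, torque) {
  stopifnot(inherits(object, "stall_fit"))
  p <- predict(object$fit, newdata = data.frame(torque_pn_nm = torque),
               interval = "confidence", level = 0.95)
  tibble::tibble(torque_pn_nm = torque, fit = p[, "fit"],
                 ci95_lo = p[, "lwr"], ci95_hi = p[, "upr"])
}

#' Convert torque-plot rates from um/s to bp/s
#'
#' Uses the buckling-arm slope of the tether's hat curve to convert um/s
#' to turns/s, then the coupling model to convert turns/s to bp/s:
#' `rate_bp_s = (rate / |hat_slope|) * bp_per_turn / coupling_efficiency`.
#'
#' @param points A torque-plot tibble whose rate columns are in um/s.
#' @param hat_slope Buckling-arm slope, um/turn (non-zero; the sign is
#'   ignored).
#' @param coupling A [coupling_model()].
#' @return The tibble with `mean_rate`, `ci95_lo`, `ci95_hi` rescaled to
#'   bp/s.
#' @export
convert_plot_units <- function(points, hat_slope, coupling = coupling_model()) {
  .check_cols(points, "mean_rate", "torque plot")
  stopifnot(inherits(coupling, "coupling_model"))
  if (!is.finite(hat_slope) || hat_slope == 0) {
    abort("hat_slope must be non-zero")
  }
  scale <- (1 / abs(hat_slope)) * coupling$bp_per_turn / coupling$coupling_efficiency
  dplyr::mutate(points, dplyr::across(
    dplyr::any_of(c("mean_rate", "ci95_lo", "ci95_hi")), ~ .x * scale))
}

#' Fit a force-velocity relationship
#'
#' Nonlinear least squares of velocity against force with either a
#' rectangular hyperbola `v = Vmax * F / (K + F)` (monotone increasing;
#' the translocation branch) or a single-phase exponential decay
#' `v = v0 * exp(-F / tau) + c` (monotone decreasing; the loop-extrusion
#' branch). A fit whose r-squared is below 0.5 is flagged as model
#' mismatch.
#'
#' @param data A data frame with `force_pn` and `velocity_bp_s` (>= 4
#'   points).
#' @param model `"rectangular_hyperbola"` or `"single_exp_decay"`.
#' @return An object of class `fv_fit` with `model`, `params` (named
#'   list), `r2`, `mismatch` and the underlying fit.
#' @export
fit_force_velocity <- function(data,
                               model = c("rectangular_hyperbola",
                                         "single_exp_decay")) {
  model <- match.arg(model)
  .check_cols(data, c("force_pn", "velocity_bp_s"), "force-velocity table")
  if (nrow(data) < 4) abort("force-velocity fit needs >= 4 points")
  f <- data$force_pn
  v <- data$velocity_bp_s
  if (sd(v) == 0) {
    # flat data: the hyperbola degenerates (K -> 0, vmax -> v) and the
    # decay degenerates (v0 -> 0); report the limit rather than fitting
    warn(sprintf("constant velocities: '%s' is degenerate", model))
    params <- if (model == "rectangular_hyperbola") {
      list(vmax = v[1], k = 0)
    } else {
      list(v0 = 0, tau = NA_real_, c0 = v[1])
    }
    return(structure(list(model = model, params = params, r2 = NA_real_,
                          mismatch = TRUE, fit = NULL,
                          data = tibble::as_tibble(data)),
                     class = "fv_fit"))
  }
  fit <- tryCatch({
    if (model == "rectangular_hyperbola") {
      minpack.lm::nlsLM(v ~ vmax * f / (k + f),
                        start = list(vmax = max(v), k = max(median(f), 1e-3)),
                        control = list(maxiter = 200))
    } else {
      minpack.lm::nlsLM(v ~ v0 * exp(-f / tau) + c0,
                        start = list(v0 = max(v) - min(v),
                                     tau = max(median(f), 1e-3),
                                     c0 = min(v)),
                        control = list(maxiter = 200))
    }
  }, error = function(e) {
    abort(sprintf("force-velocity fit failed to converge: %s", conditionMessage(e)))
  })
  ssr <- sum(residuals(fit)^2)
  sst <- sum((v - mean(v))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  params <- as.list(coef(fit))
  degenerate <- model == "rectangular_hyperbola" && params$k < 1e-6
  mismatch <- (is.finite(r2) && r2 < 0.5) || degenerate
  if (mismatch) {
    warn(sprintf("force-velocity model '%s' fits poorly (r2 = %.2f%s)",
                 model, r2, if (degenerate) ", K ~ 0" else ""))
  }
  structure(list(model = model, params = params, r2 = r2,
                 mismatch = mismatch, fit = fit,
                 data = tibble::as_tibble(data)),
            class = "fv_fit")
}

#' @export
print.fv_fit <- function(x, ...) {
  cat(sprintf("<fv_fit> %s: %s (r2 = %.3f)%s\n", x$model,
              paste(names(x$params),
                    vapply(x$params, function(p) sprintf("%.4g", p), ""),
                    sep = " = ", collapse = ", "),
              x$r2, if (x$mismatch) " [model mismatch]" else ""))
  invisible(x)
}

#' @rdname fit_force_velocity
#' @param x An `fv_fit`.
#' @param ... Unused.
#' @export
tidy.fv_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname fit_force_velocity
#' @export
glance.fv_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r2 = x$r2, mismatch = x$mismatch,
                 n = nrow(x$data))
}

#' @importFrom stats residuals
NULL
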