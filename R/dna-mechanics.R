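# Polymer-mechanics primitives shared by every analysis: extensible
# worm-like-chain (WLC) force-extension, contour-length unit bridges,
# the rotation-extension ("hat") curve model, the empirical force->torque
# power law, and the turns -> bp/s conversion with coupling efficiency.
#
# Units are fixed package-wide: um for extension, pN for force, pN*nm for
# torque, seconds for time, bp for sequence length.

# Thermal energy at 25 C, pN*nm.
.KBT_PN_NM <- 4.114

#' Elastic parameters of a double-stranded DNA tether
#'
#' Bundles the parameters of the extensible worm-like-chain model used to
#' generate theoretical force-extension curves and to convert between
#' contour length, extension and force. Defaults describe a torsionally
#' unconstrained lambda-DNA tether in physiological buffer.
#'
#' @param contour_length_bp Contour length in base pairs (default 48502,
#'   full-length lambda-DNA).
#' @param rise_per_bp Helical rise in nm/bp (default 0.338, B-form DNA).
#' @param persistence_length Persistence length in nm (default 43.3).
#' @param stretch_modulus Enthalpic stretch modulus in pN (default 1205).
#'
#' @return An object of class `wlc_params`.
#' @examples
#' wlc <- wlc_params()
#' contour_length_um(wlc$contour_length_bp, wlc$rise_per_bp)
#' @export
wlc_params <- function(contour_length_bp = 48502L,
                       rise_per_bp = 0.338,
                       persistence_length = 43.3,
                       stretch_modulus = 1205) {
  vals <- c(contour_length_bp, rise_per_bp, persistence_length, stretch_modulus)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all WLC parameters must be finite and strictly positive")
  }
  structure(
    list(
      contour_length_bp = contour_length_bp,
      rise_per_bp = rise_per_bp,
      persistence_length = persistence_length,
      stretch_modulus = stretch_modulus,
      contour_length_um = contour_length_bp * rise_per_bp / 1000
    ),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat("<wlc_params>\n")
  cat(sprintf("  contour: %d bp (%.2f um at %.3f nm/bp)\n",
              x$contour_length_bp, x$contour_length_um, x$rise_per_bp))
  cat(sprintf("  persistence length: %.1f nm, stretch modulus: %.0f pN\n",
              x$persistence_length, x$stretch_modulus))
  invisible(x)
}

#' Contour length of a DNA segment in micrometres
#'
#' @param bp Length in base pairs (non-negative).
#' @param rise_per_bp Helical rise in nm/bp (default 0.338).
#' @return Contour length in um.
#' @examples
#' contour_length_um(48502) # 16.39 um, the full extension of lambda-DNA
#' @export
contour_length_um <- function(bp, rise_per_bp = 0.338) {
  if (any(bp < 0)) abort("bp must be non-negative")
  if (any(rise_per_bp <= 0)) abort("rise_per_bp must be positive")
  bp * rise_per_bp / 1000
}

#' Total length of an end-labelled magnetic-tweezer DNA template
#'
#' A torsionally constrained template is a central duplex with a
#' multi-labelled adapter ligated at each end.
#'
#' @param center_bp Length of the central duplex in bp.
#' @param adapter_bp Length of one adapter in bp.
#' @param n_adapters Number of adapters (default 2, one per end).
#' @return Total template length in bp.
#' @examples
#' template_total_bp(12667, 500) # 13667
#' @export
template_total_bp <- function(center_bp, adapter_bp, n_adapters = 2L) {
  if (center_bp < 0 || adapter_bp < 0 || n_adapters < 0) {
    abort("template segment lengths must be non-negative")
  }
  center_bp + n_adapters * adapter_bp
}

# Marko-Siggia interpolation with enthalpic stretch: force as a function of
# the elastic fractional extension z = x/L - F/K.
.wlc_force_of_z <- function(z, lp) {
  (.KBT_PN_NM / lp) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Extension of an extensible worm-like chain at a given force
#'
#' Solves the Marko-Siggia interpolation formula with an enthalpic stretch
#' term for the equilibrium extension at each force. The mapping is strictly
#' increasing, tends to zero at zero force, and approaches
#' `contour * (1 + F/K)` in the enthalpic regime.
#'
#' @param params A [wlc_params()] object.
#' @param force Force(s) in pN, non-negative.
#' @return Extension(s) in um.
#' @examples
#' wlc_force_to_extension(wlc_params(), c(0.5, 5, 30))
#' @export
wlc_force_to_extension <- function(params, force) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(force < 0)) abort("force must be non-negative")
  lp <- params$persistence_length
  K <- params$stretch_modulus
  L <- params$contour_length_um
  vapply(force, function(f) {
    if (f == 0) return(0)
    z <- uniroot(function(z) .wlc_force_of_z(z, lp) - f,
                 lower = 0, upper = 1 - 1e-9, tol = 1e-12)$root
    L * (z + f / K)
  }, numeric(1))
}

#' Force on an extensible worm-like chain at a given extension
#'
#' Inverse of [wlc_force_to_extension()] by monotone root-finding on the
#' closed-form residual; the round trip is the identity to better than
#' 1e-6 pN over the working force range.
#'
#' @param params A [wlc_params()] object.
#' @param extension Extension(s) in um, in `[0, contour * (1 + force_cap/K))`.
#' @param force_cap Largest admissible force in pN (default 100); extensions
#'   beyond the corresponding enthalpic cap raise an error.
#' @return Force(s) in pN.
#' @examples
#' wlc_extension_to_force(wlc_params(), 12.5)
#' @export
wlc_extension_to_force <- function(params, extension, force_cap = 100) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(extension < 0)) abort("extension must be non-negative")
  lp <- params$persistence_length
  K <- params$stretch_modulus
  L <- params$contour_length_um
  x_cap <- L * (1 - 1e-9 + force_cap / K)
  if (any(extension >= x_cap)) {
    abort(sprintf("extension beyond the enthalpic cap %.3f um at force_cap %.0f pN",
                  x_cap, force_cap))
  }
  vapply(extension, function(x) {
    if (x == 0) return(0)
    # residual of F = f(z) with z = x/L - F/K
    g <- function(f) .wlc_force_of_z(pmin(pmax(x / L - f / K, 0), 1 - 1e-12), lp) - f
    uniroot(g, lower = 0, upper = force_cap, tol = 1e-10, extendInt = "no")$root
  }, numeric(1))
}

#' Empirical force-to-torque conversion for a plectonemic DNA tether
#'
#' Power-law conversion between the stretching force applied to a
#' torsionally constrained tether and the torque on the DNA,
#' `torque = coefficient * force^exponent`.
#'
#' @param coefficient Torque at 1 pN, in pN*nm (default 12.7825).
#' @param exponent Dimensionless exponent in (0, 1] (default 0.63447).
#' @return An object of class `torque_model`.
#' @export
torque_model <- function(coefficient = 12.7825, exponent = 0.63447) {
  if (coefficient <= 0) abort("coefficient must be positive")
  if (exponent <= 0 || exponent > 1) abort("exponent must lie in (0, 1]")
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "torque_model")
}

#' Torque on a torsionally constrained tether at a given force
#'
#' @param model A [torque_model()].
#' @param force Force(s) in pN, non-negative.
#' @return Torque(s) in pN*nm.
#' @examples
#' force_to_torque(torque_model(), 1) # 12.7825
#' @export
force_to_torque <- function(model, force) {
  stopifnot(inherits(model, "torque_model"))
  if (any(force < 0)) abort("force must be non-negative")
  model$coefficient * force^model$exponent
}

#' Twist-translocation coupling of a DNA motor
#'
#' Relates turns added to the superhelical axis to base pairs translocated:
#' at 1:1 coupling one turn is added per helical repeat (10.5 bp) traveled;
#' at lower coupling efficiency more base pairs must be traveled per net
#' turn, so the inferred bp/s rate is higher.
#'
#' @param bp_per_turn Base pairs per helical turn (default 10.5, B-form).
#' @param coupling_efficiency Fraction of traveled helical repeats converted
#'   to net turns, in (0, 1].
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(bp_per_turn = 10.5, coupling_efficiency = 1) {
  if (bp_per_turn <= 0) abort("bp_per_turn must be positive")
  if (coupling_efficiency <= 0 || coupling_efficiency > 1) {
    abort("coupling_efficiency must lie in (0, 1]")
  }
  structure(list(bp_per_turn = bp_per_turn,
                 coupling_efficiency = coupling_efficiency),
            class = "coupling_model")
}

#' Convert a twisting rate to a translocation rate
#'
#' @param turn_rate Twisting rate(s) in turns/s, non-negative.
#' @param model A [coupling_model()].
#' @return Translocation rate(s) in bp/s:
#'   `turn_rate * bp_per_turn / coupling_efficiency`.
#' @examples
#' turns_rate_to_bp_rate(15.05, coupling_model(coupling_efficiency = 0.75))
#' @export
turns_rate_to_bp_rate <- function(turn_rate, model = coupling_model()) {
  stopifnot(inherits(model, "coupling_model"))
  if (any(turn_rate < 0)) abort("turn_rate must be non-negative")
  turn_rate * model$bp_per_turn / model$coupling_efficiency
}

#' Idealized rotation-extension (hat) curve of a torsionally constrained tether
#'
#' Piecewise-linear model of bead extension versus applied magnet turns: a
#' torsion-absorbing plateau at the apex extension between the two buckling
#' transitions, and linear plectonemic descent beyond them. Only the arm
#' slopes and the apex are consumed downstream, so no smoothed apex is
#' modelled.
#'
#' @param apex_turn Turn number of maximal extension.
#' @param apex_extension Extension at the apex, um.
#' @param buckling_turn_neg,buckling_turn_pos Turn numbers of the negative
#'   and positive buckling transitions (`neg < apex < pos`).
#' @param slope_neg,slope_pos Arm slopes in um/turn. `slope_pos` must be
#'   negative (descent with added positive turns) and `slope_neg` positive
#'   (descent toward more negative turns).
#' @return An object of class `hat_curve_model`.
#' @export
hat_curve_model <- function(apex_turn = 0, apex_extension = 3.5,
                            buckling_turn_neg = -15, buckling_turn_pos = 15,
                            slope_neg = 0.045, slope_pos = -0.045) {
  if (!(buckling_turn_neg < apex_turn && apex_turn < buckling_turn_pos)) {
    abort("buckling turns must bracket the apex turn")
  }
  if (apex_extension <= 0) abort("apex_extension must be positive")
  if (slope_pos > 0 || slope_neg < 0) {
    abort("slopes must descend away from the apex (slope_pos <= 0 <= slope_neg)")
  }
  structure(
    list(apex_turn = apex_turn, apex_extension = apex_extension,
         buckling_turn_neg = buckling_turn_neg,
         buckling_turn_pos = buckling_turn_pos,
         slope_neg = slope_neg, slope_pos = slope_pos),
    class = "hat_curve_model"
  )
}

#' Predicted extension of a hat-curve model at given turns
#'
#' @param model A [hat_curve_model()].
#' @param turns Applied turns (any real values).
#' @return Extension(s) in um, clamped at zero.
#' @export
hat_extension <- function(model, turns) {
  stopifnot(inherits(model, "hat_curve_model"))
  ext <- rep(model$apex_extension, length(turns))
  hi <- turns > model$buckling_turn_pos
  lo <- turns < model$buckling_turn_neg
  ext[hi] <- model$apex_extension +
    model$slope_pos * (turns[hi] - model$buckling_turn_pos)
  ext[lo] <- model$apex_extension +
    model$slope_neg * (turns[lo] - model$buckling_turn_neg)
  pmax(ext, 0)
}

#' Loading extension as a percentage of full tether length
#'
#' @param load_extension Extension(s) at protein loading, um.
#' @param full_length Full extension of the tether, um.
#' @return Percentage(s), rounded to integer percent.
#' @examples
#' percent_extension(c(8, 10), 16.4) # 49, 61
#' @export
percent_extension <- function(load_extension, full_length) {
  if (full_length <= 0) abort("full_length must be positive")
  round(100 * load_extension / full_length)
}
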