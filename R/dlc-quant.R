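# D-loop capture (DLC) quantification from qPCR crossing points.
#
# The assay cross-links nascent D-loops in vivo, digests and ligates the
# chromatin, and quantifies the resulting chimeric amplicon relative to an
# intramolecular ligation control. Template content follows the standard
# exponential amplification law: content = efficiency^(-Cp).

#' Template content from a qPCR crossing point
#'
#' @param eff Amplification efficiency, fold/cycle in (1, 2].
#' @param cp Crossing point, cycles (> 0).
#' @return Relative template content `eff^(-cp)`.
#' @examples
#' dlc_content(2, 10) # 2^-10
#' @export
dlc_content <- function(eff, cp) {
  if (any(eff <= 1) || any(eff > 2)) {
    abort("amplification efficiency must lie in (1, 2]")
  }
  if (any(cp <= 0)) abort("crossing points must be positive")
  eff^(-cp)
}

#' Per-sample DLC signal from a qPCR table
#'
#' Computes the chimera and ligation-control contents and their ratio for
#' each row. With equal channel efficiencies the signal is invariant to
#' any common shift of both crossing points.
#'
#' @param measurements A data frame with columns `eff_dlc`, `cp_dlc`,
#'   `eff_lig`, `cp_lig` (plus any grouping columns such as `strain`,
#'   `replicate`, which are carried through).
#' @return The input tibble with `dlc_content`, `ligation_content` and
#'   `signal` columns appended.
#' @export
dlc_signal <- function(measurements) {
  .check_cols(measurements, c("eff_dlc", "cp_dlc", "eff_lig", "cp_lig"),
              "DLC table")
  tibble::as_tibble(measurements) |>
    dplyr::mutate(
      dlc_content = dlc_content(.data$eff_dlc, .data$cp_dlc),
      ligation_content = dlc_content(.data$eff_lig, .data$cp_lig),
      signal = .data$dlc_content / .data$ligation_content)
}

#' Strain-level DLC capture-efficiency summary
#'
#' Per-strain mean signal, standard error of the mean (>= 3 replicates
#' required), and the fold-reduction relative to a reference strain
#' (reference mean / strain mean, so the reference itself is 1).
#'
#' @param signals A tibble from [dlc_signal()] with a `strain` column.
#' @param reference Name of the reference strain (default `"WT"`).
#' @return A tibble with `strain`, `n`, `mean_signal`, `sem_signal`,
#'   `fold_vs_reference`.
#' @export
dlc_strain_summary <- function(signals, reference = "WT") {
  .check_cols(signals, c("strain", "signal"), "DLC signal table")
  if (!reference %in% signals$strain) {
    abort(sprintf("reference strain '%s' not present in the table", reference))
  }
  counts <- table(signals$strain)
  short <- names(counts)[counts < 3]
  if (length(short) > 0) {
    abort(sprintf("SEM requires >= 3 replicates per strain; too few for: %s (n = %s)",
                  paste(short, collapse = ", "),
                  paste(counts[short], collapse = ", ")))
  }
  summ <- signals |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_signal = mean(.data$signal),
                     sem_signal = sd(.data$signal) / sqrt(dplyr::n()),
                     .groups = "drop")
  ref_mean <- summ$mean_signal[summ$strain == reference]
  dplyr::mutate(summ, fold_vs_reference = ref_mean / .data$mean_signal)
}
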