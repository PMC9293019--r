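# Physical constants (CODATA 2018); energies in kcal/mol throughout.
.kB_J_per_K <- 1.380649e-23
.h_J_s <- 6.62607015e-34
.R_kcal <- 1.987204e-3 # kcal mol^-1 K^-1

#' Gas constant in kcal/(mol K)
#'
#' Exposed so that downstream scripts use the same value of R as the package
#' internals when converting between energies and ratios.
#'
#' @return The molar gas constant in kcal mol^-1 K^-1.
#' @export
gas_constant_kcal <- function() .R_kcal

.check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single finite value > 0 (kelvin).",
          class = "enaminekin_invalid_parameter")
  }
  temperature
}

#' Transition-state-theory (Eyring) rate constant
#'
#' Converts an activation free energy into a first-order rate constant,
#' \eqn{k = (k_B T / h) \exp(-\Delta G^\ddagger / RT)}, with a transmission
#' coefficient of 1. For bimolecular steps the same expression is used with a
#' 1 M standard state, so the value is in M^-1 s^-1.
#'
#' @param dg_act Activation free energy in kcal/mol. Vectorised.
#' @param temperature Absolute temperature in kelvin. Default 298.15.
#' @return Rate constant(s) in s^-1 (units of the chosen standard state).
#' @examples
#' eyring_rate(0)        # the TST prefactor, ~6.21e12 s^-1
#' eyring_rate(10)       # ~2.9e5 s^-1
#' @export
eyring_rate <- function(dg_act, temperature = 298.15) {
  .check_temperature(temperature)
  if (!is.numeric(dg_act) || any(!is.finite(dg_act))) {
    abort("`dg_act` must be finite (kcal/mol).",
          class = "enaminekin_invalid_parameter")
  }
  (.kB_J_per_K * temperature / .h_J_s) *
    exp(-dg_act / (.R_kcal * temperature))
}

#' Boltzmann populations of an energy ensemble
#'
#' @param energies Relative energies in kcal/mol (any common zero).
#' @param temperature Kelvin; default 298.15.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' boltzmann_weights(c(0, 0.41))
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  .check_temperature(temperature)
  if (length(energies) == 0L) {
    abort("`energies` must be a non-empty numeric vector.",
          class = "enaminekin_invalid_input")
  }
  if (!is.numeric(energies) || any(!is.finite(energies))) {
    abort("`energies` must be finite (kcal/mol).",
          class = "enaminekin_invalid_input")
  }
  # shift by the minimum for numerical stability before exponentiating
  w <- exp(-(energies - min(energies)) / (.R_kcal * temperature))
  w / sum(w)
}

#' Curtin-Hammett flux ratio between two channels
#'
#' For two reaction channels draining a rapidly pre-equilibrated precursor
#' pool, the product flux ratio depends only on the difference between the
#' two transition-state free energies: ratio = exp(-ddg_act / RT). Used as
#' the analytic oracle that the numerical microkinetic model must reproduce
#' in the fast-interconversion limit.
#'
#' @param ddg_act Transition-state free-energy difference (major - minor),
#'   kcal/mol. Negative values give ratios > 1.
#' @param temperature Kelvin; default 298.15.
#' @return major:minor flux ratio (dimensionless).
#' @examples
#' curtin_hammett_ratio(-1.447)  # ~11.5, i.e. a 92:8 product ratio
#' @export
curtin_hammett_ratio <- function(ddg_act, temperature = 298.15) {
  .check_temperature(temperature)
  if (!is.numeric(ddg_act) || any(!is.finite(ddg_act))) {
    abort("`ddg_act` must be finite (kcal/mol).",
          class = "enaminekin_invalid_parameter")
  }
  exp(-ddg_act / (.R_kcal * temperature))
}

#' Classify an enamine conformer from its marker dihedral
#'
#' Enamine intermediates of densely substituted proline units adopt either a
#' distal conformation (C=C away from the carboxamide, |omega| near 180 deg)
#' or a proximal one (|omega| near 0 deg). The classifier splits at
#' |omega| = 90 deg, assigning the boundary to distal.
#'
#' @param omega Dihedral angle(s) in degrees; any real value is reduced to
#'   an absolute angle in \[0, 180\].
#' @return Character vector, "distal" or "proximal".
#' @examples
#' classify_conformer(c(178, -175, 12, 90))
#' @export
classify_conformer <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega))) {
    abort("`omega` must be finite (degrees).",
          class = "enaminekin_invalid_input")
  }
  # fold to [0, 180]
  a <- abs(((omega + 180) %% 360) - 180)
  ifelse(a >= 90, "distal", "proximal")
}

#' Boltzmann population split of a conformer ensemble
#'
#' Classifies every ensemble member as distal or proximal from its marker
#' dihedral and sums Boltzmann weights per class - the population
#' post-analysis applied to a conformational-search ensemble.
#'
#' @param ensemble Data frame with columns `omega` (degrees) and `energy`
#'   (kcal/mol, any common zero).
#' @param temperature Kelvin; default 298.15.
#' @return A tibble with columns `conformer`, `n`, `weight` (weights sum
#'   to 1).
#' @export
conformer_populations <- function(ensemble, temperature = 298.15) {
  df <- as_tibble(ensemble)
  stopifnot(all(c("omega", "energy") %in% names(df)))
  df$conformer <- classify_conformer(df$omega)
  df$weight <- boltzmann_weights(df$energy, temperature)
  dplyr::summarise(dplyr::group_by(df, .data$conformer),
                   n = dplyr::n(), weight = sum(.data$weight),
                   .groups = "drop")
}
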