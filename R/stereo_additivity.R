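# Additive enantiocontrol model for dimeric catalysts: each NH pyrrolidine
# unit contributes the ee of its monomer, a D-configured unit contributes the
# mirrored (negated) value of its L form, and the dimer's expected ee is the
# weighted mean of the two contributions. N-methylated units form no enamine
# and transfer all enantiocontrol to the remaining NH site.

#' Mirror an enantiomeric excess
#'
#' A D-configured catalyst unit directs the enantiomeric product of its L
#' form, so its contribution is the negated monomer ee.
#'
#' @param ee Enantiomeric excess in percent, |ee| <= 100.
#' @return -ee.
#' @export
mirror_ee <- function(ee) {
  if (!is.numeric(ee) || any(!is.finite(ee)) || any(abs(ee) > 100)) {
    abort("`ee` must be a percentage in [-100, 100].",
          class = "enaminekin_invalid_parameter")
  }
  -ee
}

#' Describe one pyrrolidine unit of a dimeric catalyst
#'
#' @param diastereo "exo" or "endo" (X or N in the shorthand naming).
#' @param config Absolute configuration, "L" or "D".
#' @param nitrogen "NH" (enamine-forming) or "NMe" (blocked; contributes only
#'   electrophile activation).
#' @param monomer_ee The ee (percent) delivered by the unit's monomeric L/NH
#'   form; required for NH units, ignored for NMe units.
#' @return A list of class `catalyst_unit`.
#' @export
catalyst_unit <- function(diastereo = c("exo", "endo"), config = c("L", "D"),
                          nitrogen = c("NH", "NMe"), monomer_ee = NULL) {
  diastereo <- match.arg(diastereo)
  config <- match.arg(config)
  nitrogen <- match.arg(nitrogen)
  if (nitrogen == "NH") {
    if (is.null(monomer_ee)) {
      abort("an NH unit needs `monomer_ee` (the ee of its monomeric L form).",
            class = "enaminekin_invalid_parameter")
    }
    if (!is.numeric(monomer_ee) || !is.finite(monomer_ee) ||
        abs(monomer_ee) > 100) {
      abort("`monomer_ee` must be a percentage in [-100, 100].",
            class = "enaminekin_invalid_parameter")
    }
  } else {
    monomer_ee <- NA_real_
  }
  structure(list(diastereo = diastereo, config = config, nitrogen = nitrogen,
                 monomer_ee = monomer_ee),
            class = "catalyst_unit")
}

#' The ee contribution of a single catalyst unit
#'
#' Applies the L/D mirror rule to the unit's monomer ee. NA for NMe units.
#'
#' @param unit A [catalyst_unit()].
#' @return ee contribution in percent.
#' @export
unit_ee <- function(unit) {
  stopifnot(inherits(unit, "catalyst_unit"))
  if (unit$nitrogen == "NMe") return(NA_real_)
  if (unit$config == "D") mirror_ee(unit$monomer_ee) else unit$monomer_ee
}

#' Describe a dimeric catalyst
#'
#' @param unit_a,unit_b [catalyst_unit()] descriptors for the first (A) and
#'   second (B) pyrrolidine units.
#' @param weights Non-negative cycle weights (w_A, w_B) summing to 1; the
#'   50:50 default can be refined with a microkinetics-derived A:B partition.
#' @return A list of class `dimer_descriptor`.
#' @export
dimer <- function(unit_a, unit_b, weights = c(0.5, 0.5)) {
  stopifnot(inherits(unit_a, "catalyst_unit"),
            inherits(unit_b, "catalyst_unit"))
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be two non-negative numbers summing to 1.",
          class = "enaminekin_invalid_parameter")
  }
  structure(list(unit_a = unit_a, unit_b = unit_b, weights = weights),
            class = "dimer_descriptor")
}

#' Predicted (additive) ee of a dimeric catalyst
#'
#' ee_av = w_A ee_A + w_B ee_B, where each unit's contribution is its monomer
#' ee after L/D mirroring. When one unit is N-methylated the whole weight
#' goes to the remaining NH unit; two NMe units leave no active site.
#'
#' @param dm A [dimer()] descriptor.
#' @return Predicted ee in percent.
#' @export
additive_ee <- function(dm) {
  stopifnot(inherits(dm, "dimer_descriptor"))
  nh <- c(dm$unit_a$nitrogen == "NH", dm$unit_b$nitrogen == "NH")
  if (!any(nh)) {
    abort("both units are N-methylated: the dimer has no enamine-forming site.",
          class = "enaminekin_no_active_site")
  }
  w <- dm$weights
  if (!all(nh)) w <- as.numeric(nh) # all weight to the NH unit
  ees <- c(unit_ee(dm$unit_a), unit_ee(dm$unit_b))
  ees[is.na(ees)] <- 0
  sum(w * ees)
}

#' Matched/mismatched classification of a dimer
#'
#' A dimer is matched when both (mirrored) unit contributions direct the same
#' product enantiomer, i.e. their signs agree, and mismatched otherwise.
#'
#' @param dm A [dimer()] descriptor with two NH units.
#' @return "matched" or "mismatched".
#' @export
classify_matching <- function(dm) {
  stopifnot(inherits(dm, "dimer_descriptor"))
  if (dm$unit_a$nitrogen != "NH" || dm$unit_b$nitrogen != "NH") {
    abort("matching is defined for dimers with two NH units.",
          class = "enaminekin_invalid_parameter")
  }
  a <- unit_ee(dm$unit_a)
  b <- unit_ee(dm$unit_b)
  if (sign(a) != 0 && sign(a) == sign(b)) "matched" else "mismatched"
}

#' Predict additive ee for a table of dimers
#'
#' Data-frame interface to the additivity model: one row per dimer, columns
#' `diastereo_a`, `config_a`, `diastereo_b`, `config_b` and optionally
#' `nitrogen_a`, `nitrogen_b` (default "NH") and `w_a` (default 0.5).
#'
#' @param data The dimer table.
#' @param monomer_ees Named vector giving the monomer ee (percent) of the
#'   L/NH form per diastereomer, e.g. `c(exo = 89, endo = -81)`.
#' @return `data` with added columns `ee_av` and (for NH/NH rows) `matching`.
#' @export
predict_dimer_ee <- function(data, monomer_ees = c(exo = 89, endo = -81)) {
  df <- as_tibble(data)
  if (!"nitrogen_a" %in% names(df)) df$nitrogen_a <- "NH"
  if (!"nitrogen_b" %in% names(df)) df$nitrogen_b <- "NH"
  if (!"w_a" %in% names(df)) df$w_a <- 0.5
  res <- purrr::pmap_dfr(
    df[, c("diastereo_a", "config_a", "nitrogen_a",
           "diastereo_b", "config_b", "nitrogen_b", "w_a")],
    function(diastereo_a, config_a, nitrogen_a,
             diastereo_b, config_b, nitrogen_b, w_a) {
      ua <- catalyst_unit(diastereo_a, config_a, nitrogen_a,
                          monomer_ee = unname(monomer_ees[diastereo_a]))
      ub <- catalyst_unit(diastereo_b, config_b, nitrogen_b,
                          monomer_ee = unname(monomer_ees[diastereo_b]))
      dm <- dimer(ua, ub, c(w_a, 1 - w_a))
      both_nh <- nitrogen_a == "NH" && nitrogen_b == "NH"
      tibble(ee_av = additive_ee(dm),
             matching = if (both_nh) classify_matching(dm) else NA_character_)
    })
  dplyr::bind_cols(df, res)
}
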