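#' Unit and reporting policy
#'
#' Bundles the conventions used when numbers leave the package: the flux unit
#' for display and the decimal precision of report tables. Internally all
#' fluxes are held in ug N2O-N m^-2 h^-1 (the unit the cumulative-emission
#' formula expects) and nothing is rounded until a report table is built.
#'
#' @param flux_unit Display unit for fluxes, `"ug_m2_h"` (canonical) or
#'   `"mg_m2_h"` (the unit emission-flux figures conventionally use).
#' @param digits Decimal places for report tables. Default 2.
#' @return A list with class `"unit_policy"`.
#' @examples
#' unit_policy()
#' @export
unit_policy <- function(flux_unit = c("ug_m2_h", "mg_m2_h"), digits = 2) {
  flux_unit <- match.arg(flux_unit)
  if (!is.numeric(digits) || length(digits) != 1 || digits < 0 ||
      digits != as.integer(digits)) {
    abort("`digits` must be a single non-negative integer.",
      class = "nbudget_validation_error")
  }
  structure(list(flux_unit = flux_unit, digits = as.integer(digits)),
    class = "unit_policy")
}

#' Round half away from zero for report tables
#'
#' Commercial rounding (half away from zero), as used in the printed budget
#' tables: 0.005 rounds to 0.01 and -0.005 to -0.01, unlike base [round()]
#' which rounds half to even. Used only when formatting reports; internal
#' computation never rounds.
#'
#' @param x Numeric vector (finite).
#' @param policy A [unit_policy()], or a number of decimal places.
#' @return `x` rounded to the policy's decimal places.
#' @examples
#' round_report(33.3875)  # 33.39
#' round_report(-88.690)  # -88.69
#' @export
round_report <- function(x, policy = unit_policy()) {
  digits <- if (inherits(policy, "unit_policy")) policy$digits else as.integer(policy)
  if (any(!is.finite(x) & !is.na(x))) {
    abort("`x` must be finite.", class = "nbudget_validation_error")
  }
  p <- 10^digits
  # tiny nudge so values that are exact halves in decimal but sit just below
  # one half in binary (e.g. 33.3875 * 100) still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Convert a flux between canonical and display units
#'
#' Conversions are exact powers of ten: 1 mg m^-2 h^-1 = 1000 ug m^-2 h^-1.
#'
#' @param x Numeric flux values.
#' @param from,to Units, `"ug_m2_h"` or `"mg_m2_h"`.
#' @return `x` expressed in `to` units.
#' @examples
#' convert_flux(450, "ug_m2_h", "mg_m2_h")
#' @export
convert_flux <- function(x, from = "ug_m2_h", to = "ug_m2_h") {
  scale <- c(ug_m2_h = 1, mg_m2_h = 1000)
  if (!from %in% names(scale) || !to %in% names(scale)) {
    abort("Flux units must be 'ug_m2_h' or 'mg_m2_h'.",
      class = "nbudget_argument_error")
  }
  x * scale[[from]] / scale[[to]]
}
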