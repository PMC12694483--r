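# Closed static-chamber N2O flux.
#
# A sealed chamber of height H (m) accumulates N2O; the headspace
# concentration (uL/L) is sampled over minutes and its least-squares slope
# dc/dt (uL L^-1 min^-1) gives the soil-to-atmosphere flux
#
#   F = rho * H * dc/dt * 273/(273 + T) * 60
#
# with rho = 2 * 14 / 22.4 = 1.25 kg/m^3, the N2O-N density at standard
# conditions (so fluxes are on an N2O-N mass basis), and T the mean chamber
# air temperature (deg C). The printed product of that formula is
# mg m^-2 h^-1; the package stores fluxes in the canonical ug m^-2 h^-1
# (x 1000), the unit the seasonal integration constant expects.

RHO_N2O_N <- 2 * 14 / 22.4  # kg/m^3 at 0 degC, N2O-N basis

#' Least-squares slope of a chamber concentration series
#'
#' Ordinary least-squares slope of concentration against elapsed minutes,
#' with the fit's r-squared and point count as quality diagnostics. With two
#' points r-squared is 1 by construction; with a constant series the slope is
#' 0 and r-squared is undefined (`NA`).
#'
#' @param minute Sampling times, minutes since chamber closure (>= 2 values,
#'   not all equal).
#' @param conc_ul_l N2O concentrations, uL/L.
#' @return A list with `slope` (uL/L/min), `r_squared`, and `n`.
#' @examples
#' concentration_slope(c(0, 30), c(0.30, 0.60))$slope  # 0.01
#' @export
concentration_slope <- function(minute, conc_ul_l) {
  n <- length(minute)
  if (n < 2 || length(conc_ul_l) != n) {
    abort("Need >= 2 paired (minute, concentration) samples.",
      class = "nbudget_data_error")
  }
  sxx <- sum((minute - mean(minute))^2)
  if (sxx == 0) {
    abort("All sampling minutes are equal; slope is not estimable.",
      class = "nbudget_data_error")
  }
  syy <- sum((conc_ul_l - mean(conc_ul_l))^2)
  sxy <- sum((minute - mean(minute)) * (conc_ul_l - mean(conc_ul_l)))
  slope <- sxy / sxx
  r2 <- if (syy == 0) NA_real_ else if (n == 2) 1 else sxy^2 / (sxx * syy)
  list(slope = slope, r_squared = r2, n = n)
}

#' N2O flux from a chamber slope
#'
#' Applies the static-chamber flux formula to a concentration slope. The
#' temperature term 273/(273 + T) corrects the gas density to chamber
#' temperature; negative slopes give negative fluxes (soil uptake) and are
#' retained.
#'
#' @param slope Concentration slope, uL/L/min.
#' @param height_m Chamber height, m (> 0).
#' @param temp_c Mean chamber air temperature, deg C (> -273).
#' @return Flux in ug N2O-N m^-2 h^-1. Vectorised.
#' @examples
#' chamber_flux_value(0.01, height_m = 0.6, temp_c = 0)  # 450
#' @export
chamber_flux_value <- function(slope, height_m, temp_c) {
  if (any(height_m <= 0, na.rm = TRUE)) {
    abort("`height_m` must be > 0.", class = "nbudget_validation_error")
  }
  if (any(temp_c <= -273, na.rm = TRUE)) {
    abort("`temp_c` must be > -273.", class = "nbudget_domain_error")
  }
  mg <- RHO_N2O_N * height_m * slope * 273 / (273 + temp_c) * 60
  convert_flux(mg, from = "mg_m2_h", to = "ug_m2_h")
}

#' Per-deployment fluxes from a chamber table
#'
#' Fits the concentration slope for every chamber deployment (one plot,
#' date and position) and converts it to a flux. Deployments with >= 3
#' points and r-squared below `r2_flag` are flagged, not dropped: low linear
#' fit quality is exposed for inspection but the flux is still usable.
#'
#' @param chamber A chamber table in the `chamber` schema (see
#'   [read_table()]): rows are individual headspace samples.
#' @param r2_flag Flagging threshold for the slope fit's r-squared.
#'   Default 0.90.
#' @return A flux tibble in the `flux` schema: one row per deployment with
#'   `flux_ug_m2_h`, `r_squared`, `n_points` and a `flagged` column.
#' @export
chamber_fluxes <- function(chamber, r2_flag = 0.90) {
  chamber <- validate_table(chamber, "chamber")
  chamber |>
    dplyr::group_by(.data$year, .data$pattern, .data$n_rate, .data$replicate,
      .data$date, .data$position) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$height_m) > 1 || dplyr::n_distinct(df$temp_c) > 1) {
        abort("Chamber height and temperature must be constant within a deployment.",
          class = "nbudget_data_error")
      }
      fit <- concentration_slope(df$minute, df$conc_ul_l)
      tibble::tibble(
        flux_ug_m2_h = chamber_flux_value(fit$slope, df$height_m[1], df$temp_c[1]),
        r_squared = fit$r_squared,
        n_points = as.integer(fit$n)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = .data$n_points >= 3 &
      (is.na(.data$r_squared) | .data$r_squared < r2_flag))
}

#' Area-weighted plot flux from ridge and furrow chambers
#'
#' Ridge-furrow plots are sampled at both positions; the plot-level flux is
#' the area-weighted average `w_ridge * ridge + (1 - w_ridge) * furrow`.
#' Flat-planted plots pass through unchanged. The weight is the ridge's share
#' of plot surface area.
#'
#' @param flux A flux tibble (schema `flux`), e.g. from [chamber_fluxes()].
#' @param w_ridge Ridge area fraction in `[0, 1]`. Default 0.5.
#' @return A flux tibble with one `position = "plot"` row per plot-date.
#' @export
position_weighted_flux <- function(flux, w_ridge = 0.5) {
  if (!is.numeric(w_ridge) || length(w_ridge) != 1 || w_ridge < 0 || w_ridge > 1) {
    abort("`w_ridge` must be a single number in [0, 1].",
      class = "nbudget_argument_error")
  }
  flux <- validate_table(flux, "flux")
  flux |>
    dplyr::group_by(.data$year, .data$pattern, .data$n_rate, .data$replicate,
      .data$date) |>
    dplyr::group_modify(function(df, key) {
      pos <- sort(df$position)
      if (identical(pos, "flat") || identical(pos, "plot")) {
        out <- df[c("flux_ug_m2_h", "r_squared", "n_points")]
      } else if (identical(pos, c("furrow", "ridge"))) {
        r <- df[df$position == "ridge", ]
        f <- df[df$position == "furrow", ]
        out <- tibble::tibble(
          flux_ug_m2_h = w_ridge * r$flux_ug_m2_h + (1 - w_ridge) * f$flux_ug_m2_h,
          r_squared = min(r$r_squared, f$r_squared),
          n_points = min(r$n_points, f$n_points)
        )
      } else {
        abort(
          sprintf("Cannot pair positions {%s} for a plot-date; expected 'flat' or 'ridge'+'furrow'.",
            paste(pos, collapse = ", ")),
          class = "nbudget_pairing_error"
        )
      }
      out$position <- "plot"
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("position", .after = "date")
}

#' Trapezoidal cumulative emission over one season
#'
#' Integrates dated fluxes between the first and last sampling date:
#' `f = sum((F[i+1] + F[i]) / 2 * t[i] * 24 * 1e-5)` with `F` in
#' ug m^-2 h^-1 and `t[i]` the interval in whole days, giving kg/ha. No
#' extrapolation outside the sampled range.
#'
#' @param date Sampling dates (`Date`), >= 2, distinct.
#' @param flux_ug_m2_h Fluxes, ug N2O-N m^-2 h^-1.
#' @return Seasonal total, kg/ha.
#' @examples
#' cumulative_emission(as.Date("2023-06-01") + c(0, 10), c(50, 50))  # 0.12
#' @export
cumulative_emission <- function(date, flux_ug_m2_h) {
  if (length(date) < 2) {
    abort("Need >= 2 dated fluxes to integrate.", class = "nbudget_data_error")
  }
  if (anyDuplicated(date)) {
    abort("Duplicate sampling dates in one plot-year series.",
      class = "nbudget_data_error")
  }
  o <- order(date)
  f <- flux_ug_m2_h[o]
  t_days <- as.numeric(diff(date[o]), units = "days")
  sum((f[-1] + f[-length(f)]) / 2 * t_days * 24 * 1e-5)
}

#' Seasonal N2O emission totals per plot-year
#'
#' Combines ridge/furrow chamber positions into plot-level fluxes (see
#' [position_weighted_flux()]) and integrates each plot-year's dated series
#' with the trapezoidal rule.
#'
#' @inheritParams position_weighted_flux
#' @return A tibble keyed by `year, pattern, n_rate, replicate` with
#'   `n2o_kg_ha`, the campaign date range, and `n_dates`.
#' @export
season_emissions <- function(flux, w_ridge = 0.5) {
  position_weighted_flux(flux, w_ridge) |>
    dplyr::group_by(.data$year, .data$pattern, .data$n_rate, .data$replicate) |>
    dplyr::summarise(
      n2o_kg_ha = cumulative_emission(.data$date, .data$flux_ug_m2_h),
      first_date = min(.data$date),
      last_date = max(.data$date),
      n_dates = dplyr::n(),
      .groups = "drop"
    )
}
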