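# Soil inorganic nitrogen stocks.
#
# A layer's stock (kg N/ha) is bulk density (g/cm^3) x thickness (cm) x
# concentration (mg N/kg dry soil) / 10; the divisor 10 is the exact unit
# conversion. Profile stocks sum contiguous layers, by default three 20 cm
# layers spanning 0-60 cm.

#' Inorganic nitrogen stock of one soil layer
#'
#' @param bulk_density Bulk density, g/cm^3 (> 0).
#' @param thickness_cm Layer thickness, cm (> 0).
#' @param conc_mg_kg Nitrate-N or ammonium-N concentration, mg/kg (>= 0).
#' @return Stock in kg N/ha. Vectorised.
#' @examples
#' layer_stock(1.45, 20, 10)  # 29 kg/ha
#' @export
layer_stock <- function(bulk_density, thickness_cm, conc_mg_kg) {
  if (any(bulk_density <= 0, na.rm = TRUE)) {
    abort("`bulk_density` must be > 0.", class = "nbudget_validation_error")
  }
  if (any(thickness_cm <= 0, na.rm = TRUE)) {
    abort("`thickness_cm` must be > 0.", class = "nbudget_validation_error")
  }
  if (any(conc_mg_kg < 0, na.rm = TRUE)) {
    abort("`conc_mg_kg` must be >= 0.", class = "nbudget_validation_error")
  }
  bulk_density * thickness_cm * conc_mg_kg / 10
}

check_profile_layers <- function(depth_top, depth_bottom) {
  o <- order(depth_top)
  top <- depth_top[o]
  bottom <- depth_bottom[o]
  if (length(top) > 1 && any(abs(bottom[-length(bottom)] - top[-1]) > 1e-9)) {
    abort("Soil profile layers must be contiguous (no gaps or overlaps).",
      class = "nbudget_profile_error")
  }
  invisible(o)
}

#' Per-profile soil inorganic nitrogen stocks
#'
#' Computes, for every soil profile (one plot on one sampling date), the
#' nitrate-N stock, ammonium-N stock and their sum over the profile's layers.
#' Layers within a profile must be contiguous and non-overlapping.
#'
#' @param soil A soil table in the `soil` schema (see [read_table()]): one row
#'   per layer with `year, pattern, n_rate, replicate, date, depth_top_cm,
#'   depth_bottom_cm, bulk_density_g_cm3, no3_mg_kg, nh4_mg_kg`.
#' @return A tibble with one row per profile and columns `no3_stock_kg_ha`,
#'   `nh4_stock_kg_ha`, `inorganic_n_kg_ha`, plus `depth_top_cm`/
#'   `depth_bottom_cm` giving the covered range.
#' @examples
#' soil <- tibble::tibble(
#'   year = 2023L, pattern = "FP", n_rate = 0, replicate = 1L,
#'   date = as.Date("2023-09-01"),
#'   depth_top_cm = c(0, 20, 40), depth_bottom_cm = c(20, 40, 60),
#'   bulk_density_g_cm3 = 1.45, no3_mg_kg = 10, nh4_mg_kg = 5
#' )
#' soil_stocks(soil)
#' @export
soil_stocks <- function(soil) {
  soil <- validate_table(soil, "soil")
  soil |>
    dplyr::group_by(.data$year, .data$pattern, .data$n_rate, .data$replicate,
      .data$date) |>
    dplyr::group_modify(function(df, key) {
      check_profile_layers(df$depth_top_cm, df$depth_bottom_cm)
      h <- df$depth_bottom_cm - df$depth_top_cm
      tibble::tibble(
        depth_top_cm = min(df$depth_top_cm),
        depth_bottom_cm = max(df$depth_bottom_cm),
        no3_stock_kg_ha = sum(layer_stock(df$bulk_density_g_cm3, h, df$no3_mg_kg)),
        nh4_stock_kg_ha = sum(layer_stock(df$bulk_density_g_cm3, h, df$nh4_mg_kg))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(inorganic_n_kg_ha = .data$no3_stock_kg_ha + .data$nh4_stock_kg_ha)
}

#' Total inorganic nitrogen reserve of one profile
#'
#' Convenience wrapper for a single profile given as vectors: the sum of the
#' nitrate and ammonium stocks over its layers.
#'
#' @inheritParams layer_stock
#' @param depth_top_cm,depth_bottom_cm Layer bounds, cm; layers must be
#'   contiguous.
#' @param no3_mg_kg,nh4_mg_kg Concentrations per layer, mg/kg.
#' @return Total inorganic N, kg/ha.
#' @export
inorganic_n_reserve <- function(depth_top_cm, depth_bottom_cm, bulk_density,
                                no3_mg_kg, nh4_mg_kg) {
  check_profile_layers(depth_top_cm, depth_bottom_cm)
  h <- depth_bottom_cm - depth_top_cm
  sum(layer_stock(bulk_density, h, no3_mg_kg)) +
    sum(layer_stock(bulk_density, h, nh4_mg_kg))
}
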