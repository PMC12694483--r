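# Plant nitrogen accumulation: organ N content (% of dry matter) times organ
# dry matter yield, summed over leaves and stems and then over cuts.

#' Nitrogen accumulation of one plant organ
#'
#' @param n_pct Nitrogen content, percent of dry matter (0-100).
#' @param dm_kg_ha Dry matter yield, kg/ha (>= 0).
#' @return N accumulation, kg N/ha. Vectorised.
#' @examples
#' organ_accumulation(3, 2000)  # 60 kg N/ha
#' @export
organ_accumulation <- function(n_pct, dm_kg_ha) {
  if (any(n_pct < 0 | n_pct > 100, na.rm = TRUE)) {
    abort("`n_pct` must be in [0, 100].", class = "nbudget_validation_error")
  }
  if (any(dm_kg_ha < 0, na.rm = TRUE)) {
    abort("`dm_kg_ha` must be >= 0.", class = "nbudget_validation_error")
  }
  n_pct / 100 * dm_kg_ha
}

#' Whole-plant nitrogen accumulation per cut sample
#'
#' Adds a `plant_n_kg_ha` column: leaf accumulation plus stem accumulation
#' for each per-cut sample row.
#'
#' @param plant A plant table in the `plant` schema (see [read_table()]).
#' @return The input tibble with `plant_n_kg_ha` and `dm_kg_ha` columns added.
#' @export
plant_accumulation <- function(plant) {
  plant <- validate_table(plant, "plant")
  plant |>
    dplyr::mutate(
      plant_n_kg_ha = organ_accumulation(.data$leaf_n_pct, .data$leaf_dm_kg_ha) +
        organ_accumulation(.data$stem_n_pct, .data$stem_dm_kg_ha),
      dm_kg_ha = .data$leaf_dm_kg_ha + .data$stem_dm_kg_ha
    )
}

#' Seasonal plant nitrogen and hay-yield summary
#'
#' Sums nitrogen accumulation and dry matter over cuts for each plot-year.
#' Cut indices must be distinct within a plot-year; the result is invariant
#' to the order of the input rows.
#'
#' @inheritParams plant_accumulation
#' @return A tibble keyed by `year, pattern, n_rate, replicate` with
#'   `plant_n_kg_ha` (kg N/ha, summed over cuts), `hay_yield_kg_ha` and
#'   `hay_yield_t_ha` (the reporting unit), and `n_cuts`.
#' @examples
#' plant <- tibble::tibble(
#'   year = 2023L, pattern = "PM", n_rate = 160, replicate = 1L,
#'   cut = 1:3, date = as.Date("2023-06-05") + c(0, 40, 80),
#'   leaf_n_pct = 3, stem_n_pct = 1.5,
#'   leaf_dm_kg_ha = 2000, stem_dm_kg_ha = 3000
#' )
#' season_summary(plant)
#' @export
season_summary <- function(plant) {
  acc <- plant_accumulation(plant)
  dup <- acc |>
    dplyr::count(.data$year, .data$pattern, .data$n_rate, .data$replicate,
      .data$cut) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(
      sprintf("Duplicate cut index within a plot-year (%d case(s), e.g. %s %s rate %g rep %d cut %d).",
        nrow(dup), dup$year[1], dup$pattern[1], dup$n_rate[1],
        dup$replicate[1], dup$cut[1]),
      class = "nbudget_data_error"
    )
  }
  acc |>
    dplyr::group_by(.data$year, .data$pattern, .data$n_rate, .data$replicate) |>
    dplyr::summarise(
      plant_n_kg_ha = sum(.data$plant_n_kg_ha),
      hay_yield_kg_ha = sum(.data$dm_kg_ha),
      n_cuts = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(hay_yield_t_ha = .data$hay_yield_kg_ha / 1000)
}
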