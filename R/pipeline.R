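# End-to-end orchestration: simulate (or load) -> soil stocks -> plant
# summary -> chamber fluxes -> seasonal emissions -> nitrogen budget ->
# treatment statistics -> report files. Each stage reads and writes only the
# declared CSV schemas, so running the stages by hand gives the same outputs
# as run_pipeline().

#' Pipeline configuration
#'
#' Collects the run parameters: where to write, the synthetic design (or
#' paths of existing input tables), the ridge area weight, balance
#' classification thresholds, significance level, and the reporting policy.
#'
#' @param out_dir Output directory for the report bundle.
#' @param design A [synthetic_design()] used when no input paths are given.
#' @param inputs Optional named list with paths `soil`, `plant`, `chamber`
#'   to existing CSV tables; when supplied the generator is not used.
#' @param w_ridge Ridge area fraction for plot-level fluxes.
#' @param thresholds Balance classification band, kg/ha.
#' @param alpha Significance level for the ANOVA and LSD display.
#' @param policy A [unit_policy()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, design = synthetic_design(),
                            inputs = NULL, w_ridge = 0.5,
                            thresholds = c(-20, 20), alpha = 0.05,
                            policy = unit_policy()) {
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).", class = "nbudget_validation_error")
  }
  if (!is.null(inputs)) {
    need <- c("soil", "plant", "chamber")
    if (!all(need %in% names(inputs))) {
      abort("`inputs` must name soil, plant and chamber CSV paths.",
        class = "nbudget_validation_error")
    }
    gone <- need[!vapply(inputs[need], file.exists, logical(1))]
    if (length(gone) > 0) {
      abort(sprintf("Input file(s) missing: %s.",
        paste(unlist(inputs[gone]), collapse = ", ")),
        class = "nbudget_io_error")
    }
  }
  structure(
    list(out_dir = out_dir, design = design, inputs = inputs,
      w_ridge = w_ridge, thresholds = thresholds, alpha = alpha,
      policy = policy),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()]; `design` keys are passed to [synthetic_design()].
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- do.call(synthetic_design, cfg$design %||% list())
  pipeline_config(
    out_dir = cfg$out_dir %||% ".",
    design = design,
    inputs = cfg$inputs,
    w_ridge = cfg$w_ridge %||% 0.5,
    thresholds = unlist(cfg$thresholds %||% c(-20, 20)),
    alpha = cfg$alpha %||% 0.05,
    policy = unit_policy(digits = cfg$digits %||% 2)
  )
}

#' Run the full nitrogen-budget pipeline
#'
#' Executes every stage in order and writes the report bundle to the
#' configured directory: `soil_stocks.csv`, `plant_summary.csv`, `flux.csv`,
#' `emissions.csv`, `budget_report.csv` (the budget-table layout),
#' `anova_report.csv`, `letters.csv` and `run_log.txt`. Idempotent: the same
#' configuration writes identical files.
#'
#' Budget components are formed per treatment-year from replicate means:
#' pre-season profile inorganic N is the initial term, the end-of-season
#' profile the residue, seasonal plant N the uptake term and the trapezoid
#' emission total the atmosphere term. The ANOVA analyses plant N
#' accumulation against rate, pattern and year; the LSD letters compare
#' pattern means.
#'
#' @param config A [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @return Invisibly, a list with every stage's tibble (`soil_stocks`,
#'   `plant_summary`, `flux`, `emissions`, `budget`, `anova`, `letters`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a YAML path.",
      class = "nbudget_argument_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  if (is.null(config$inputs)) {
    sim <- simulate_trial(config$design, out_dir = config$out_dir)
    soil <- sim$soil; plant <- sim$plant; chamber <- sim$chamber
  } else {
    soil <- read_table(config$inputs$soil, "soil")
    plant <- read_table(config$inputs$plant, "plant")
    chamber <- read_table(config$inputs$chamber, "chamber")
  }

  stocks <- soil_stocks(soil)
  plant_sum <- season_summary(plant)
  flux <- chamber_fluxes(chamber)
  emissions <- season_emissions(flux, w_ridge = config$w_ridge)

  # spring profile = initial term, fall profile = residue
  soil_terms <- stocks |>
    dplyr::group_by(.data$year, .data$pattern, .data$n_rate, .data$replicate) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      initial_soil_n = dplyr::first(.data$inorganic_n_kg_ha),
      soil_residue = dplyr::last(.data$inorganic_n_kg_ha),
      .groups = "drop"
    )
  components <- soil_terms |>
    dplyr::inner_join(
      dplyr::select(plant_sum, "year", "pattern", "n_rate", "replicate",
        plant_accumulation = "plant_n_kg_ha"),
      by = c("year", "pattern", "n_rate", "replicate")
    ) |>
    dplyr::inner_join(
      dplyr::select(emissions, "year", "pattern", "n_rate", "replicate",
        n2o_emission = "n2o_kg_ha"),
      by = c("year", "pattern", "n_rate", "replicate")
    )
  budget <- nitrogen_budget(components, thresholds = config$thresholds)

  stats_data <- dplyr::select(plant_sum, "year", "pattern", "n_rate",
    "replicate", "plant_n_kg_ha")
  fit <- anova_factorial(stats_data, "plant_n_kg_ha",
    c("n_rate", "pattern", "year"))
  prechecks <- precheck_assumptions(stats_data, "plant_n_kg_ha",
    c("n_rate", "pattern", "year"))
  pattern_means <- stats_data |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(m = mean(.data$plant_n_kg_ha), n = dplyr::n(),
      .groups = "drop")
  omnibus_p <- fit$table$p.value[fit$table$term == "pattern"]
  letters <- lsd_groups(
    setNames(pattern_means$m, pattern_means$pattern),
    mse = fit$mse, df_error = fit$df_error, n = pattern_means$n[1],
    alpha = config$alpha, omnibus_p = omnibus_p
  )

  readr::write_csv(stocks, p("soil_stocks.csv"), progress = FALSE)
  readr::write_csv(plant_sum, p("plant_summary.csv"), progress = FALSE)
  write_table(flux, p("flux.csv"), "flux")
  readr::write_csv(emissions, p("emissions.csv"), progress = FALSE)
  readr::write_csv(budget_table(budget, config$policy), p("budget_report.csv"),
    progress = FALSE)
  readr::write_csv(tidy(fit), p("anova_report.csv"), progress = FALSE)
  readr::write_csv(prechecks, p("precheck_report.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(letters), p("letters.csv"),
    progress = FALSE)
  writeLines(c(
    sprintf("nbudget %s", as.character(utils::packageVersion("nbudget"))),
    sprintf("R %s", getRversion()),
    sprintf("seed: %d", config$design$seed),
    sprintf("w_ridge: %g", config$w_ridge),
    sprintf("thresholds: [%g, %g]", config$thresholds[1], config$thresholds[2]),
    sprintf("alpha: %g", config$alpha),
    sprintf("inputs: %s",
      if (is.null(config$inputs)) "synthetic" else "user-supplied")
  ), p("run_log.txt"))

  invisible(list(
    soil_stocks = stocks, plant_summary = plant_sum, flux = flux,
    emissions = emissions, budget = budget, anova = fit,
    prechecks = prechecks, letters = letters
  ))
}

#' Worked-example budget component table
#'
#' Loads the packaged 24-row component table of a published two-year
#' mulched ridge-furrow alfalfa trial (12 treatments x 2 years): nitrogen
#' rate, pre-season and end-of-season soil inorganic N, plant N
#' accumulation and seasonal N2O emission, together with the originally
#' reported balance and loss-rate columns for regression comparison.
#'
#' @return A tibble with the `budget` schema columns plus
#'   `published_balance` and `published_anlr` (the latter `NA` for
#'   unfertilized treatments).
#' @examples
#' head(trial_budget_components())
#' @export
trial_budget_components <- function() {
  path <- system.file("extdata", "budget_components_trial.csv",
    package = "nbudget", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), pattern = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
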