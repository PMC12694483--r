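# Apparent nitrogen balance of the plant-soil-atmosphere system.
#
# Inputs: fertilizer N plus pre-season soil inorganic N (0-60 cm).
# Outputs: end-of-season soil inorganic N, plant N accumulation, and seasonal
# N2O emission. Balance = input - output; the apparent nitrogen loss rate
# (ANLR) expresses the balance as a percentage of the fertilizer rate and is
# undefined for unfertilized treatments. Biological N fixation, leaching and
# NH3 volatilization are not part of the ledger (see the methods vignette's
# limitations), which is why the balance is "apparent".

#' Assemble per-treatment-year nitrogen budgets
#'
#' Builds the nitrogen ledger from its components. If the component table
#' carries a `replicate` column, replicate means are taken first (one budget
#' per treatment-year, as budget tables are conventionally reported). The
#' ledger identities hold exactly: `n_input = n_rate + initial_soil_n`,
#' `n_output = soil_residue + plant_accumulation + n2o_emission`,
#' `balance = n_input - n_output`, and `anlr = balance / n_rate * 100` when
#' `n_rate > 0` (`NA` otherwise). Nothing is rounded.
#'
#' @param components A data frame in the `budget` schema (see
#'   [read_table()]): `year, pattern, n_rate, initial_soil_n, soil_residue,
#'   plant_accumulation, n2o_emission`, all in kg/ha, optionally with a
#'   `replicate` column.
#' @param thresholds Length-2 numeric `(low, high)` in kg/ha classifying the
#'   balance: below `low` is `"deficit"`, above `high` is `"surplus"`, else
#'   `"near_equilibrium"`. Default `c(-20, 20)`.
#' @return A tibble of class `"nitrogen_budget"` with the component columns
#'   plus `n_input`, `n_output`, `balance`, `anlr`, and `balance_class`.
#' @examples
#' nitrogen_budget(tibble::tibble(
#'   year = 2023L, pattern = "PM", n_rate = 160, initial_soil_n = 48.6,
#'   soil_residue = 48.7, plant_accumulation = 148.03, n2o_emission = 2.14
#' ))
#' @export
nitrogen_budget <- function(components, thresholds = c(-20, 20)) {
  if (length(thresholds) != 2 || !is.numeric(thresholds) ||
      thresholds[1] >= thresholds[2]) {
    abort("`thresholds` must be numeric (low, high) with low < high.",
      class = "nbudget_argument_error")
  }
  components <- validate_table(components, "budget")
  if ("replicate" %in% names(components)) {
    components <- components |>
      dplyr::group_by(.data$year, .data$pattern, .data$n_rate) |>
      dplyr::summarise(dplyr::across(
        c("initial_soil_n", "soil_residue", "plant_accumulation", "n2o_emission"),
        mean
      ), .groups = "drop")
  }
  dup <- dplyr::count(components, .data$year, .data$pattern, .data$n_rate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("More than one component row per (year, pattern, n_rate); supply a `replicate` column to average.",
      class = "nbudget_data_error")
  }
  out <- components |>
    dplyr::mutate(
      label = treatment_label(.data$pattern, .data$n_rate),
      n_input = .data$n_rate + .data$initial_soil_n,
      n_output = .data$soil_residue + .data$plant_accumulation + .data$n2o_emission,
      balance = .data$n_input - .data$n_output,
      anlr = dplyr::if_else(.data$n_rate > 0,
        .data$balance / .data$n_rate * 100, NA_real_),
      balance_class = classify_balance(.data$balance, thresholds)
    ) |>
    dplyr::arrange(.data$pattern, .data$n_rate, .data$year)
  structure(out, class = c("nitrogen_budget", class(out)),
    thresholds = thresholds)
}

#' Classify an apparent nitrogen balance
#'
#' @param balance Numeric balances, kg/ha.
#' @param thresholds `(low, high)` kg/ha; see [nitrogen_budget()].
#' @return Factor with levels `deficit`, `near_equilibrium`, `surplus`.
#' @examples
#' classify_balance(c(-88.69, 9.73, 150.09))
#' @export
classify_balance <- function(balance, thresholds = c(-20, 20)) {
  if (thresholds[1] >= thresholds[2]) {
    abort("`thresholds` must satisfy low < high.", class = "nbudget_argument_error")
  }
  factor(
    dplyr::case_when(
      balance < thresholds[1] ~ "deficit",
      balance > thresholds[2] ~ "surplus",
      TRUE ~ "near_equilibrium"
    ),
    levels = c("deficit", "near_equilibrium", "surplus")
  )
}

#' Format a nitrogen budget as a report table
#'
#' Rounds to the policy's precision (half away from zero) and renders the
#' undefined zero-rate ANLR cells as an em dash, mirroring how budget tables
#' are printed in the field's literature.
#'
#' @param budget A `"nitrogen_budget"` from [nitrogen_budget()].
#' @param policy A [unit_policy()].
#' @return A tibble with character `anlr`; numeric columns rounded.
#' @export
budget_table <- function(budget, policy = unit_policy()) {
  if (!inherits(budget, "nitrogen_budget")) {
    abort("`budget` must be a nitrogen_budget object.",
      class = "nbudget_argument_error")
  }
  budget |>
    tibble::as_tibble() |>
    dplyr::mutate(
      dplyr::across(
        c("initial_soil_n", "soil_residue", "plant_accumulation",
          "n2o_emission", "n_input", "n_output", "balance"),
        ~ round_report(.x, policy)
      ),
      anlr = dplyr::if_else(is.na(.data$anlr), "—",
        formatC(round_report(.data$anlr, policy),
          format = "f", digits = policy$digits))
    ) |>
    dplyr::select("label", "pattern", "n_rate", "year", "initial_soil_n",
      "soil_residue", "plant_accumulation", "n2o_emission", "n_input",
      "n_output", "balance", "anlr", "balance_class")
}

#' @export
#' @method tidy nitrogen_budget
#' @rdname nitrogen_budget_methods
#' @param x A `"nitrogen_budget"` object.
#' @param ... Unused.
tidy.nitrogen_budget <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary methods for nitrogen budgets
#'
#' `tidy()` returns the budget as a plain tibble; `glance()` gives a one-row
#' overview (treatment-year count, balance range, class counts).
#'
#' @name nitrogen_budget_methods
#' @export
#' @method glance nitrogen_budget
glance.nitrogen_budget <- function(x, ...) {
  tibble::tibble(
    n_budgets = nrow(x),
    n_years = dplyr::n_distinct(x$year),
    mean_balance = mean(x$balance),
    min_balance = min(x$balance),
    max_balance = max(x$balance),
    n_deficit = sum(x$balance_class == "deficit"),
    n_near_equilibrium = sum(x$balance_class == "near_equilibrium"),
    n_surplus = sum(x$balance_class == "surplus")
  )
}

#' @export
print.nitrogen_budget <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf(
    "# Nitrogen budget: %d treatment-year(s); near-equilibrium band [%g, %g] kg/ha\n",
    nrow(x), thr[1], thr[2]))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
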