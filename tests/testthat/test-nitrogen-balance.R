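budget_row <- function(n_rate, initial, residue, plant, n2o,
                       pattern = "FP", year = 2023L) {
  tibble::tibble(
    year = year, pattern = pattern, n_rate = n_rate,
    initial_soil_n = initial, soil_residue = residue,
    plant_accumulation = plant, n2o_emission = n2o
  )
}

test_that("ledger reproduces worked treatment-year examples", {
  b <- nitrogen_budget(budget_row(0, 40.03, 36.5, 91.01, 1.21))
  expect_equal(b$balance, -88.69)
  expect_true(is.na(b$anlr))

  b2 <- nitrogen_budget(budget_row(160, 48.6, 48.7, 148.03, 2.14, "PM"))
  expect_equal(b2$balance, 9.73)
  expect_equal(round_report(b2$anlr), 6.08)

  b3 <- nitrogen_budget(budget_row(160, 47.6, 38.8, 113.57, 1.81))
  expect_equal(round_report(b3$anlr), 33.39)

  zero <- nitrogen_budget(budget_row(100, 50, 30, 118, 2))
  expect_equal(zero$balance, 0)
})

test_that("ledger identities hold exactly on randomized components", {
  withr::local_seed(17)
  for (i in 1:50) {
    comp <- budget_row(
      n_rate = sample(c(0, 80, 160, 240), 1),
      initial = stats::runif(1, 20, 90), residue = stats::runif(1, 20, 90),
      plant = stats::runif(1, 60, 180), n2o = stats::runif(1, 0.5, 3.5)
    )
    b <- nitrogen_budget(comp)
    expect_identical(b$n_input, b$n_rate + b$initial_soil_n)
    expect_identical(b$n_output,
      b$soil_residue + b$plant_accumulation + b$n2o_emission)
    expect_identical(b$n_input - b$n_output - b$balance, 0)
    if (b$n_rate > 0) {
      # ANLR inverts back to the balance before any rounding
      expect_equal(b$anlr * b$n_rate / 100, b$balance)
    }
  }
})

test_that("balance is monotone in inputs and outputs", {
  base <- nitrogen_budget(budget_row(160, 50, 40, 120, 2))$balance
  expect_gt(nitrogen_budget(budget_row(240, 50, 40, 120, 2))$balance, base)
  expect_lt(nitrogen_budget(budget_row(160, 50, 45, 120, 2))$balance, base)
  expect_lt(nitrogen_budget(budget_row(160, 50, 40, 130, 2))$balance, base)
  expect_lt(nitrogen_budget(budget_row(160, 50, 40, 120, 3))$balance, base)
})

test_that("replicate-level components are averaged before the ledger", {
  comp <- dplyr::bind_rows(
    dplyr::mutate(budget_row(160, 40, 30, 100, 2), replicate = 1L),
    dplyr::mutate(budget_row(160, 60, 50, 120, 3), replicate = 2L)
  )
  b <- nitrogen_budget(comp)
  expect_equal(nrow(b), 1)
  expect_equal(b$initial_soil_n, 50)
  expect_equal(b$balance, (160 + 50) - (40 + 110 + 2.5))

  no_rep <- dplyr::select(comp, -"replicate")
  expect_error(nitrogen_budget(no_rep), class = "nbudget_data_error")
  expect_error(nitrogen_budget(dplyr::mutate(budget_row(160, 50, 40, 120, 2),
    plant_accumulation = -1)), class = "nbudget_validation_error")
})

test_that("balance classification follows the configured band", {
  expect_equal(as.character(classify_balance(c(-88.69, 9.73, 150.09))),
    c("deficit", "near_equilibrium", "surplus"))
  expect_equal(as.character(classify_balance(0, c(-1, 1))), "near_equilibrium")
  expect_equal(as.character(classify_balance(25, c(-30, 30))), "near_equilibrium")
  expect_error(classify_balance(0, c(5, -5)), class = "nbudget_argument_error")
})

test_that("the published two-year component table is reproduced within 0.01", {
  comp <- trial_budget_components()
  b <- nitrogen_budget(dplyr::select(comp, -"published_balance",
    -"published_anlr"))
  merged <- dplyr::inner_join(
    tibble::as_tibble(b), comp,
    by = c("year", "pattern", "n_rate"),
    suffix = c("", ".pub")
  )
  expect_equal(nrow(merged), 24)
  expect_true(all(abs(merged$balance - merged$published_balance) <= 0.01))
  defined <- !is.na(merged$published_anlr)
  expect_equal(sum(defined), 18)
  expect_true(all(abs(merged$anlr[defined] - merged$published_anlr[defined]) <= 0.01))
  expect_true(all(is.na(merged$anlr[!defined])))
  expect_true(all(merged$n_rate[!defined] == 0))
})

test_that("budget report table rounds and renders undefined loss rates", {
  comp <- trial_budget_components()
  tab <- budget_table(nitrogen_budget(
    dplyr::select(comp, -"published_balance", -"published_anlr")))
  expect_equal(sum(tab$anlr == "—"), 6)
  expect_equal(tab$balance[tab$label == "PMC2" & tab$year == 2023], 9.73)
  expect_equal(tab$anlr[tab$label == "PMC2" & tab$year == 2024], "1.15")

  single <- budget_table(nitrogen_budget(budget_row(160, 48.6, 48.7, 148.03,
    2.14, "PM")))
  expect_equal(nrow(single), 1)
  expect_equal(single$anlr, "6.08")
})

test_that("tidy, glance and autoplot work on a budget", {
  b <- nitrogen_budget(dplyr::select(trial_budget_components(),
    -"published_balance", -"published_anlr"))
  expect_s3_class(tidy(b), "tbl_df")
  g <- glance(b)
  expect_equal(g$n_budgets, 24)
  expect_equal(g$n_deficit + g$n_near_equilibrium + g$n_surplus, 24)
  expect_s3_class(autoplot(b), "ggplot")
})
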