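test_that("the generator is deterministic under its seed", {
  s1 <- simulate_trial(synthetic_design(seed = 42))
  s2 <- simulate_trial(synthetic_design(seed = 42))
  expect_identical(s1$soil, s2$soil)
  expect_identical(s1$plant, s2$plant)
  expect_identical(s1$chamber, s2$chamber)
  s3 <- simulate_trial(synthetic_design(seed = 43))
  expect_false(identical(s1$plant, s3$plant))

  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_trial(synthetic_design(seed = 42), out_dir = d1)
  simulate_trial(synthetic_design(seed = 42), out_dir = d2)
  for (f in c("soil.csv", "plant.csv", "chamber.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("design validation rejects inconsistent parameters", {
  expect_error(synthetic_design(cv = -0.1), class = "nbudget_validation_error")
  expect_error(synthetic_design(plant_peak_rate = 100),
    class = "nbudget_validation_error")
  expect_error(synthetic_design(pattern_effects = c(FP = 1, JM = 1)),
    class = "nbudget_validation_error")
  expect_error(synthetic_design(cut_weights = c(0.5, 0.5, 0.5)),
    class = "nbudget_validation_error")
  expect_error(simulate_trial(list()), class = "nbudget_validation_error")
})

test_that("with no noise every observation equals its stored truth", {
  sim <- simulate_trial(synthetic_design(seed = 1, cv = 0))
  expect_equal(sim$soil$no3_mg_kg, sim$truth$soil$no3_truth)
  expect_equal(sim$soil$nh4_mg_kg, sim$truth$soil$nh4_truth)
  expect_equal(sim$plant$leaf_dm_kg_ha, sim$truth$plant$leaf_dm_truth)
  expect_equal(sim$plant$stem_dm_kg_ha, sim$truth$plant$stem_dm_truth)

  # recovered per-deployment plot fluxes equal the truth curve
  fluxes <- position_weighted_flux(chamber_fluxes(sim$chamber), 0.5)
  merged <- dplyr::inner_join(fluxes, sim$truth$flux,
    by = c("year", "pattern", "n_rate", "replicate", "date"))
  expect_equal(merged$flux_ug_m2_h, merged$flux_truth_ug, tolerance = 1e-9)

  # seasonal plant N equals the designed season totals
  ps <- season_summary(sim$plant) |>
    dplyr::inner_join(sim$truth$plant_season,
      by = c("year", "pattern", "n_rate", "replicate"))
  expect_equal(ps$plant_n_kg_ha, ps$plant_n_truth_kg_ha)
})

test_that("noise-free means are peaked at 160 kg/ha and ordered PM > JM > FP", {
  sim <- simulate_trial(synthetic_design(seed = 2, cv = 0))
  means <- season_summary(sim$plant) |>
    dplyr::group_by(.data$pattern, .data$n_rate) |>
    dplyr::summarise(m = mean(.data$plant_n_kg_ha), .groups = "drop")
  by_rate <- tidyr::pivot_wider(means, names_from = "pattern",
    values_from = "m")
  expect_true(all(by_rate$PM > by_rate$JM & by_rate$JM > by_rate$FP))
  peak <- means |>
    dplyr::group_by(.data$n_rate) |>
    dplyr::summarise(m = mean(.data$m), .groups = "drop")
  expect_equal(peak$n_rate[which.max(peak$m)], 160)
  # the reported level ranking: C2 > C3 > C1 > C0
  expect_equal(peak$n_rate[order(peak$m, decreasing = TRUE)],
    c(160, 240, 80, 0))
})

test_that("seasonal emission totals fall in the observed field-scale band", {
  sim <- simulate_trial(synthetic_design(seed = 3, cv = 0))
  totals <- season_emissions(chamber_fluxes(sim$chamber), 0.5)
  expect_true(all(totals$n2o_kg_ha >= 1.2 & totals$n2o_kg_ha <= 3.0))
  # monotone in N rate and ordered by pattern within each year
  ord <- totals |>
    dplyr::group_by(.data$year, .data$pattern) |>
    dplyr::arrange(.data$n_rate, .by_group = TRUE) |>
    dplyr::summarise(mono = !is.unsorted(.data$n2o_kg_ha), .groups = "drop")
  expect_true(all(ord$mono))
})

test_that("recovery report: exact at zero noise, ordering held at default noise", {
  sim0 <- simulate_trial(synthetic_design(seed = 4, cv = 0))
  rec0 <- recover_effects(sim0)
  expect_true(rec0$pattern_order_ok)
  expect_true(rec0$peak_rate_ok)
  expect_lt(rec0$max_emission_rel_err, 0.01)

  sim8 <- simulate_trial(synthetic_design(seed = 42, cv = 0.08))
  rec8 <- recover_effects(sim8)
  expect_true(rec8$pattern_order_ok)
  expect_true(rec8$peak_rate_ok)

  # permutation invariance: shuffled rows give the identical report
  withr::local_seed(99)
  shuffled <- sim8
  shuffled$plant <- sim8$plant[sample(nrow(sim8$plant)), ]
  shuffled$chamber <- sim8$chamber[sample(nrow(sim8$chamber)), ]
  rec_shuf <- recover_effects(shuffled)
  expect_equal(rec_shuf$plant_means, rec8$plant_means)
  expect_equal(
    dplyr::arrange(rec_shuf$emission, .data$year, .data$pattern, .data$n_rate,
      .data$replicate),
    dplyr::arrange(rec8$emission, .data$year, .data$pattern, .data$n_rate,
      .data$replicate)
  )
})

test_that("generated tables have the full factorial shape and pass schemas", {
  sim <- simulate_trial(synthetic_design(seed = 5))
  expect_silent(validate_table(sim$soil, "soil"))
  expect_silent(validate_table(sim$plant, "plant"))
  expect_silent(validate_table(sim$chamber, "chamber"))
  # 2 years x 3 patterns x 4 rates x 3 reps
  expect_equal(nrow(dplyr::distinct(sim$plant, year, pattern, n_rate, replicate)),
    72)
  # soil: 2 seasons x 3 layers per plot-year
  expect_equal(nrow(sim$soil), 72 * 2 * 3)
  # flat plots sample one position, ridge-furrow two
  pos <- dplyr::distinct(sim$chamber, pattern, position)
  expect_setequal(pos$position[pos$pattern == "FP"], "flat")
  expect_setequal(pos$position[pos$pattern == "PM"], c("ridge", "furrow"))
})
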