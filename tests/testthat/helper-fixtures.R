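# Small in-code fixtures shared across tests.

soil_fixture <- function(no3 = 10, nh4 = 5, bd = 1.45,
                         tops = c(0, 20, 40), bottoms = c(20, 40, 60)) {
  tibble::tibble(
    year = 2023L, pattern = "FP", n_rate = 0, replicate = 1L,
    date = as.Date("2023-09-01"),
    depth_top_cm = tops, depth_bottom_cm = bottoms,
    bulk_density_g_cm3 = bd,
    no3_mg_kg = rep_len(no3, length(tops)),
    nh4_mg_kg = rep_len(nh4, length(tops))
  )
}

random_profile <- function() {
  k <- sample(2:4, 1)
  bounds <- sort(c(0, cumsum(stats::runif(k, 5, 30))))
  soil_fixture(
    no3 = stats::runif(k, 0, 40), nh4 = stats::runif(k, 0, 15),
    bd = stats::runif(k, 1.0, 1.7),
    tops = bounds[-(k + 1)], bottoms = bounds[-1]
  )
}

plant_fixture <- function(leaf_n = 3, stem_n = 1.5,
                          leaf_dm = 2000, stem_dm = 3000, cuts = 1:3) {
  tibble::tibble(
    year = 2023L, pattern = "PM", n_rate = 160, replicate = 1L,
    cut = as.integer(cuts),
    date = as.Date("2023-06-05") + 40 * (cuts - 1),
    leaf_n_pct = rep_len(leaf_n, length(cuts)),
    stem_n_pct = rep_len(stem_n, length(cuts)),
    leaf_dm_kg_ha = rep_len(leaf_dm, length(cuts)),
    stem_dm_kg_ha = rep_len(stem_dm, length(cuts))
  )
}

chamber_fixture <- function(minute = c(0, 10, 20, 30), conc = NULL,
                            slope = 0.01, height = 0.6, temp = 25,
                            position = "flat") {
  if (is.null(conc)) conc <- 0.33 + slope * minute
  tibble::tibble(
    year = 2023L, pattern = if (position == "flat") "FP" else "PM",
    n_rate = 160, replicate = 1L, date = as.Date("2023-07-01"),
    position = position, height_m = height, temp_c = temp,
    minute = minute, conc_ul_l = conc
  )
}

flux_fixture <- function(dates, flux, position = "flat", pattern = "FP") {
  tibble::tibble(
    year = 2023L, pattern = pattern, n_rate = 160, replicate = 1L,
    date = dates, position = position, flux_ug_m2_h = flux,
    r_squared = 1, n_points = 4L
  )
}

# independent closed-form OLS slope oracle
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# independent hand-dimensional-analysis flux oracle (result in ug m^-2 h^-1)
flux_oracle <- function(slope, H, T) {
  (2 * 14 / 22.4) * H * slope * 273 / (273 + T) * 60 * 1000
}

# brute-force pairwise LSD letter check: two levels must share a letter
# exactly when their means differ by at most the LSD
letters_consistent <- function(groups, lsd) {
  k <- nrow(groups)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      share <- length(intersect(
        strsplit(groups$letters[i], "")[[1]],
        strsplit(groups$letters[j], "")[[1]]
      )) > 0
      close <- abs(groups$mean[i] - groups$mean[j]) <= lsd
      if (share != close) return(FALSE)
    }
  }
  TRUE
}
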