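# brute-force sums-of-squares decomposition for a balanced 2x2x2 design
# with r replicates, computed directly from cell and marginal means
ss_oracle_222 <- function(df) {
  m <- mean(df$y)
  agg <- function(...) tapply(df$y, list(...), mean)
  ma <- agg(df$a); mb <- agg(df$b); mc <- agg(df$c)
  mab <- agg(df$a, df$b); mac <- agg(df$a, df$c); mbc <- agg(df$b, df$c)
  mabc <- agg(df$a, df$b, df$c)
  r <- nrow(df) / 8
  ss <- list(
    a = 4 * r * sum((ma - m)^2),
    b = 4 * r * sum((mb - m)^2),
    c = 4 * r * sum((mc - m)^2)
  )
  ss$ab <- 2 * r * sum((mab - outer(ma, rep(1, 2)) - outer(rep(1, 2), mb) + m)^2)
  ss$ac <- 2 * r * sum((mac - outer(ma, rep(1, 2)) - outer(rep(1, 2), mc) + m)^2)
  ss$bc <- 2 * r * sum((mbc - outer(mb, rep(1, 2)) - outer(rep(1, 2), mc) + m)^2)
  dev <- mabc
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    dev[i, j, k] <- mabc[i, j, k] - mab[i, j] - mac[i, k] - mbc[j, k] +
      ma[i] + mb[j] + mc[k] - m
  }
  ss$abc <- r * sum(dev^2)
  cellmean <- mabc[cbind(match(df$a, dimnames(mabc)[[1]]),
    match(df$b, dimnames(mabc)[[2]]),
    match(df$c, dimnames(mabc)[[3]]))]
  ss$error <- sum((df$y - cellmean)^2)
  ss
}

make_222 <- function(r = 3, seed = 101) {
  withr::with_seed(seed, {
    df <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2"),
      rep = seq_len(r), stringsAsFactors = FALSE)
    df$y <- 10 + 2 * (df$a == "a2") - 1.5 * (df$b == "b2") +
      0.8 * (df$a == "a2") * (df$c == "c2") + stats::rnorm(nrow(df))
    df
  })
}

test_that("constant responses give zero F and p = 1 for every term", {
  df <- make_222()
  df$y <- 7
  fit <- anova_factorial(df, "y", c("a", "b", "c"))
  terms <- dplyr::filter(fit$table, term != "Residuals")
  expect_true(all(terms$statistic == 0))
  expect_true(all(terms$p.value == 1))
  expect_true(all(terms$signif == "ns"))
})

test_that("one-factor two-level ANOVA F equals the pooled t statistic squared", {
  withr::local_seed(29)
  for (i in 1:10) {
    g1 <- stats::rnorm(6, 10, 2)
    g2 <- stats::rnorm(6, 12, 2)
    df <- data.frame(y = c(g1, g2), g = rep(c("A", "B"), each = 6))
    fit <- anova_factorial(df, "y", "g")
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    f_anova <- fit$table$statistic[fit$table$term == "g"]
    expect_equal(f_anova, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(fit$table$p.value[fit$table$term == "g"], tt$p.value,
      tolerance = 1e-9)
  }
})

test_that("balanced 2x2x2 sums of squares match the cell-mean oracle", {
  for (seed in c(101, 202, 303)) {
    df <- make_222(seed = seed)
    fit <- anova_factorial(df, "y", c("a", "b", "c"))
    oracle <- ss_oracle_222(df)
    got <- setNames(fit$table$sumsq, fit$table$term)
    expect_equal(got[["a"]], oracle$a, tolerance = 1e-10)
    expect_equal(got[["b"]], oracle$b, tolerance = 1e-10)
    expect_equal(got[["c"]], oracle$c, tolerance = 1e-10)
    expect_equal(got[["a x b"]], oracle$ab, tolerance = 1e-10)
    expect_equal(got[["a x c"]], oracle$ac, tolerance = 1e-10)
    expect_equal(got[["b x c"]], oracle$bc, tolerance = 1e-10)
    expect_equal(got[["a x b x c"]], oracle$abc, tolerance = 1e-10)
    expect_equal(got[["Residuals"]], oracle$error, tolerance = 1e-10)
    # the decomposition is exhaustive
    expect_equal(sum(fit$table$sumsq), sum((df$y - mean(df$y))^2),
      tolerance = 1e-10)
  }
})

test_that("F is invariant to shifting and scaling the response", {
  df <- make_222()
  f0 <- anova_factorial(df, "y", c("a", "b", "c"))$table$statistic
  df$y2 <- df$y + 100
  df$y3 <- df$y * 7
  f_shift <- anova_factorial(df, "y2", c("a", "b", "c"))$table$statistic
  f_scale <- anova_factorial(df, "y3", c("a", "b", "c"))$table$statistic
  expect_equal(f_shift, f0, tolerance = 1e-9)
  expect_equal(f_scale, f0, tolerance = 1e-9)
})

test_that("interaction order can be capped and errors are informative", {
  df <- make_222()
  fit <- anova_factorial(df, "y", c("a", "b", "c"), max_order = 1)
  expect_false(any(grepl(" x ", fit$table$term)))
  expect_error(anova_factorial(df, "nope", c("a", "b")),
    class = "nbudget_argument_error")
  expect_error(anova_factorial(df, "y", c("a", "zzz")),
    class = "nbudget_argument_error")
  one_per_cell <- dplyr::filter(df, rep == 1)
  expect_error(anova_factorial(one_per_cell, "y", c("a", "b", "c")),
    class = "nbudget_design_error")
  expect_warning(anova_factorial(df[-1, ], "y", c("a", "b", "c")),
    class = "nbudget_unbalanced_warning")
})

test_that("prechecks report Shapiro-Wilk and Levene without blocking", {
  df <- make_222()
  pc <- precheck_assumptions(df, "y", c("a", "b", "c"))
  expect_equal(pc$test, c("shapiro_wilk", "levene"))
  expect_true(all(pc$note == "ok"))
  expect_true(pc$statistic[1] <= 1)
  expect_true(all(pc$p.value >= 0 & pc$p.value <= 1))

  # literally identical group distributions give a zero Levene statistic
  ident <- data.frame(
    y = rep(c(1, 2, 3), times = 4),
    g = rep(c("a", "b", "c", "d"), each = 3)
  )
  lv <- precheck_assumptions(ident, "y", "g")
  expect_equal(lv$statistic[lv$test == "levene"], 0)
})

test_that("Levene detects strong heteroscedasticity in most seeded replicates", {
  hits <- 0
  for (s in 1:200) {
    df <- withr::with_seed(1000 + s, data.frame(
      y = c(stats::rnorm(30, 0, 1), stats::rnorm(30, 0, 5)),
      g = rep(c("lo", "hi"), each = 30)
    ))
    p <- precheck_assumptions(df, "y", "g")
    p <- p$p.value[p$test == "levene"]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
})

test_that("LSD letters separate and join means as the threshold dictates", {
  g <- lsd_groups(c(A = 20, B = 10), mse = 1, df_error = 10, n = 3)
  expect_equal(g$letters, c("a", "b"))
  g2 <- lsd_groups(c(A = 10, B = 10, C = 10), mse = 1, df_error = 10, n = 3)
  expect_true(all(g2$letters == "a"))
  # protection: non-significant omnibus leaves one group
  g3 <- lsd_groups(c(A = 20, B = 10), mse = 1, df_error = 10, n = 3,
    omnibus_p = 0.4)
  expect_true(all(g3$letters == "a"))
  expect_error(lsd_groups(c(10, 20), 1, 10, 3), class = "nbudget_argument_error")
  expect_error(lsd_groups(c(A = 1, B = 2), -1, 10, 3),
    class = "nbudget_argument_error")
})

test_that("letters match the exhaustive pairwise-comparison oracle", {
  withr::local_seed(47)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    means <- setNames(stats::runif(k, 0, 10), paste0("L", seq_len(k)))
    mse <- stats::runif(1, 0.2, 4)
    g <- lsd_groups(means, mse = mse, df_error = 12, n = 3)
    expect_true(letters_consistent(g, attr(g, "lsd")))
  }
})
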