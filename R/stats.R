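# Factorial treatment statistics for the trial's crossed fixed-effects
# design: n-way ANOVA (rate x pattern x year and lower-order variants),
# Shapiro-Wilk / Levene prechecks, and the protected LSD post hoc with a
# compact letter display at alpha = 0.05 -- the analysis toolchain agronomy
# trials conventionally report.

#' Crossed fixed-effects factorial ANOVA
#'
#' Fits a fixed-effects ANOVA with all interactions among `factors` up to
#' `max_order`. Balanced designs use the exact orthogonal (Type I)
#' decomposition, for which the sums of squares are order-independent;
#' unbalanced data fall back to Type II sums of squares with a warning.
#' Terms whose sum of squares is numerically zero are reported with
#' `statistic = 0, p.value = 1` (a term that explains nothing, as when all
#' responses are equal).
#'
#' @param data A data frame of plot-level observations.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names (each with >= 2
#'   levels in the data).
#' @param max_order Highest interaction order to include; defaults to the
#'   full factorial.
#' @return An object of class `"nbudget_anova"`: a list with `table` (term,
#'   df, sumsq, meansq, statistic, p.value, signif), the fitted `model`, and
#'   `residuals`. `signif` uses the conventional tags: `**` for p < 0.01,
#'   `*` for p < 0.05, `ns` otherwise.
#' @examples
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)
#' d$resp <- rnorm(nrow(d)) + (d$a == "x") * 2
#' anova_factorial(d, "resp", c("a", "b"))
#' @export
anova_factorial <- function(data, response, factors, max_order = length(factors)) {
  if (!response %in% names(data)) {
    abort(sprintf("Response column '%s' not found.", response),
      class = "nbudget_argument_error")
  }
  missing_f <- setdiff(factors, names(data))
  if (length(missing_f) > 0) {
    abort(sprintf("Unknown factor column(s): %s.", paste(missing_f, collapse = ", ")),
      class = "nbudget_argument_error")
  }
  max_order <- min(max_order, length(factors))
  df <- data
  df$.response <- df[[response]]
  for (f in factors) df[[f]] <- factor(df[[f]])
  if (any(vapply(df[factors], nlevels, 1L) < 2)) {
    abort("Every factor needs >= 2 levels in the data.",
      class = "nbudget_design_error")
  }
  cells <- table(df[factors])
  if (all(cells <= 1) && max_order == length(factors)) {
    # full factorial without replication leaves no error degrees of freedom
    abort("No error degrees of freedom: full factorial with one observation per cell.",
      class = "nbudget_design_error")
  }
  balanced <- length(unique(as.vector(cells))) == 1 && all(cells > 0)
  rhs <- if (max_order >= 2) {
    sprintf("(%s)^%d", paste(factors, collapse = " + "), max_order)
  } else {
    paste(factors, collapse = " + ")
  }
  fml <- stats::as.formula(paste(".response ~", rhs))
  fit <- lm(fml, data = df)
  if (balanced) {
    # degenerate (perfect-fit) designs are handled by the zero-SS rule below
    a <- suppressWarnings(stats::anova(fit))
    tab <- tibble::tibble(
      term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`
    )
  } else {
    warn("Unbalanced design: using Type II sums of squares.",
      class = "nbudget_unbalanced_warning")
    a <- car::Anova(fit, type = 2)
    tab <- tibble::tibble(
      term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`
    )
  }
  resid_row <- tab$term == "Residuals"
  if (!any(resid_row) || tab$df[resid_row] < 1) {
    abort("No error degrees of freedom for the requested model.",
      class = "nbudget_design_error")
  }
  mse <- tab$sumsq[resid_row] / tab$df[resid_row]
  df_err <- tab$df[resid_row]
  # a term is "zero" relative to the response's own scale, so a constant
  # response yields F = 0, p = 1 throughout rather than 0/0
  eps <- 1e-10 * (sum(df$.response^2) / length(df$.response) + 1e-300)
  tab <- tab |>
    dplyr::mutate(
      term = gsub(":", " x ", .data$term),
      meansq = .data$sumsq / .data$df,
      statistic = dplyr::if_else(resid_row, NA_real_,
        dplyr::if_else(.data$sumsq <= eps, 0, .data$meansq / mse)),
      p.value = dplyr::if_else(resid_row, NA_real_,
        dplyr::if_else(.data$sumsq <= eps, 1,
          pf(.data$meansq / mse, .data$df, df_err, lower.tail = FALSE))),
      signif = dplyr::case_when(
        is.na(.data$p.value) ~ "",
        .data$p.value < 0.01 ~ "**",
        .data$p.value < 0.05 ~ "*",
        TRUE ~ "ns"
      )
    )
  structure(
    list(table = tab, model = fit, residuals = stats::residuals(fit),
      response = response, factors = factors, balanced = balanced,
      mse = mse, df_error = df_err),
    class = "nbudget_anova"
  )
}

#' @export
#' @method tidy nbudget_anova
tidy.nbudget_anova <- function(x, ...) x$table

#' @export
#' @method glance nbudget_anova
glance.nbudget_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared, sigma = s$sigma,
    df_error = x$df_error, mse = x$mse,
    balanced = x$balanced, n = length(x$residuals)
  )
}

#' @export
print.nbudget_anova <- function(x, ...) {
  cat(sprintf("# Factorial ANOVA of %s (~ %s); %s design\n",
    x$response, paste(x$factors, collapse = " x "),
    if (x$balanced) "balanced" else "unbalanced (Type II SS)"))
  print(x$table, ...)
  invisible(x)
}

#' Normality and variance-homogeneity prechecks
#'
#' Advisory checks run before a factorial ANOVA: Shapiro-Wilk on the
#' residuals of the full-interaction cell-means fit, and Levene's test
#' (centered on cell means, the classical form) across the design cells.
#' Results are reported, never used to block the ANOVA.
#'
#' @inheritParams anova_factorial
#' @return A tibble with one row per test: `test`, `statistic`, `p.value`,
#'   `note` (`"ok"` or `"not testable"` with the reason).
#' @export
precheck_assumptions <- function(data, response, factors) {
  df <- data
  df$.response <- df[[response]]
  for (f in factors) df[[f]] <- factor(df[[f]])
  df$.cell <- interaction(df[factors], drop = TRUE)
  res <- stats::residuals(lm(.response ~ .cell, data = df))
  shapiro_row <- if (length(res) >= 3 && length(res) <= 5000 && sd(res) > 0) {
    sw <- shapiro.test(res)
    tibble::tibble(test = "shapiro_wilk", statistic = unname(sw$statistic),
      p.value = sw$p.value, note = "ok")
  } else {
    tibble::tibble(test = "shapiro_wilk", statistic = NA_real_,
      p.value = NA_real_, note = "not testable: need 3-5000 non-constant residuals")
  }
  enough <- nlevels(df$.cell) >= 2 && all(table(df$.cell) >= 2)
  levene_row <- if (enough) {
    lv <- car::leveneTest(.response ~ .cell, data = df, center = mean)
    tibble::tibble(test = "levene", statistic = lv$`F value`[1],
      p.value = lv$`Pr(>F)`[1], note = "ok")
  } else {
    tibble::tibble(test = "levene", statistic = NA_real_, p.value = NA_real_,
      note = "not testable: need >= 2 groups with >= 2 observations")
  }
  dplyr::bind_rows(shapiro_row, levene_row)
}

#' Protected LSD compact letter display
#'
#' Fisher's least significant difference, `LSD = t(1 - alpha/2, df) *
#' sqrt(2 * mse / n)`, applied to a set of level means sharing a pooled error
#' variance. Levels whose means differ by at most the LSD share a letter;
#' letters are assigned to the maximal runs of the means sorted in
#' descending order (with a single common threshold the "shares a letter"
#' relation is an interval graph, so contiguous runs represent it exactly).
#' Protected: when the omnibus p-value is supplied and not significant, no
#' pairwise separation is attempted and all levels share `"a"`.
#'
#' @param means Named numeric vector of level means.
#' @param mse Pooled error mean square (> 0), e.g. from [anova_factorial()].
#' @param df_error Error degrees of freedom (>= 1).
#' @param n Observations per level mean (equal n; the LSD formula assumes a
#'   balanced comparison).
#' @param alpha Significance level. Default 0.05.
#' @param omnibus_p Optional omnibus F-test p-value for protection.
#' @return A tibble with `level`, `mean`, `letters`, sorted by descending
#'   mean, with the LSD value as attribute `"lsd"`.
#' @examples
#' lsd_groups(c(A = 10, B = 9.8, C = 5), mse = 0.5, df_error = 12, n = 3)
#' @export
lsd_groups <- function(means, mse, df_error, n, alpha = 0.05, omnibus_p = NULL) {
  if (is.null(names(means)) || anyDuplicated(names(means))) {
    abort("`means` must be uniquely named.", class = "nbudget_argument_error")
  }
  if (!is.numeric(mse) || mse <= 0) {
    abort("`mse` must be > 0.", class = "nbudget_argument_error")
  }
  if (df_error < 1) {
    abort("`df_error` must be >= 1.", class = "nbudget_argument_error")
  }
  if (length(n) != 1 || n < 1) {
    abort("`n` must be a single per-level count; unequal n is not supported.",
      class = "nbudget_argument_error")
  }
  lsd <- qt(1 - alpha / 2, df_error) * sqrt(2 * mse / n)
  o <- order(means, decreasing = TRUE)
  m <- means[o]
  k <- length(m)
  if (!is.null(omnibus_p) && omnibus_p > alpha) {
    groups <- matrix(TRUE, nrow = k, ncol = 1)
  } else {
    # for each start i, the furthest level still within one LSD; keep the
    # maximal runs (ends strictly increase)
    ends <- vapply(seq_len(k), function(i) max(which(m[i] - m <= lsd)), integer(1))
    starts <- which(seq_len(k) == 1L | ends > c(0L, ends[-k]))
    runs <- lapply(starts, function(i) c(i, ends[i]))
    groups <- vapply(runs, function(r) seq_len(k) >= r[1] & seq_len(k) <= r[2],
      logical(k))
    groups <- matrix(groups, nrow = k)
  }
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- apply(groups, 1, function(row) {
    paste(letter_pool[which(row)], collapse = "")
  })
  out <- tibble::tibble(level = names(m), mean = unname(m), letters = lab)
  structure(out, class = c("nbudget_lsd", class(out)), lsd = lsd, alpha = alpha)
}
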