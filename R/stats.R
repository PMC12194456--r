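#' Choose a two-group test from the data
#'
#' Continuous variables: if both groups pass the Shapiro-Wilk normality test
#' (p >= 0.05 in each), the two-sided unpaired Student's t-test is used;
#' otherwise the Mann-Whitney U test. Categorical variables: Fisher's exact
#' test when any expected cell count is below 5, otherwise chi-square.
#'
#' @param x,y Numeric observations of the two groups (continuous case);
#'   at least 3 per group.
#' @param alpha Normality-gate threshold on the Shapiro-Wilk p-value.
#' @return `"student_t"` or `"mann_whitney"`.
#' @seealso [choose_categorical_test()]
#' @export
choose_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("choose_test: need at least 3 observations per group", call. = FALSE)
  normal <- function(v) {
    if (length(unique(v)) == 1L) return(FALSE)  # shapiro undefined; not normal
    stats::shapiro.test(v)$p.value >= alpha
  }
  if (normal(x) && normal(y)) "student_t" else "mann_whitney"
}

#' Choose a test for a contingency table
#'
#' @param tab A contingency table (matrix of counts).
#' @return `"fisher_exact"` if any expected count is below 5, else
#'   `"chi_square"`.
#' @export
choose_categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) "fisher_exact" else "chi_square"
}

summarise_group <- function(v, test_used) {
  if (test_used == "student_t")
    sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
  else
    sprintf("%.2f (%.2f–%.2f)", stats::median(v), min(v), max(v))
}

#' Compare a variable between the two fluid groups
#'
#' Applies the normality-gated battery of [choose_test()]: Student's t-test
#' (classical equal-variance by default; Welch via `var_equal = FALSE`) or
#' Mann-Whitney U for numeric variables, chi-square or Fisher's exact for
#' categorical ones. All tests are two-sided; no multiple-testing correction
#' is applied (each row of a comparison table is reported at its nominal
#' two-sided p).
#'
#' @param table Cohort data frame with a `group_label` column.
#' @param variable Name of the column to compare.
#' @param group Name of the grouping column.
#' @param var_equal Use the classical equal-variance t-test (default) rather
#'   than Welch.
#' @return A `dka_comparison` object: list with `variable`, `test_used`,
#'   `statistic`, `p_value`, `group_summaries`, `groups`.
#' @export
compare_groups <- function(table, variable, group = "group_label",
                           var_equal = TRUE) {
  if (is.null(table[[variable]]))
    stop("compare_groups: no column `", variable, "`", call. = FALSE)
  g <- factor(table[[group]])
  if (nlevels(g) < 2)
    stop("compare_groups: need two groups, found ",
         nlevels(g), call. = FALSE)
  v <- table[[variable]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2)
    stop("compare_groups: need two groups, found ", nlevels(g), call. = FALSE)

  if (is.numeric(v)) {
    sp <- split(v, g)
    if (length(unique(v)) == 1L)
      stop("compare_groups: `", variable,
           "` is constant in both groups (degenerate input)", call. = FALSE)
    test_used <- choose_test(sp[[1]], sp[[2]])
    if (test_used == "student_t") {
      ht <- stats::t.test(sp[[1]], sp[[2]], var.equal = var_equal)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]]))
    }
    summaries <- vapply(sp, summarise_group, character(1),
                        test_used = test_used)
  } else {
    tab <- table(v, g)
    test_used <- choose_categorical_test(tab)
    ht <- if (test_used == "fisher_exact") stats::fisher.test(tab)
          else suppressWarnings(stats::chisq.test(tab))
    summaries <- apply(tab, 2, function(col)
      paste(sprintf("%s: %d", rownames(tab), col), collapse = ", "))
  }
  structure(list(variable = variable,
                 test_used = test_used,
                 statistic = if (!is.null(ht$statistic))
                   unname(ht$statistic) else NA_real_,
                 p_value = ht$p.value,
                 group_summaries = summaries,
                 groups = levels(g)),
            class = "dka_comparison")
}

#' @export
print.dka_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s\n", x$variable, x$groups[1], x$groups[2]))
  cat(sprintf("  %s  %s\n", x$groups[1], x$group_summaries[1]))
  cat(sprintf("  %s  %s\n", x$groups[2], x$group_summaries[2]))
  cat(sprintf("  test = %s, p = %s%s\n", x$test_used,
              format.pval(x$p_value, digits = 3),
              if (x$p_value < 0.05) " *" else ""))
  invisible(x)
}

#' Run the comparison battery over several variables
#'
#' @inheritParams compare_groups
#' @param variables Character vector of column names.
#' @return Data frame with one row per variable: group summaries, test used,
#'   p-value.
#' @export
comparison_table <- function(table, variables, group = "group_label") {
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(table, v, group = group)
    data.frame(variable = v,
               group1 = unname(cmp$group_summaries[1]),
               group2 = unname(cmp$group_summaries[2]),
               test_used = cmp$test_used,
               p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation of a variable with ICU length of stay
#'
#' @param table Cohort data frame with `los_icu_days`.
#' @param variable Column to correlate with LOS.
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_with_los <- function(table, variable) {
  x <- table[[variable]]
  y <- table$los_icu_days
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("correlate_with_los: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate_with_los: zero variance in `", variable,
         "` or LOS (degenerate input)", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Default predictor set for the LOS regression
#'
#' Age, BMI, APACHE II, SOFA, and the six-hour deltas of pH (x100), PaCO2,
#' HCO3, Na, Cl, lactate, SIG and glucose.
#'
#' @return Character vector of cohort column names.
#' @export
los_predictors <- function() {
  c("age", "bmi", "apache2", "sofa",
    "delta_ph", "delta_paco2", "delta_hco3", "delta_na", "delta_cl",
    "delta_lactate", "delta_sig", "delta_glucose")
}

#' Multivariate linear regression of ICU length of stay
#'
#' Ordinary least squares of `los_icu_days` on the chosen predictors, with
#' intercept. `delta_ph` is rescaled by 100 before fitting (so its
#' coefficient is per 0.01 pH unit). Reports per-coefficient 95\% confidence
#' intervals and p-values, the model R-squared and the Durbin-Watson
#' statistic.
#'
#' @param table Derived cohort data frame (see [derive_cohort()]).
#' @param predictors Character vector of predictor columns; defaults to
#'   [los_predictors()].
#' @param outcome Outcome column, `los_icu_days` by default.
#' @return A `dka_regression` object with elements `coefficients` (data frame
#'   `term`, `estimate`, `ci_low`, `ci_high`, `p_value`), `r_squared`,
#'   `durbin_watson`, `n`, and the underlying `fit`.
#' @export
los_regression <- function(table, predictors = los_predictors(),
                           outcome = "los_icu_days") {
  missing_nm <- setdiff(c(outcome, predictors), names(table))
  if (length(missing_nm))
    stop("los_regression: missing column(s): ",
         paste(missing_nm, collapse = ", "), call. = FALSE)
  dat <- table[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if ("delta_ph" %in% names(dat)) {
    dat$delta_ph_x100 <- 100 * dat$delta_ph
    dat$delta_ph <- NULL
    predictors[predictors == "delta_ph"] <- "delta_ph_x100"
  }
  if (nrow(dat) <= length(predictors))
    stop("los_regression: need more observations than predictors (n = ",
         nrow(dat), ", p = ", length(predictors), ")", call. = FALSE)
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = dat)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased))
    stop("los_regression: rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      ci_low = ci[, 1],
                      ci_high = ci[, 2],
                      p_value = sm$coefficients[, 4],
                      row.names = NULL,
                      stringsAsFactors = FALSE)
  # only the statistic is reported; dwtest's exact-p fallback warning is moot
  dw <- suppressWarnings(lmtest::dwtest(fit))
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 durbin_watson = unname(dw$statistic),
                 n = nrow(dat),
                 outcome = outcome,
                 fit = fit),
            class = "dka_regression")
}

#' @export
print.dka_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Linear model for %s (n = %d)\n", x$outcome, x$n))
  cat(sprintf("R-squared: %.2f; Durbin-Watson: %.2f\n",
              x$r_squared, x$durbin_watson))
  co <- x$coefficients
  co$estimate <- signif(co$estimate, digits)
  co$ci <- sprintf("(%.3f; %.3f)", co$ci_low, co$ci_high)
  co$p_value <- signif(co$p_value, 2)
  print(co[, c("term", "estimate", "ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.dka_regression <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.dka_regression <- function(object, ...) summary(object$fit, ...)

#' Power of the two-sided two-sample t-test
#'
#' Exact power from the noncentral t distribution, allowing unequal group
#' sizes: with noncentrality `ncp = mean_diff / (sd * sqrt(1/n1 + 1/n2))` and
#' critical value `tc = qt(1 - alpha/2, n1 + n2 - 2)`, the power is
#' `P(T > tc) + P(T < -tc)` for `T ~ t(df, ncp)`. At `mean_diff = 0` this
#' reduces to the test size `alpha`.
#'
#' @param n1,n2 Group sizes (each >= 2).
#' @param mean_diff True difference in means (same units as `sd`).
#' @param sd Common standard deviation (> 0).
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Power in `[0, 1]`.
#' @examples
#' two_sample_t_power(21, 13, mean_diff = 9, sd = 3)  # ~1
#' @export
two_sample_t_power <- function(n1, n2, mean_diff, sd, alpha = 0.05) {
  if (n1 < 2 || n2 < 2)
    stop("two_sample_t_power: need n1, n2 >= 2", call. = FALSE)
  if (!is.finite(sd) || sd <= 0)
    stop("two_sample_t_power: `sd` must be positive", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("two_sample_t_power: `alpha` must be in (0, 1)", call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- mean_diff / (sd * sqrt(1 / n1 + 1 / n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}
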