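test_that("normality gate picks the t-test for normal-shaped samples only", {
  x <- qnorm(ppoints(20))            # exact normal quantiles
  y <- qnorm(ppoints(25)) + 1
  expect_identical(choose_test(x, y), "student_t")
  heavy <- qcauchy(ppoints(20))      # heavy-tailed: Shapiro-Wilk rejects
  expect_identical(choose_test(x, heavy), "mann_whitney")
  expect_error(choose_test(1:2, 1:10), "at least 3")
})

test_that("categorical gate uses Fisher below expected count 5", {
  expect_identical(choose_categorical_test(matrix(c(1, 9, 10, 8), 2)),
                   "fisher_exact")
  expect_identical(choose_categorical_test(matrix(c(20, 25, 30, 22), 2)),
                   "chi_square")
})

test_that("group comparison handles separation, ties and degeneracy", {
  tab <- data.frame(group_label = rep(c("GI", "GII"), each = 3),
                    v = c(1, 2, 3, 101, 102, 103))
  cmp <- compare_groups(tab, "v")
  expect_lt(cmp$p_value, 0.05)

  same <- data.frame(group_label = rep(c("GI", "GII"), each = 4),
                     v = rep(c(1, 2, 3, 4), 2))
  cmp_same <- compare_groups(same, "v")
  expect_equal(cmp_same$p_value, 1)

  const <- data.frame(group_label = rep(c("GI", "GII"), each = 4), v = 5)
  expect_error(compare_groups(const, "v"), "degenerate")
  expect_error(compare_groups(tab, "nope"), "nope")
  single <- tab[tab$group_label == "GI", ]
  expect_error(compare_groups(single, "v"), "two groups")
})

test_that("Mann-Whitney agrees with exhaustive permutation enumeration", {
  set.seed(31)
  for (n1 in 3:6) for (n2 in c(3, 5, 6)) {
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    p_pkg <- suppressWarnings(wilcox.test(x, y)$p.value)
    expect_equal(p_pkg, mw_enum_p(x, y), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("Fisher exact equals hypergeometric enumeration on 2x2 tables", {
  set.seed(32)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + c(1, 0, 0, 1), 2)
    expect_equal(fisher.test(tab)$p.value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("LOS correlation recovers exact linear relations", {
  tab <- data.frame(los_icu_days = 2 * (1:10), x = 1:10)
  expect_equal(correlate_with_los(tab, "x")$r, 1)
  tab$y <- -tab$los_icu_days + 7
  expect_equal(correlate_with_los(tab, "y")$r, -1)
  tab$z <- 5
  expect_error(correlate_with_los(tab, "z"), "zero variance")
  expect_error(correlate_with_los(tab[1:2, ], "x"), "3 complete")
})

test_that("LOS regression is exact on noise-free data and flags collinearity", {
  set.seed(33)
  n <- 60
  tab <- data.frame(age = rnorm(n, 50, 10), bmi = rnorm(n, 25, 3),
                    delta_cl = rnorm(n, 4, 3))
  tab$los_icu_days <- 1 + 0.05 * tab$age + 0.2 * tab$delta_cl
  fit <- suppressWarnings(  # lm flags the deliberately perfect fit
    los_regression(tab, c("age", "bmi", "delta_cl")))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(coef(fit)[["delta_cl"]], 0.2, tolerance = 1e-9)

  tab$dup <- tab$age * 2
  expect_error(los_regression(tab, c("age", "bmi", "dup")), "collinear")
  expect_error(los_regression(tab[1:3, ], c("age", "bmi", "delta_cl")),
               "more observations")
})

test_that("LOS regression recovers a known chloride coefficient", {
  set.seed(34)
  n <- 200
  tab <- data.frame(delta_cl = rnorm(n, 5, 4), age = rnorm(n, 50, 15),
                    bmi = rnorm(n, 25, 4), delta_lactate = rnorm(n, -0.5, 1))
  tab$los_icu_days <- 2 + 0.2 * tab$delta_cl + rnorm(n, 0, 0.1)
  fit <- los_regression(tab, c("delta_cl", "age", "bmi", "delta_lactate"))
  est <- coef(fit)[["delta_cl"]]
  expect_gt(est, 0.15); expect_lt(est, 0.25)
  expect_gt(fit$durbin_watson, 1); expect_lt(fit$durbin_watson, 3)
})

test_that("regression CIs cover truth and keep nominal type-I error", {
  set.seed(35)
  n <- 80; reps <- 250
  beta <- c(x1 = 0.5, x2 = 0)
  cover <- logical(reps); reject_null <- logical(reps)
  for (r in seq_len(reps)) {
    tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    tab$los_icu_days <- 1 + beta[["x1"]] * tab$x1 + rnorm(n)
    fit <- los_regression(tab, c("x1", "x2", "x3"))
    co <- fit$coefficients
    cover[r] <- co$ci_low[co$term == "x1"] <= 0.5 &&
      co$ci_high[co$term == "x1"] >= 0.5
    reject_null[r] <- co$p_value[co$term == "x2"] < 0.05
  }
  expect_gt(mean(cover), 0.90); expect_lt(mean(cover), 0.99)
  expect_gt(mean(reject_null), 0.01); expect_lt(mean(reject_null), 0.10)
})

test_that("delta-pH enters the regression rescaled by 100", {
  set.seed(36)
  n <- 100
  tab <- data.frame(delta_ph = rnorm(n, 0.2, 0.05), x = rnorm(n))
  tab$los_icu_days <- 2 + 10 * tab$delta_ph + rnorm(n, 0, 0.01)
  fit <- los_regression(tab, c("delta_ph", "x"))
  expect_true("delta_ph_x100" %in% fit$coefficients$term)
  expect_equal(coef(fit)[["delta_ph_x100"]], 0.1, tolerance = 0.02)
})

test_that("t-test power follows the noncentral t distribution", {
  expect_equal(two_sample_t_power(21, 13, 0, 3), 0.05, tolerance = 1e-12)
  expect_gt(two_sample_t_power(21, 13, 9, 3), 0.99)
  # monotone in effect size, n, and alpha
  expect_gt(two_sample_t_power(50, 50, 0.5, 1),
            two_sample_t_power(10, 10, 0.5, 1))
  expect_gt(two_sample_t_power(20, 20, 0.8, 1),
            two_sample_t_power(20, 20, 0.4, 1))
  expect_gt(two_sample_t_power(20, 20, 0.5, 1, alpha = 0.10),
            two_sample_t_power(20, 20, 0.5, 1, alpha = 0.05))
  # equal-n case agrees with stats::power.t.test (which drops the far tail)
  expect_equal(two_sample_t_power(15, 15, 0.7, 1),
               power.t.test(n = 15, delta = 0.7, sd = 1)$power,
               tolerance = 2e-4)
  # and with a Monte-Carlo oracle at moderate power
  set.seed(37)
  expect_equal(two_sample_t_power(15, 15, 1, 1),
               mc_t_power(15, 15, 1, 1, 0.05), tolerance = 0.01)
  expect_error(two_sample_t_power(1, 10, 1, 1), "n1")
  expect_error(two_sample_t_power(10, 10, 1, -1), "sd")
  expect_error(two_sample_t_power(10, 10, 1, 1, alpha = 1.2), "alpha")
})
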