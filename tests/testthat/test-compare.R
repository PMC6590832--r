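# OLS engine, encompassing comparison, Welch/paired t, Holm, predictor
# comparison report.

test_that("ols_fit matches the normal-equations oracle", {
  set.seed(8)
  for (i in 1:5) {
    d <- tibble::tibble(x1 = rnorm(12), x2 = rnorm(12))
    d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + rnorm(12, 0, 0.3)
    fit <- ols_fit(d, "y", c("x1", "x2"))
    xm <- cbind(1, d$x1, d$x2)
    beta <- solve(t(xm) %*% xm, t(xm) %*% d$y)
    expect_equal(fit$coefficients$estimate, as.vector(beta),
                 tolerance = 1e-10, ignore_attr = TRUE)
    rss <- sum((d$y - xm %*% beta)^2)
    tss <- sum((d$y - mean(d$y))^2)
    expect_equal(fit$r_squared, 1 - rss / tss, tolerance = 1e-10)
    expect_equal(fit$df_residual, 9)
  }
})

test_that("ols_fit handles exact fits, orthogonal predictors and errors", {
  d <- tibble::tibble(x = 1:10, y = 3 - 2 * (1:10))
  expect_equal(suppressWarnings(ols_fit(d, "y", "x"))$r_squared, 1)
  # constructed orthogonal response: slope exactly zero
  d2 <- tibble::tibble(x = c(-1, 0, 1), y = c(1, -2, 1))
  expect_equal(ols_fit(d2, "y", "x")$coefficients$estimate[2], 0)
  dup <- tibble::tibble(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(ols_fit(dup, "y", c("x", "z")), "[Ss]ingular")
  expect_error(ols_fit(d[1:2, ], "y", "x"), "observations")
  expect_named(glance(suppressWarnings(ols_fit(d, "y", "x"))),
               c("r_squared", "f_statistic", "df1", "df2", "p_value", "n",
                 "residual_ss", "df_residual"))
})

test_that("encompassing partial-F equals the squared coefficient t", {
  set.seed(19)
  for (i in 1:10) {
    d <- tibble::tibble(pi = rnorm(30), f = rnorm(30))
    d$y <- 0.6 * d$pi + 0.2 * d$f + rnorm(30)
    enc <- encompassing_test(d, "y", "pi", "f")
    tt <- enc$combined$coefficients$t_statistic
    expect_equal(enc$tests$partial_f[enc$tests$dropped == "pi"], unname(tt[2])^2,
                 tolerance = 1e-8)
    expect_equal(enc$tests$partial_f[enc$tests$dropped == "f"], unname(tt[3])^2,
                 tolerance = 1e-8)
    expect_equal(enc$tests$df2, rep(27L, 2))
    # nesting monotonicity of R^2
    expect_gte(enc$combined$r_squared,
               max(enc$fit_a$r_squared, enc$fit_b$r_squared) - 1e-12)
  }
})

test_that("encompassing comparison agrees with the lmtest Wald oracle", {
  skip_if_not_installed("lmtest")
  set.seed(23)
  d <- tibble::tibble(pi = runif(40), f = runif(40))
  d$y <- 1 + 0.8 * d$pi + rnorm(40, 0, 0.4)
  enc <- encompassing_test(d, "y", "pi", "f")
  full <- stats::lm(y ~ pi + f, data = d)
  w_pi <- lmtest::waldtest(stats::lm(y ~ f, data = d), full)
  w_f <- lmtest::waldtest(stats::lm(y ~ pi, data = d), full)
  expect_equal(enc$tests$partial_f[enc$tests$dropped == "pi"],
               w_pi$F[2], tolerance = 1e-10)
  expect_equal(enc$tests$p_value[enc$tests$dropped == "pi"],
               w_pi$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(enc$tests$partial_f[enc$tests$dropped == "f"],
               w_f$F[2], tolerance = 1e-10)
})

test_that("encompassing degenerate and collinear cases behave", {
  d <- tibble::tibble(pi = seq(0, 1, length.out = 20),
                      noise = rnorm(20))
  d$y <- 2 * d$pi
  enc <- suppressWarnings(encompassing_test(d, "y", "pi", "noise"))
  expect_gt(enc$tests$partial_f[enc$tests$dropped == "pi"], 1e6)
  expect_lt(enc$tests$partial_f[enc$tests$dropped == "noise"], 10)
  expect_error(encompassing_test(dplyr::mutate(d, f = pi), "y", "pi", "f"),
               "collinear")
})

test_that("Welch t: direction, frozen two-sample example, df reduction", {
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t_statistic, 0)
  shift <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$t_statistic, -5)
  a <- c(27.5, 21, 19, 23.6, 17, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6,
         19, 21.7, 21.4)
  b <- c(27.1, 22, 20.8, 23.4, 23.4, 23.5, 25.8, 22, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5)
  # frozen from direct evaluation of the Welch formulas
  res <- welch_t(a, b)
  expect_equal(res$t_statistic, -2.707778, tolerance = 1e-6)
  expect_equal(res$df, 26.95275, tolerance = 1e-5)
  manual_t <- (mean(a) - mean(b)) / sqrt(var(a) / 15 + var(b) / 14)
  manual_df <- (var(a) / 15 + var(b) / 14)^2 /
    ((var(a) / 15)^2 / 14 + (var(b) / 14)^2 / 13)
  expect_equal(res$t_statistic, manual_t, tolerance = 1e-12)
  expect_equal(res$df, manual_df, tolerance = 1e-12)
  # equal sizes and variances: df collapses to the pooled n1 + n2 - 2
  x <- c(1, 2, 3, 4, 5)
  expect_equal(welch_t(x, x + 1)$df, 8)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("paired t: df bookkeeping and degenerate differences", {
  set.seed(4)
  before <- rnorm(10)
  res <- paired_t(before, before + rnorm(10))
  expect_equal(res$df, 9) # ten pairs
  zero <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_true(zero$undefined)
  expect_true(is.na(zero$t_statistic))
  alt <- paired_t(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(alt$t_statistic, 0)
  # oracle: one-sample t on the differences
  d2 <- rnorm(8)
  o <- t.test(d2, mu = 0)
  expect_equal(paired_t(rep(0, 8), d2)$t_statistic, unname(o$statistic))
})

test_that("Holm adjustment: hand-worked and boundary cases", {
  expect_equal(holm_correction(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correction(0.2, m = 1), 0.2)
  expect_equal(holm_correction(rep(1, 4)), rep(1, 4))
  # family larger than the supplied set
  expect_equal(holm_correction(c(0.01, 0.02), m = 5), c(0.05, 0.08))
  expect_equal(holm_correction(c(0.01, 0.02), m = 5),
               p.adjust(c(0.01, 0.02, 1, 1, 1), "holm")[1:2],
               tolerance = 1e-12)
  expect_error(holm_correction(c(0.5, 1.2)), "0, 1")
  expect_error(holm_correction(c(0.5, 0.2), m = 1), "Family size")
})

make_comparison_inputs <- function(n_per = 10, seed = 1) {
  withr::with_seed(seed, {
    groups <- rep(c("OB", "Low", "Medium", "High"), each = n_per)
    f_vals <- c(OB = 0, Low = 0.125, Medium = 0.219, High = 0.381)
    ret <- c(OB = 1, Low = 0.78, Medium = 0.68, High = 0.52)[groups] +
      rnorm(length(groups), 0, 0.05)
    lines <- tibble::tibble(
      line_id = sprintf("x%02d", seq_along(groups)), group = groups,
      expected_f = unname(f_vals[groups]),
      extinction_gen = ifelse(seq_along(groups) %% 13 == 0, 2L,
                              NA_integer_))
    diversity <- tibble::tibble(line_id = lines$line_id,
                                pi_sum = 1000 * ret,
                                pi_relative = ret / mean(ret[groups == "OB"]))
    slopes <- tibble::tibble(line_id = lines$line_id,
                             trait = "productivity",
                             slope = 0.1 * ret + rnorm(length(ret), 0, 0.01))
    deltas <- tibble::tibble(line_id = lines$line_id, medium = "stress",
                             delta = 0.2 * ret + rnorm(length(ret), 0, 0.02))
    list(lines = lines, diversity = diversity, slopes = slopes,
         deltas = deltas)
  })
}

test_that("compare_predictors reports models, contrasts and eligibility", {
  inp <- make_comparison_inputs()
  cmp <- compare_predictors(inp$slopes, inp$deltas, inp$diversity,
                            inp$lines)
  expect_s3_class(cmp, "predictor_comparison")
  expect_setequal(unique(cmp$models$response),
                  c("slope_productivity", "viability_stress"))
  expect_setequal(unique(cmp$models$predictor), c("pi", "expected_f"))
  # responses were built proportional to realised diversity: pi must win
  r2 <- function(resp, pred) {
    cmp$models$r_squared[cmp$models$response == resp &
                           cmp$models$predictor == pred]
  }
  expect_gt(r2("slope_productivity", "pi"),
            r2("slope_productivity", "expected_f"))
  expect_equal(cmp$n_eligible,
               sum(is.na(inp$lines$extinction_gen)))
  expect_setequal(cmp$contrasts$contrast,
                  c("OB_vs_Low", "OB_vs_Medium", "OB_vs_High",
                    "extinct_vs_survived"))
  expect_true(all(cmp$contrasts$p_holm >= cmp$contrasts$p_value - 1e-15))
  expect_named(glance(cmp),
               c("response", "r_squared_pi", "r_squared_expected_f",
                 "n_eligible"))
})

test_that("compare_predictors: exact fit and small-sample refusal", {
  inp <- make_comparison_inputs()
  exact <- dplyr::mutate(inp$slopes,
                         slope = inp$diversity$pi_relative * 2)
  cmp <- suppressWarnings(compare_predictors(exact, inp$deltas[0, ],
                                             inp$diversity, inp$lines))
  expect_equal(
    cmp$models$r_squared[cmp$models$predictor == "pi" &
                           cmp$models$response == "slope_productivity"],
    1, tolerance = 1e-12)
  few <- lapply(make_comparison_inputs(n_per = 2), function(x) x)
  expect_error(compare_predictors(few$slopes, few$deltas, few$diversity,
                                  few$lines), "eligible")
})
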