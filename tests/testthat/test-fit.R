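test_that("linear fits recover exact and degenerate cases", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit <- fit_linear(d, "y", "x")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"], 2,
               tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-12)

  dc <- tibble::tibble(x = rnorm(10), y = rep(3, 10))
  fitc <- fit_linear(dc, "y", "x")
  expect_equal(fitc$coefficients$estimate[2], 0, tolerance = 1e-12)
})

test_that("linear estimates match an independent normal-equations solve", {
  d <- lin_data(20, c(0.5, -1, 2), seed = 4)
  fit <- fit_linear(d, "y", c("x1", "x2", "x3"))
  X <- cbind(1, as.matrix(d[c("x1", "x2", "x3")]))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d$y)[, 1]
  expect_equal(fit$coefficients$estimate, unname(beta_oracle),
               tolerance = 1e-8)
  # residuals orthogonal to every design column
  r <- residuals(fit$model)
  expect_lt(max(abs(t(scale(X[, -1])) %*% r)) / nrow(d), 1e-6)
})

test_that("rank-deficient designs error naming the dependent column", {
  d <- lin_data(30, c(1, 0), seed = 2)
  d$x2 <- 2 * d$x1
  expect_error(fit_linear(d, "y", c("x1", "x2")), "x2")
})

test_that("logistic intercept-only fit equals the logit of the prevalence", {
  d <- tibble::tibble(y = rep(c(1, 0), c(3, 7)))
  fit <- fit_logistic(d, "y")
  expect_equal(fit$coefficients$estimate[1], log(0.3 / 0.7),
               tolerance = 1e-8)
})

test_that("logistic fits shrink to the null and flag separation", {
  d <- withr::with_seed(8, tibble::tibble(
    x = rnorm(2000), y = rbinom(2000, 1, 0.4)))
  fit <- fit_logistic(d, "y", "x")
  expect_lt(abs(fit$coefficients$estimate[2]), 0.12)
  expect_false(fit$separation)
  expect_gt(fit$coefficients$p_value[2], 0.01)

  dsep <- tibble::tibble(x = c(-(10:1), 1:10) / 3,
                         y = rep(c(0, 1), each = 10))
  expect_warning(fsep <- fit_logistic(dsep, "y", "x"), "separation")
  expect_true(fsep$separation)
})

test_that("nested fits never decrease the log-likelihood", {
  d <- withr::with_seed(3, tibble::tibble(
    x1 = rnorm(80), x2 = rnorm(80),
    y = rbinom(80, 1, plogis(0.5 * x1))))
  f0 <- fit_logistic(d, "y")
  f1 <- fit_logistic(d, "y", "x1")
  f2 <- fit_logistic(d, "y", c("x1", "x2"))
  expect_gte(f1$log_likelihood, f0$log_likelihood)
  expect_gte(f2$log_likelihood, f1$log_likelihood)
})

test_that("adjusted R-squared follows its closed form and ordering", {
  expect_equal(adjusted_r2(1, 50, 5), 1)
  expect_equal(adjusted_r2(0, 100, 0), 0)
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_error(adjusted_r2(0.5, 5, 4), "n > p \\+ 1")
  for (seed in 1:20) {
    v <- withr::with_seed(seed, c(runif(1), sample(20:200, 1), sample(0:10, 1)))
    adj <- adjusted_r2(v[1], v[2], v[3])
    expect_lte(adj, v[1])
    if (v[3] > 0 && v[1] < 1) expect_lt(adj, v[1])
  }
})

test_that("standardized estimates equal raw ones on standardized data and are scale-free", {
  d <- lin_data(200, c(0.4, -0.7), seed = 5)
  d_std <- dplyr::mutate(d, dplyr::across(dplyr::everything(),
                                          ~ as.numeric(scale(.x))))
  fit_std <- fit_linear(d_std, "y", c("x1", "x2"))
  se <- standardized_estimates(fit_std)
  raw <- fit_std$coefficients
  expect_equal(se$std_estimate[match("x1", se$term)],
               raw$estimate[raw$term == "x1"], tolerance = 1e-10)

  d10 <- dplyr::mutate(d, x1 = x1 * 10)
  s1 <- standardized_estimates(fit_linear(d, "y", c("x1", "x2")))
  s2 <- standardized_estimates(fit_linear(d10, "y", c("x1", "x2")))
  expect_equal(s1$std_estimate[match("x1", s1$term)],
               s2$std_estimate[match("x1", s2$term)], tolerance = 1e-10)

  # hand-computed sd ratio
  fit <- fit_linear(d, "y", c("x1", "x2"))
  b1 <- fit$coefficients$estimate[fit$coefficients$term == "x1"]
  expect_equal(s1$std_estimate[match("x1", s1$term)],
               b1 * sd(fit$data$x1) / sd(fit$data$y), tolerance = 1e-10)

  dz <- dplyr::mutate(d, x2 = 1)
  expect_error(standardized_estimates(fit_linear(dz, "y", c("x1", "x2"))))
})

test_that("tidy and glance expose the fit in broom style", {
  d <- lin_data(40, c(1), seed = 6)
  fit <- fit_linear(d, "y", "x1")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value"))
  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_true(is.na(gl$c_statistic))
  expect_equal(gl$r2_adj, fit$r2_adj)
})
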