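test_that("relevance verdicts apply the strict-below thresholds", {
  lin_low <- structure(list(family = "linear", r2_adj = 0.29),
                       class = "pred_fit")
  expect_false(characterize_model(lin_low)$relevant)
  log_edge <- structure(list(family = "logistic", c_statistic = 0.6),
                        class = "pred_fit")
  expect_true(characterize_model(log_edge)$relevant)

  d <- tibble::tibble(x = 1:30, y = 3 * (1:30) - 2)
  noiseless <- fit_linear(d, "y", "x")
  verdict <- characterize_model(noiseless)
  expect_equal(verdict$value, 1, tolerance = 1e-12)
  expect_true(verdict$relevant)
})

test_that("incremental inclusion orders by influence and matches nested tests", {
  d <- lin_data(260, c(0.7, 0.25, 0), seed = 71)
  d$y_pre <- withr::with_seed(72, rnorm(260))
  steps <- incremental_inclusion(d, "y", "y_pre", c("x1", "x2", "x3"))
  expect_equal(steps$term[1], "x1")  # most influential enters first
  expect_lt(steps$p_value[1], 0.001)
  expect_equal(nrow(steps), 3)
  expect_true(all(diff(c(0, steps$step)) == 1))

  # single retained covariate: the one step equals the direct nested test
  one <- incremental_inclusion(d, "y", "y_pre", "x1")
  red <- fit_linear(d, "y", "y_pre")
  full <- fit_linear(d, "y", c("y_pre", "x1"))
  expect_equal(one$p_value, f_change_test(red, full)$p_value,
               tolerance = 1e-12)
})

test_that("clean data pass the robustness check with stable metrics", {
  d <- lin_data(400, c(0.9, 0.5), noise_sd = 0.7, seed = 81)
  fit <- fit_linear(d, "y", c("x1", "x2"))
  # no aberrant rows by construction: the residual criterion excludes
  # (almost) nothing and the metric is stable
  rb <- robustness_check(fit, rule = "residual")
  expect_true(rb$robust)
  expect_lt(abs(rb$metric_before - rb$metric_after), 0.05)
  expect_lt(rb$n_excluded / rb$n_before, 0.05)
  expect_equal(rb$n_before - rb$n_after, rb$n_excluded)
})

test_that("a fit driven by gross outliers is flagged as not robust", {
  d <- withr::with_seed(82, tibble::tibble(x = rnorm(95), y = rnorm(95)))
  d <- dplyr::bind_rows(d, withr::with_seed(84, tibble::tibble(
    x = 10 + rnorm(5, sd = 0.1), y = 10 + rnorm(5, sd = 0.1))))
  fit <- fit_linear(d, "y", "x")
  expect_gt(fit$r2_adj, 0.5)  # apparent fit created by the outliers alone
  rb <- robustness_check(fit)
  expect_false(rb$robust)
  expect_lt(rb$metric_after, 0.2)
})

test_that("robustness is a no-op on its own retained subset when nothing is excluded", {
  d <- withr::with_seed(83, tibble::tibble(x = rnorm(100)))
  d$y <- 0.8 * d$x + runif(100, -1, 1)  # bounded errors: no residual outliers
  fit <- fit_linear(d, "y", "x")
  rb1 <- robustness_check(fit, rule = "residual")
  expect_equal(rb1$n_excluded, 0L)
  rb2 <- robustness_check(attr(rb1, "refit"), rule = "residual")
  expect_lt(abs(rb2$metric_after - rb1$metric_after), 1e-12)
})

test_that("bootstrap optimism is reproducible and coherent", {
  co <- make_null_cohort(120, 5, seed = 91)
  cfg <- run_config("y", ground_truth(co)$candidates, "y_pre",
                    bootstrap_reps = 15, seed = 91)
  o1 <- bootstrap_optimism(co, cfg)
  o2 <- bootstrap_optimism(co, cfg)
  expect_identical(glance(o1), glance(o2))
  expect_identical(o1$replicates, o2$replicates)
  expect_equal(nrow(o1$replicates) + o1$n_failed, o1$B)
  if (o1$optimism >= 0) expect_lte(o1$corrected, o1$apparent)
  expect_error(bootstrap_optimism(co, cfg, B = 0), "B >= 1")
})

test_that("with a fixed model the corrected metric approaches the held-out truth", {
  d <- withr::with_seed(93, {
    x <- rnorm(800)
    tibble::tibble(subject_id = 1:800, y_pre = rnorm(800), x = x,
                   y = 0.6 * x + rnorm(800))
  })
  cfg <- run_config("y", "x", "y_pre", bootstrap_reps = 40, seed = 93)
  fixed <- function(data, seed) fit_linear(data, "y", c("y_pre", "x"))
  opt <- bootstrap_optimism(d, cfg, pipeline = fixed)
  expect_lt(abs(opt$optimism), 0.05)

  # held-out oracle: the model's adjusted R2 on a fresh draw from the
  # same mechanism
  fresh <- withr::with_seed(94, {
    x <- rnorm(4000)
    tibble::tibble(y_pre = rnorm(4000), x = x, y = 0.6 * x + rnorm(4000))
  })
  oos <- conselect:::model_metric(opt$fit, fresh)
  expect_lt(abs(opt$corrected - oos), 0.05)
})

test_that("replicates with empty consensus fall back to the forced-only model", {
  co <- make_null_cohort(60, 3, seed = 95)
  cfg <- run_config("y", ground_truth(co)$candidates, "y_pre",
                    bootstrap_reps = 10, seed = 95,
                    screen_alpha = 1e-6)  # screening almost surely empty
  opt <- bootstrap_optimism(co, cfg)
  expect_equal(nrow(opt$replicates) + opt$n_failed, 10L)
  expect_equal(opt$fit$terms, "y_pre")  # original fell back too
})
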