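test_that("equation evaluation is intercept at zero and matches fit predictions", {
  eq <- prediction_equation(
    2.16, c(CGIC = -0.28, NRS3 = -0.31, PDQScore = 0.06, SQScore = -0.41),
    outcome = "optimal_responder_score")
  at0 <- evaluate_equation(eq, list(CGIC = 0, NRS3 = 0, PDQScore = 0,
                                    SQScore = 0))
  expect_equal(at0$linear_predictor, 2.16)

  expect_error(evaluate_equation(eq, list(CGIC = 1, NRS3 = 2)), "PDQScore")

  d <- lin_data(60, c(0.5, -0.9), seed = 1)
  fit <- fit_linear(d, "y", c("x1", "x2"))
  pred_eq <- evaluate_equation(fit, d)$linear_predictor
  expect_equal(pred_eq, unname(predict(fit, d)), tolerance = 1e-12)
})

test_that("logistic equations report both the score and the inverse-logit", {
  eq <- prediction_equation(0.4, c(a = 1), family = "logistic")
  out <- evaluate_equation(eq, list(a = 1))
  expect_equal(out$linear_predictor, 1.4)
  expect_equal(out$response, plogis(1.4))
})

test_that("the most influential predictor spans exactly 0-100 points", {
  eq1 <- prediction_equation(0, c(a = 2), outcome = "y")
  nom1 <- build_nomogram(eq1, ranges = list(a = c(0, 5)))
  expect_equal(nom1$axes$points_max, 100)
  expect_equal(nom1$total_points_max, 100)

  # influence ratio 2:1 -> point spans 100 and 50
  eq2 <- prediction_equation(1, c(a = 2, b = -1), outcome = "y")
  nom2 <- build_nomogram(eq2, ranges = list(a = c(0, 5), b = c(0, 5)))
  expect_equal(nom2$axes$points_max[nom2$axes$term == "a"], 100)
  expect_equal(nom2$axes$points_max[nom2$axes$term == "b"], 50)
  # negative coefficient: zero-points end is the range maximum
  expect_equal(nom2$axes$zero_value[nom2$axes$term == "b"], 5)

  expect_error(build_nomogram(eq2, ranges = list(a = c(2, 2), b = c(0, 5))),
               "Zero-width")
})

test_that("total points at the extremes hit the extreme predictions", {
  eq <- prediction_equation(10, c(a = 1.5, b = -2), outcome = "y")
  nom <- build_nomogram(eq, ranges = list(a = c(0, 4), b = c(1, 3)))
  # total = 0: every predictor at its minimum-contribution end
  lo <- total_points_to_response(nom, 0)
  expect_equal(lo$response,
               evaluate_equation(eq, list(a = 0, b = 3))$response,
               tolerance = 1e-12)
  hi <- total_points_to_response(nom, nom$total_points_max)
  expect_equal(hi$response,
               evaluate_equation(eq, list(a = 4, b = 1))$response,
               tolerance = 1e-12)
  expect_error(total_points_to_response(nom, nom$total_points_max + 1),
               "Total points")
})

test_that("nomogram read-off equals the direct equation on random points", {
  eq <- prediction_equation(
    44.6, c(sf12_mcs_pre = -0.65, pdq_score = -0.27, hads_d = -0.83),
    outcome = "MCS")
  ranges <- list(sf12_mcs_pre = c(10, 70), pdq_score = c(0, 38),
                 hads_d = c(0, 21))
  nom <- build_nomogram(eq, ranges = ranges)
  vals <- withr::with_seed(5, tibble::tibble(
    sf12_mcs_pre = runif(500, 10, 70),
    pdq_score = runif(500, 0, 38),
    hads_d = runif(500, 0, 21)))
  direct <- evaluate_equation(eq, vals)$response
  readoff <- vapply(seq_len(nrow(vals)), function(i) {
    total <- points_for(nom, vals[i, ])
    total_points_to_response(nom, total$points[total$term == "total"])$response
  }, numeric(1))
  expect_equal(readoff, direct, tolerance = 1e-10)
})

test_that("reordering predictors never changes any point value", {
  eq_ab <- prediction_equation(0, c(a = 1, b = 2), outcome = "y")
  eq_ba <- prediction_equation(0, c(b = 2, a = 1), outcome = "y")
  ranges <- list(a = c(0, 3), b = c(0, 3))
  p1 <- points_for(build_nomogram(eq_ab, ranges), list(a = 1.7, b = 0.4))
  p2 <- points_for(build_nomogram(eq_ba, ranges), list(a = 1.7, b = 0.4))
  expect_equal(dplyr::arrange(p1, term), dplyr::arrange(p2, term))
})

test_that("equation text renders in the published style", {
  eq <- prediction_equation(44.6, c(mcs_pre = -0.65, pdq = -0.27),
                            outcome = "MCS")
  expect_equal(format_equation(eq), "MCS = 44.6 - 0.65*mcs_pre - 0.27*pdq")
})
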