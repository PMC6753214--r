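test_that("forward selection adds the strongest predictor first, matching a one-step oracle", {
  d <- lin_data(120, c(0, 0, 0.8, 0, 0), seed = 21)
  cands <- paste0("x", 1:5)
  sel <- forward_select(d, "y", character(), cands)
  expect_equal(sel$term[1], "x3")
  # one-step oracle: the first entrant minimizes the residual sum of squares
  rss1 <- vapply(cands, function(v) rss_of(d, "y", v), numeric(1))
  expect_equal(sel$term[1], names(which.min(rss1)))
})

test_that("forward and backward match exhaustive best-subset on orthogonal designs", {
  for (seed in 1:6) {
    Q <- orthonormal_design(48, 4, seed = seed)
    d <- withr::with_seed(100 + seed, {
      beta <- sample(c(0, 0, 0.4, 0.8))
      dd <- tibble::as_tibble(as.data.frame(Q))
      names(dd) <- paste0("x", 1:4)
      dd$y <- as.numeric(Q %*% beta) + rnorm(48, sd = 0.6)
      dd
    })
    cands <- paste0("x", 1:4)
    fwd <- forward_select(d, "y", character(), cands)
    bwd <- backward_select(d, "y", character(), cands)
    expect_setequal(fwd$term, bwd$term)
    if (nrow(fwd) > 0) {
      expect_equal(sort(fwd$term), best_subset(d, "y", cands, nrow(fwd)))
    }
  }
})

test_that("backward selection never removes forced covariates", {
  d <- withr::with_seed(31, tibble::tibble(
    y_pre = rnorm(100), x1 = rnorm(100), x2 = rnorm(100),
    y = rnorm(100)))  # baseline truly unrelated: its p is large
  sel <- backward_select(d, "y", "y_pre", c("x1", "x2"))
  fit <- selection_fit(sel)
  expect_true("y_pre" %in% fit$terms)
  expect_false("y_pre" %in% sel$term)  # forced, not "selected"
  expect_gt(fit$coefficients$p_value[fit$coefficients$term == "y_pre"], 0.05)
})

test_that("lasso limit cases: infinite penalty empties, zero penalty equals OLS", {
  d <- lin_data(80, c(0.7, -0.4, 0), seed = 41)
  cands <- paste0("x", 1:3)
  hi <- lasso_select(d, "y", character(), cands, lambda = 1e3)
  expect_equal(nrow(hi), 0)
  lo <- lasso_select(d, "y", character(), cands, lambda = 0)
  ols <- fit_linear(d, "y", cands)
  b_lasso <- attr(lo, "lasso_coef")[cands]
  b_ols <- setNames(ols$coefficients$estimate[-1], cands)
  expect_equal(b_lasso, b_ols, tolerance = 1e-4)
})

test_that("lasso on an orthonormal column equals closed-form soft-thresholding", {
  n <- 200
  x <- orthonormal_design(n, 1, seed = 51)[, 1]
  x <- x - mean(x); x <- x / sqrt(mean(x^2))  # glmnet's internal scaling
  y <- withr::with_seed(52, 0.5 * x + rnorm(n, sd = 0.4))
  y <- y - mean(y)
  d <- tibble::tibble(x = x, y = y)
  b_ols <- sum(x * y) / sum(x^2)
  for (lam in c(0.05, 0.2, 0.45, 0.8)) {
    sel <- lasso_select(d, "y", character(), "x", lambda = lam)
    expected <- sign(b_ols) * max(abs(b_ols) - lam, 0)
    expect_equal(unname(attr(sel, "lasso_coef")["x"]), expected,
                 tolerance = 1e-4)
  }
})

test_that("lasso refuses binary outcomes explicitly", {
  d <- tibble::tibble(x = rnorm(40), y = rbinom(40, 1, 0.5))
  expect_error(lasso_select(d, "y", character(), "x"), "linear")
})

test_that("the consensus rule retains two-weak-one-strong candidates", {
  u <- c("cgic", "nrs3", "pdq", "sq")
  fwd <- fake_selection("forward", c("cgic", "nrs3"), c(0.01, 0.2), u)
  bwd <- fake_selection("backward", c("cgic", "pdq"), c(0.0005, 0.04), u)
  las <- fake_selection("lasso", "pdq", 0.3, u)
  cons <- consensus_select(list(fwd, bwd, las))
  # cgic: weak in forward+backward, strong in backward -> retained
  expect_true(cons$retained[cons$candidate == "cgic"])
  # pdq: weak only in backward -> rejected; nrs3: weak in none strong in none
  expect_false(cons$retained[cons$candidate == "pdq"])
  expect_false(cons$retained[cons$candidate == "nrs3"])
  expect_equal(consensus_retained(cons), "cgic")

  # selected by one method only, however strong, fails two-out-of-three
  one <- consensus_select(list(
    fake_selection("forward", "cgic", 1e-6, u),
    fake_selection("backward", character(), numeric(), u),
    fake_selection("lasso", character(), numeric(), u)))
  expect_false(any(one$retained))

  # dominating case: strong everywhere
  all3 <- consensus_select(list(
    fake_selection("forward", "sq", 5e-4, u),
    fake_selection("backward", "sq", 5e-4, u),
    fake_selection("lasso", "sq", 5e-4, u)))
  expect_equal(consensus_retained(all3), "sq")
})

test_that("two-process consensus (logistic: no lasso) needs both weak and one strong", {
  u <- c("a", "b")
  both <- consensus_select(list(
    fake_selection("forward", "a", 0.0004, u),
    fake_selection("backward", "a", 0.03, u)))
  expect_equal(consensus_retained(both), "a")
  one_of_two <- consensus_select(list(
    fake_selection("forward", "a", 0.0004, u),
    fake_selection("backward", character(), numeric(), u)))
  expect_false(any(one_of_two$retained))
})

test_that("consensus is monotone in p and contained in the union of selections", {
  u <- paste0("c", 1:6)
  base_ps <- withr::with_seed(61, replicate(3, runif(6) * 0.2, simplify = FALSE))
  mk <- function(ps) list(
    fake_selection("forward", u[ps[[1]] < 0.15], ps[[1]][ps[[1]] < 0.15], u),
    fake_selection("backward", u[ps[[2]] < 0.15], ps[[2]][ps[[2]] < 0.15], u),
    fake_selection("lasso", u[ps[[3]] < 0.15], ps[[3]][ps[[3]] < 0.15], u))
  cons <- consensus_select(mk(base_ps))
  union_sel <- unique(unlist(purrr::map(mk(base_ps), "term")))
  expect_true(all(consensus_retained(cons) %in% union_sel))

  lowered <- base_ps
  lowered[[1]][2] <- 1e-6  # lowering any p must never drop a candidate
  cons_low <- consensus_select(mk(lowered))
  expect_true(all(consensus_retained(cons) %in% consensus_retained(cons_low)))

  expect_error(
    consensus_select(list(fake_selection("forward", "a", 0.01, c("a", "b")),
                          fake_selection("backward", "a", 0.01, c("a", "z")))),
    "universes")
})
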