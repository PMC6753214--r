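#' Fit a linear or logistic prediction model
#'
#' The workhorse fit behind every pipeline stage. `fit_linear()` fits an
#' ordinary least-squares model, `fit_logistic()` a maximum-likelihood
#' logistic model (iteratively reweighted least squares, convergence
#' tolerance 1e-10, at most 100 iterations); `fit_model()` dispatches on
#' the outcome: exactly two distinct values is treated as binary. Rows
#' with a missing value in the outcome or any term are dropped
#' (complete-case analysis per model); the rows actually used are kept in
#' the returned object so downstream metrics and standardization always
#' refer to them.
#'
#' Wald p-values use the t distribution with `n - p - 1` degrees of
#' freedom for linear fits (small-sample correctness) and the normal
#' approximation for logistic fits. Perfect or quasi-perfect separation in
#' a logistic fit (any standardized coefficient magnitude above 15, or
#' non-convergence) raises a warning and sets the `separation` flag.
#'
#' @param data Cohort or data frame.
#' @param outcome Name of the outcome column.
#' @param terms Character vector of covariate names (may be empty for an
#'   intercept-only model).
#' @param family `"auto"`, `"linear"` or `"logistic"`.
#' @return An object of class `pred_fit`: a list with elements `family`,
#'   `outcome`, `terms`, `n`, `p`, `coefficients` (tibble `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `log_likelihood`,
#'   `residual_variance` (linear), `r2`, `r2_adj` (linear),
#'   `c_statistic` (logistic), `separation` (logistic), `model` (the
#'   underlying `lm`/`glm`) and `data` (complete-case rows used).
#'   Supports [tidy()], [glance()], [predict()].
#' @examples
#' d <- data.frame(y = rnorm(30), x1 = rnorm(30), x2 = rnorm(30))
#' fit <- fit_linear(d, "y", c("x1", "x2"))
#' tidy(fit)
#' glance(fit)
#' @export
fit_model <- function(data, outcome, terms = character(),
                      family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  check_columns(data, c(outcome, terms))
  if (family == "auto") family <- infer_family(data[[outcome]])
  if (family == "linear") fit_linear(data, outcome, terms)
  else fit_logistic(data, outcome, terms)
}

#' @rdname fit_model
#' @export
fit_linear <- function(data, outcome, terms = character()) {
  d <- complete_model_frame(data, outcome, terms)
  n <- nrow(d); p <- length(terms)
  if (n <= p + 1) {
    abort(sprintf("Need n > p + 1 complete cases (n = %d, p = %d).", n, p))
  }
  fml <- model_formula(outcome, terms)
  m <- lm(fml, data = d, singular.ok = TRUE)
  check_rank(m, terms)
  sm <- withCallingHandlers(
    summary(m),
    warning = function(w) {
      # noiseless fixtures legitimately produce exact fits
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients  # t statistics, p from t with n - p - 1 df
  rss <- sum(residuals(m)^2)
  tss <- sum((d[[outcome]] - mean(d[[outcome]]))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  new_pred_fit(
    family = "linear", outcome = outcome, terms = terms, n = n, p = p,
    coefficients = coef_tibble(co),
    log_likelihood = as.numeric(logLik(m)),
    residual_variance = rss / (n - p - 1),
    r2 = r2,
    r2_adj = if (p == 0) r2 else adjusted_r2(r2, n, p),
    model = m, data = d
  )
}

#' @rdname fit_model
#' @export
fit_logistic <- function(data, outcome, terms = character()) {
  d <- complete_model_frame(data, outcome, terms)
  n <- nrow(d); p <- length(terms)
  if (n <= p + 1) {
    abort(sprintf("Need n > p + 1 complete cases (n = %d, p = %d).", n, p))
  }
  y <- as_binary01(d[[outcome]])
  if (length(unique(y)) < 2) {
    abort(sprintf("Outcome `%s` has only one class among complete cases.",
                  outcome))
  }
  d[[outcome]] <- y
  fml <- model_formula(outcome, terms)
  m <- withCallingHandlers(
    glm(fml, data = d, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  check_rank(m, terms)
  sm <- summary(m)
  sds <- vapply(terms, function(v) sd(d[[v]]), numeric(1))
  est <- coef(m)[terms]
  separation <- !m$converged ||
    (length(terms) > 0 && any(abs(est * sds) > 15, na.rm = TRUE))
  if (separation) {
    warn(sprintf(
      "Possible (quasi-)separation in logistic fit of `%s`: estimates diverge.",
      outcome))
  }
  lp <- as.numeric(predict(m, type = "link"))
  new_pred_fit(
    family = "logistic", outcome = outcome, terms = terms, n = n, p = p,
    coefficients = coef_tibble(sm$coefficients),
    log_likelihood = as.numeric(logLik(m)),
    c_statistic = c_statistic(lp, y),
    separation = separation,
    model = m, data = d
  )
}

new_pred_fit <- function(...) {
  structure(list(...), class = "pred_fit")
}

complete_model_frame <- function(data, outcome, terms) {
  data <- tibble::as_tibble(data)
  if (outcome %in% terms) {
    abort(sprintf("`%s` cannot be both outcome and covariate.", outcome))
  }
  cols <- c(outcome, terms)
  d <- data[cols]
  d[complete.cases(d), , drop = FALSE]
}

model_formula <- function(outcome, terms) {
  rhs <- if (length(terms) == 0) "1" else
    paste(sprintf("`%s`", terms), collapse = " + ")
  as.formula(sprintf("`%s` ~ %s", outcome, rhs))
}

check_rank <- function(m, terms) {
  bad <- names(coef(m))[is.na(coef(m))]
  if (length(bad) > 0) {
    abort(sprintf("Design is rank deficient; dependent column(s): %s",
                  paste(gsub("`", "", bad), collapse = ", ")))
  }
  invisible(m)
}

coef_tibble <- function(co) {
  tibble::tibble(
    term = gsub("`", "", rownames(co)),
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    p_value = unname(co[, 4])
  )
}

as_binary01 <- function(y) {
  vals <- sort(unique(y))
  if (length(vals) != 2) {
    abort("Binary outcome must take exactly two distinct values.")
  }
  as.integer(y == vals[2])
}

#' @export
print.pred_fit <- function(x, ...) {
  cat(sprintf("<pred_fit> %s model: %s ~ %s  (n = %d)\n",
              x$family, x$outcome,
              if (x$p == 0) "1" else paste(x$terms, collapse = " + "),
              x$n))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy pred_fit
#' @export
tidy.pred_fit <- function(x, ...) x$coefficients

#' @method glance pred_fit
#' @export
glance.pred_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n = x$n, p = x$p,
    r2 = x$r2 %||% NA_real_,
    r2_adj = x$r2_adj %||% NA_real_,
    c_statistic = x$c_statistic %||% NA_real_,
    log_likelihood = x$log_likelihood
  )
}

#' @export
predict.pred_fit <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  lp <- if (is.null(newdata)) {
    if (object$family == "logistic") {
      as.numeric(predict(object$model, type = "link"))
    } else {
      as.numeric(fitted(object$model))
    }
  } else {
    b <- object$coefficients$estimate
    names(b) <- object$coefficients$term
    check_columns(newdata, object$terms, "newdata")
    lp <- rep(b[["(Intercept)"]], nrow(newdata))
    for (v in object$terms) lp <- lp + b[[v]] * newdata[[v]]
    lp
  }
  if (type == "response" && object$family == "logistic") inv_logit(lp) else lp
}

#' Adjusted coefficient of determination
#'
#' The part of outcome variability explained by the prediction, penalized
#' for the number of fitted covariates:
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`. Equals 1 for perfect prediction
#' and 0 (or below) when the model explains nothing.
#'
#' @param r2 Unadjusted R-squared in `[0, 1]`.
#' @param n Number of cases.
#' @param p Number of fitted covariates (excluding the intercept).
#' @return The adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p + 1)) abort("adjusted_r2 requires n > p + 1.")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Concordance statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen positive subject receives a
#' higher score than a randomly chosen negative one, counting ties as one
#' half: over all positive/negative pairs,
#' `(concordant + 0.5 * tied) / total`. Equals the trapezoidal area under
#' the ROC curve and `U / (n1 * n0)` for the Mann-Whitney U statistic.
#' 0.5 means no discrimination, 1 perfect discrimination.
#'
#' @param scores Numeric vector of predicted scores (any strictly
#'   increasing transform leaves the result unchanged).
#' @param labels Binary vector (two distinct values; the larger is the
#'   positive class).
#' @return The c-statistic in `[0, 1]`.
#' @examples
#' c_statistic(c(0.9, 0.3, 0.6, 0.6), c(1, 0, 1, 0)) # 0.875
#' @export
c_statistic <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(unique(labels)) != 2) {
    abort("Both outcome classes must be present to compute a c-statistic.")
  }
  y <- as_binary01(labels)
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  cmp <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(cmp)
}

#' Nested-model improvement tests
#'
#' `f_change_test()` compares two nested linear fits on the same rows via
#' the F-change statistic from their residual sums of squares;
#' `likelihood_ratio_test()` compares two nested logistic fits via twice
#' the log-likelihood difference against a chi-squared distribution. Both
#' quantify whether the added covariates significantly improve the
#' prediction; identical models give a statistic of 0 and p = 1.
#'
#' @param reduced,full `pred_fit` objects; `reduced$terms` must be a
#'   subset of `full$terms`, both fit on the same number of rows and of
#'   the appropriate family.
#' @return A one-row tibble with `statistic`, `df1`/`df` and `df2`,
#'   `p_value`.
#' @export
f_change_test <- function(reduced, full) {
  check_nested(reduced, full, "linear")
  n <- full$n
  rss_r <- sum(residuals(reduced$model)^2)
  rss_f <- sum(residuals(full$model)^2)
  d <- full$p - reduced$p
  df2 <- n - full$p - 1
  if (d == 0) {
    return(tibble::tibble(statistic = 0, df1 = 0L, df2 = df2, p_value = 1))
  }
  f <- ((rss_r - rss_f) / d) / (rss_f / df2)
  f <- max(f, 0)
  tibble::tibble(statistic = f, df1 = as.integer(d), df2 = df2,
                 p_value = pf(f, d, df2, lower.tail = FALSE))
}

#' @rdname f_change_test
#' @export
likelihood_ratio_test <- function(reduced, full) {
  check_nested(reduced, full, "logistic")
  d <- full$p - reduced$p
  stat <- max(2 * (full$log_likelihood - reduced$log_likelihood), 0)
  if (d == 0) {
    return(tibble::tibble(statistic = 0, df = 0L, p_value = 1))
  }
  tibble::tibble(statistic = stat, df = as.integer(d),
                 p_value = pchisq(stat, d, lower.tail = FALSE))
}

check_nested <- function(reduced, full, family) {
  if (reduced$family != family || full$family != family) {
    abort(sprintf("Both fits must be %s models.", family))
  }
  if (!all(reduced$terms %in% full$terms)) {
    abort("Models are not nested: reduced terms are not a subset of the full terms.")
  }
  if (reduced$n != full$n) {
    abort("Models were fit on different numbers of rows.")
  }
  invisible(TRUE)
}

#' Standardized parameter estimates
#'
#' Puts estimates on a comparable scale across covariates: for linear
#' models `estimate * sd(x) / sd(y)` (the classic standardized beta), for
#' logistic models `estimate * sd(x)` (change in log-odds per SD of the
#' covariate). Standard deviations are taken over the complete-case rows
#' the model was actually fit on.
#'
#' @param fit A `pred_fit`.
#' @param data Optional data frame to standardize against; defaults to the
#'   rows used by the fit.
#' @return A tibble `term`, `estimate`, `std_estimate`, sorted by
#'   decreasing `abs(std_estimate)` (most to least influential).
#' @export
standardized_estimates <- function(fit, data = NULL) {
  d <- data %||% fit$data
  sdy <- sd(d[[fit$outcome]])
  out <- fit$coefficients |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(
      sd_x = purrr::map_dbl(.data$term, ~ sd(d[[.x]])),
      std_estimate = if (fit$family == "linear") {
        .data$estimate * .data$sd_x / sdy
      } else {
        .data$estimate * .data$sd_x
      }
    )
  if (any(out$sd_x == 0)) {
    abort(sprintf("Zero-variance covariate(s): %s",
                  paste(out$term[out$sd_x == 0], collapse = ", ")))
  }
  out |>
    dplyr::arrange(dplyr::desc(abs(.data$std_estimate))) |>
    dplyr::select("term", "estimate", "std_estimate")
}
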