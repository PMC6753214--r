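#' Bivariable screening of candidate predictors
#'
#' Stage 1 of the predictor-identification algorithm. Each candidate is
#' assessed in its own bivariable model of the outcome that always
#' includes the baseline value of the outcome
#' (`outcome ~ baseline + candidate`), linear or logistic according to the
#' outcome's scale. Candidates whose Wald p-value falls below `alpha` are
#' retained for the collinearity and consensus stages; the baseline
#' covariate itself is never screened out. For each candidate the
#' relationship with the outcome is also mapped ([relationship_map()]):
#' the advisory nonlinearity/non-monotonicity flags are reported, not used
#' to exclude — they exist to judge the validity of the consecutively
#' applied (generalized) linear models.
#'
#' @param data Cohort or data frame.
#' @param outcome Outcome column name.
#' @param baseline Name of the baseline value of the outcome (forced into
#'   every model).
#' @param candidates Character vector of candidate names.
#' @param alpha Retention threshold on the candidate's p-value
#'   (default 0.05).
#' @param family `"auto"` (default), `"linear"` or `"logistic"`.
#' @return A tibble of class `screen_result`, one row per candidate:
#'   `candidate`, `estimate`, `p_value`, `sign`, `pearson_r`,
#'   `spearman_rho`, `monotone_nonlinear`, `non_monotone`, `n`,
#'   `retained`. Attribute `"retained"` holds the retained names.
#' @export
bivariable_screen <- function(data, outcome, baseline, candidates,
                              alpha = 0.05,
                              family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  check_columns(data, c(outcome, baseline, candidates))
  if (outcome %in% candidates) {
    abort("A candidate column is identical to the outcome.")
  }
  if (family == "auto") family <- infer_family(data[[outcome]])
  rows <- purrr::map(candidates, function(cand) {
    fit <- fit_model(data, outcome, c(baseline, cand), family = family)
    co <- fit$coefficients[fit$coefficients$term == cand, ]
    d <- fit$data
    rel <- if (nrow(d) >= 10 && sd(d[[cand]]) > 0 && sd(d[[outcome]]) > 0) {
      relationship_map(d[[cand]], d[[outcome]])
    } else {
      tibble::tibble(pearson_r = NA_real_, spearman_rho = NA_real_,
                     quadratic_p = NA_real_,
                     monotone_nonlinear = NA, non_monotone = NA)
    }
    tibble::tibble(
      candidate = cand,
      estimate = co$estimate,
      p_value = co$p_value,
      sign = sign(co$estimate),
      pearson_r = rel$pearson_r,
      spearman_rho = rel$spearman_rho,
      monotone_nonlinear = rel$monotone_nonlinear,
      non_monotone = rel$non_monotone,
      n = fit$n
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(retained = .data$p_value < alpha)
  attr(out, "retained") <- out$candidate[out$retained]
  attr(out, "alpha") <- alpha
  attr(out, "family") <- family
  class(out) <- c("screen_result", class(out))
  out
}

#' @rdname bivariable_screen
#' @param x A `screen_result`.
#' @export
retained_candidates <- function(x) attr(x, "retained")

#' Map the shape of a bivariate relationship
#'
#' Diagnostics for judging whether a linear model is an adequate
#' description of a candidate-outcome relationship: Pearson r (linear
#' association), Spearman rho (monotone association), and the p-value of a
#' quadratic term in `y ~ x + x^2`. Two advisory flags are derived:
#' `monotone_nonlinear` when `abs(rho) - abs(r) > 0.1` (monotone but
#' appreciably non-linear) and `non_monotone` when the quadratic term is
#' significant at 0.05 while `abs(rho) < 0.3` (curvature without an
#' overall monotone trend).
#'
#' @param x,y Numeric vectors of equal length, `n >= 10`, each with
#'   positive variance.
#' @return A one-row tibble: `pearson_r`, `spearman_rho`, `quadratic_p`,
#'   `monotone_nonlinear`, `non_monotone`.
#' @export
relationship_map <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) abort("relationship_map needs n >= 10.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance input.")
  r <- cor(x, y)
  rho <- cor(x, y, method = "spearman")
  d <- data.frame(.y = y, .x = x, .x2 = x^2)
  quad_p <- if (sd(d$.x2) == 0 || qr(cbind(1, x, x^2))$rank < 3) {
    NA_real_
  } else {
    m <- lm(.y ~ .x + .x2, data = d)
    sm <- withCallingHandlers(
      summary(m),
      warning = function(w) {
        # exact functional relationships are legitimate inputs here
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    sm$coefficients[".x2", 4]
  }
  tibble::tibble(
    pearson_r = r,
    spearman_rho = rho,
    quadratic_p = quad_p,
    monotone_nonlinear = (abs(rho) - abs(r)) > 0.1,
    non_monotone = !is.na(quad_p) && quad_p < 0.05 && abs(rho) < 0.3
  )
}
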