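#' Encode a prediction equation
#'
#' A minimal container for a published or hand-specified prediction
#' equation — an intercept plus per-covariate coefficients — so that
#' equations reported in the literature can be evaluated and turned into
#' nomograms without refitting. The evaluator is link-agnostic: for a
#' binary outcome it reports both the linear score and its inverse-logit.
#'
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric vector of per-covariate estimates.
#' @param family `"linear"` or `"logistic"`.
#' @param outcome Optional outcome label used in printed equations.
#' @return An object of class `pred_equation`.
#' @examples
#' eq <- prediction_equation(
#'   44.6, c(sf12_mcs_pre = -0.65, pdq_score = -0.27, hads_d = -0.83),
#'   outcome = "MCS"
#' )
#' evaluate_equation(eq, list(sf12_mcs_pre = 0, pdq_score = 0, hads_d = 0))
#' @export
prediction_equation <- function(intercept, coefficients,
                                family = c("linear", "logistic"),
                                outcome = "y") {
  family <- match.arg(family)
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("`coefficients` must be a fully named numeric vector.")
  }
  structure(list(
    intercept = as.numeric(intercept),
    coefficients = coefficients,
    terms = names(coefficients),
    family = family,
    outcome = outcome
  ), class = "pred_equation")
}

#' @rdname prediction_equation
#' @param x A `pred_fit` or `pred_equation`.
#' @export
as_equation <- function(x) {
  if (inherits(x, "pred_equation")) return(x)
  if (!inherits(x, "pred_fit")) abort("Cannot coerce to a prediction equation.")
  b <- setNames(x$coefficients$estimate, x$coefficients$term)
  prediction_equation(b[["(Intercept)"]], b[x$terms],
                      family = x$family, outcome = x$outcome)
}

#' @export
print.pred_equation <- function(x, ...) {
  cat("<pred_equation>", format_equation(x), "\n")
  invisible(x)
}

#' Evaluate a prediction equation at given covariate values
#'
#' Computes `intercept + sum(estimate * value)` for each supplied row of
#' covariate values. Logistic-family equations additionally report the
#' inverse-logit of the score; for linear equations the response equals
#' the score.
#'
#' @param object A `pred_fit` or [prediction_equation()].
#' @param values A named list/vector or data frame supplying a value for
#'   every covariate of the equation (a missing one is an error naming
#'   it).
#' @return A tibble with one row per input row: `linear_predictor`,
#'   `response`.
#' @export
evaluate_equation <- function(object, values) {
  eq <- as_equation(object)
  if (!is.data.frame(values)) values <- tibble::as_tibble(as.list(values))
  missing <- setdiff(eq$terms, names(values))
  if (length(missing) > 0) {
    abort(sprintf("No value supplied for covariate(s): %s",
                  paste(missing, collapse = ", ")))
  }
  lp <- rep(eq$intercept, nrow(values))
  for (v in eq$terms) lp <- lp + eq$coefficients[[v]] * values[[v]]
  tibble::tibble(
    linear_predictor = lp,
    response = if (eq$family == "logistic") inv_logit(lp) else lp
  )
}

#' Render a prediction equation as text
#'
#' @param object A `pred_fit` or `pred_equation`.
#' @param digits Significant digits for the printed coefficients.
#' @return A single string like `"MCS = 44.6 - 0.65*sf12_mcs_pre - ..."`.
#' @export
format_equation <- function(object, digits = 3) {
  eq <- as_equation(object)
  fmt <- function(x) format(signif(x, digits), trim = TRUE)
  parts <- sprintf(" %s %s*%s",
                   ifelse(eq$coefficients < 0, "-", "+"),
                   fmt(abs(eq$coefficients)), eq$terms)
  paste0(eq$outcome, " = ", fmt(eq$intercept), paste(parts, collapse = ""))
}

#' Build a nomogram from a fitted model or equation
#'
#' Converts a prediction equation into the classic points-based nomogram:
#' each predictor's observed (or instrument-defined) range is mapped
#' affinely onto a points axis, anchored so that the most influential
#' predictor — the one with the largest `abs(estimate) * range width`,
#' i.e. the longest line — spans exactly 0 to 100 points, and every
#' predictor's zero-points end is the value minimizing its contribution
#' to the score. Summing the per-predictor points gives total points,
#' which map affinely back to the linear predictor, so a nomogram
#' read-off reproduces the direct equation prediction exactly.
#'
#' @param object A `pred_fit` (ranges default to the fitted cohort's
#'   observed min/max) or a `pred_equation` (ranges must be supplied).
#' @param ranges Optional named list of `c(min, max)` per covariate,
#'   overriding observed ranges (e.g. `c(0, 10)` for an NRS).
#' @return An object of class `nomogram_table`: list with `axes` (tibble
#'   `term`, `estimate`, `range_min`, `range_max`, `influence`,
#'   `zero_value`, `points_max`), `points_per_unit` of the linear
#'   predictor (`scale`), `lp_offset`, `family`, `outcome`,
#'   `total_points_max`. See [points_for()], [total_points_to_response()]
#'   and [autoplot()].
#' @export
build_nomogram <- function(object, ranges = NULL) {
  eq <- as_equation(object)
  obs_range <- function(v) {
    if (!is.null(ranges) && v %in% names(ranges)) {
      as.numeric(ranges[[v]])
    } else if (inherits(object, "pred_fit")) {
      range(object$data[[v]])
    } else {
      abort(sprintf("No range supplied for covariate `%s`.", v))
    }
  }
  axes <- purrr::map_dfr(eq$terms, function(v) {
    r <- obs_range(v)
    if (!(r[2] > r[1])) abort(sprintf("Zero-width range for `%s`.", v))
    b <- eq$coefficients[[v]]
    tibble::tibble(
      term = v, estimate = b, range_min = r[1], range_max = r[2],
      influence = abs(b) * (r[2] - r[1]),
      zero_value = if (b >= 0) r[1] else r[2]
    )
  })
  max_inf <- max(axes$influence)
  if (max_inf <= 0) abort("All predictors have zero influence.")
  axes$points_max <- 100 * axes$influence / max_inf
  lp_offset <- eq$intercept +
    sum(purrr::map2_dbl(axes$estimate, axes$zero_value, `*`))
  structure(list(
    axes = axes,
    scale = max_inf / 100,  # linear-predictor units per point
    lp_offset = lp_offset,
    family = eq$family,
    outcome = eq$outcome,
    total_points_max = sum(axes$points_max)
  ), class = "nomogram_table")
}

#' @export
print.nomogram_table <- function(x, ...) {
  cat(sprintf("<nomogram_table> %s (%s family), total points 0-%.1f\n",
              x$outcome, x$family, x$total_points_max))
  print(x$axes)
  invisible(x)
}

#' @method tidy nomogram_table
#' @export
tidy.nomogram_table <- function(x, ...) x$axes

#' Per-predictor points for given covariate values
#'
#' @param nomogram A `nomogram_table`.
#' @param values Named list/vector or data frame of covariate values
#'   (one row).
#' @return A tibble `term`, `value`, `points`, with the total appended as
#'   term `"total"`.
#' @export
points_for <- function(nomogram, values) {
  values <- as.list(values)
  ax <- nomogram$axes
  missing <- setdiff(ax$term, names(values))
  if (length(missing) > 0) {
    abort(sprintf("No value supplied for covariate(s): %s",
                  paste(missing, collapse = ", ")))
  }
  pts <- purrr::pmap_dbl(ax, function(term, estimate, zero_value, ...) {
    estimate * (values[[term]] - zero_value) / nomogram$scale
  })
  out <- tibble::tibble(term = ax$term,
                        value = unlist(values[ax$term]),
                        points = pts)
  dplyr::bind_rows(out, tibble::tibble(term = "total", value = NA,
                                       points = sum(pts)))
}

#' Read a predicted response off the nomogram's total-points axis
#'
#' Inverts the affine total-points map back to the linear predictor (and,
#' for logistic equations, the inverse-logit response); round-trips
#' exactly with [evaluate_equation()].
#'
#' @param nomogram A `nomogram_table`.
#' @param total Numeric vector of total points within
#'   `[0, total_points_max]`.
#' @return A tibble `total_points`, `linear_predictor`, `response`.
#' @export
total_points_to_response <- function(nomogram, total) {
  tol <- 1e-8 * max(1, nomogram$total_points_max)
  if (any(total < -tol | total > nomogram$total_points_max + tol)) {
    abort(sprintf("Total points must lie in [0, %.2f].",
                  nomogram$total_points_max))
  }
  lp <- nomogram$lp_offset + total * nomogram$scale
  tibble::tibble(
    total_points = total,
    linear_predictor = lp,
    response = if (nomogram$family == "logistic") inv_logit(lp) else lp
  )
}
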