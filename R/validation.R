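#' Relevance verdict for a fitted model
#'
#' Characterizes a model by its family-appropriate performance metric and
#' flags it as irrelevant when the metric falls below the configured
#' threshold: adjusted R-squared below `r2_relevance` (default 0.3) for
#' linear models, c-statistic below `c_relevance` (default 0.6) for
#' logistic models. The thresholds are strict: a model sitting exactly on
#' the threshold counts as relevant.
#'
#' @param fit A `pred_fit`.
#' @param r2_relevance,c_relevance Relevance thresholds.
#' @return A one-row tibble: `family`, `metric`, `value`, `threshold`,
#'   `relevant`.
#' @export
characterize_model <- function(fit, r2_relevance = 0.3, c_relevance = 0.6) {
  if (fit$family == "linear") {
    tibble::tibble(family = "linear", metric = "r2_adj",
                   value = fit$r2_adj, threshold = r2_relevance,
                   relevant = fit$r2_adj >= r2_relevance)
  } else {
    tibble::tibble(family = "logistic", metric = "c_statistic",
                   value = fit$c_statistic, threshold = c_relevance,
                   relevant = fit$c_statistic >= c_relevance)
  }
}

#' Stepwise reinvestigation of the retained predictors
#'
#' Rebuilds the final model by adding the retained covariates one at a
#' time, from the most to the least influential (ordered by the absolute
#' standardized estimate in the full model), and reports at each step
#' whether the added covariate significantly improves the prediction:
#' F-change test for linear models, likelihood-ratio test for logistic
#' models.
#'
#' @param data Cohort or data frame.
#' @param outcome Outcome column name.
#' @param forced Always-included covariates.
#' @param retained Character vector of retained predictors (non-empty).
#' @param family `"auto"`, `"linear"` or `"logistic"`.
#' @return A tibble, one row per step: `step`, `term`, `statistic`,
#'   `p_value`, `metric` (cumulative adjusted R-squared or c-statistic).
#' @export
incremental_inclusion <- function(data, outcome, forced, retained,
                                  family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  if (length(retained) == 0) abort("`retained` must be non-empty.")
  if (family == "auto") family <- infer_family(data[[outcome]])
  d <- complete_model_frame(data, outcome, unique(c(forced, retained)))
  full <- fit_model(d, outcome, c(forced, retained), family = family)
  ord <- standardized_estimates(full) |>
    dplyr::filter(.data$term %in% retained) |>
    dplyr::pull("term")
  prev <- fit_model(d, outcome, forced, family = family)
  purrr::map_dfr(seq_along(ord), function(k) {
    cur <- fit_model(d, outcome, c(forced, ord[seq_len(k)]), family = family)
    tst <- if (family == "linear") f_change_test(prev, cur)
           else likelihood_ratio_test(prev, cur)
    prev <<- cur
    tibble::tibble(
      step = k, term = ord[k],
      statistic = tst$statistic, p_value = tst$p_value,
      metric = if (family == "linear") cur$r2_adj else cur$c_statistic
    )
  })
}

# Family-appropriate performance of a fitted model evaluated on `newdata`
# (the fit's own rows when NULL). Linear: adjusted R-squared of the
# model's predictions; logistic: c-statistic of the linear predictor.
model_metric <- function(fit, newdata = NULL) {
  if (is.null(newdata)) {
    return(if (fit$family == "linear") fit$r2_adj else fit$c_statistic)
  }
  d <- complete_model_frame(newdata, fit$outcome, fit$terms)
  pred <- predict(fit, d)
  y <- d[[fit$outcome]]
  if (fit$family == "linear") {
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    adjusted_r2(r2, length(y), fit$p)
  } else {
    c_statistic(pred, y)
  }
}

#' Robustness of a model to aberrant value ranges
#'
#' Tests whether the model's performance survives the exclusion of
#' aberrant ranges of values. The default exclusion rule removes rows
#' whose predicted value lies outside the 5th-95th percentile of the
#' model's predictions or whose standardized residual exceeds 2.5 in
#' magnitude; the model is then refit on the remaining rows. The model is
#' robust when the after-exclusion metric retains at least
#' `retention_fraction` (default one half) of the before-exclusion metric
#' and still clears the relevance threshold; a considerable decrease
#' flags the model as not robust.
#'
#' @param fit A `pred_fit`.
#' @param rule Which exclusions to apply: `"both"` (default),
#'   `"prediction"` or `"residual"`.
#' @param retention_fraction Minimum retained fraction of the metric.
#' @param pred_quantiles Length-2 probabilities for the prediction window.
#' @param resid_threshold Standardized-residual cutoff.
#' @param r2_relevance,c_relevance Relevance thresholds (see
#'   [characterize_model()]).
#' @return A one-row tibble: `family`, `metric_before`, `metric_after`,
#'   `n_before`, `n_after`, `n_excluded`, `robust`. The refit is attached
#'   as attribute `"refit"`.
#' @export
robustness_check <- function(fit, rule = c("both", "prediction", "residual"),
                             retention_fraction = 0.5,
                             pred_quantiles = c(0.05, 0.95),
                             resid_threshold = 2.5,
                             r2_relevance = 0.3, c_relevance = 0.6) {
  rule <- match.arg(rule)
  d <- fit$data
  pred <- predict(fit)
  out_pred <- rep(FALSE, nrow(d))
  out_resid <- rep(FALSE, nrow(d))
  if (rule %in% c("both", "prediction")) {
    q <- quantile(pred, pred_quantiles)
    out_pred <- pred < q[1] | pred > q[2]
  }
  if (rule %in% c("both", "residual")) {
    out_resid <- abs(rstandard(fit$model)) > resid_threshold
  }
  keep <- !(out_pred | out_resid)
  n_after <- sum(keep)
  if (n_after < max(20, 5 * fit$p)) {
    abort(sprintf("Only %d rows left after exclusion; need >= %d.",
                  n_after, max(20, 5 * fit$p)))
  }
  refit <- fit_model(d[keep, , drop = FALSE], fit$outcome, fit$terms,
                     family = fit$family)
  before <- model_metric(fit)
  after <- model_metric(refit)
  threshold <- if (fit$family == "linear") r2_relevance else c_relevance
  out <- tibble::tibble(
    family = fit$family,
    metric_before = before,
    metric_after = after,
    n_before = nrow(d),
    n_after = n_after,
    n_excluded = nrow(d) - n_after,
    robust = after >= retention_fraction * before & after >= threshold
  )
  attr(out, "refit") <- refit
  out
}

#' Whole-pipeline bootstrap estimate of optimism
#'
#' Estimates how much of a model's apparent performance is an artifact of
#' having selected and fitted it on the same data. The entire selection
#' process — screening, factor-analytic reduction, the three selection
#' processes and the consensus rule — is re-applied to `B` bootstrap
#' resamples of the cohort; each resample's model is evaluated both on
#' the resample itself (`apparent_b`) and on the original cohort
#' (`test_b`). The optimism is `mean(apparent_b - test_b)`, and the
#' optimism-corrected performance is the original apparent metric minus
#' the optimism. Replicates whose resample lacks an outcome class
#' (logistic) or that fail to fit are excluded and counted; replicates
#' where the consensus retains nothing fall back to the forced-only
#' model.
#'
#' @param data Cohort or data frame.
#' @param config A [run_config()].
#' @param pipeline A function `(data, seed) -> pred_fit or NULL`
#'   implementing the model-building strategy to be validated. Default:
#'   the full screen/reduce/consensus pipeline defined by `config`
#'   ([consensus_pipeline()]). Pass a fixed-model function to validate a
#'   prespecified model without reselection.
#' @param B Number of bootstrap replicates (default
#'   `config$bootstrap_reps`).
#' @param seed Seed (default `config$seed`); each replicate draws from
#'   its own substream so results are reproducible and independent of
#'   `B`.
#' @return An object of class `optimism_report`: list with `family`,
#'   `apparent`, `optimism`, `corrected`, `B`, `n_failed`, `seed`, the
#'   original-data `fit`, and `replicates` (tibble `b`, `apparent`,
#'   `test`). [tidy()] returns the replicate table, [glance()] the
#'   summary row.
#' @export
bootstrap_optimism <- function(data, config, pipeline = NULL,
                               B = NULL, seed = NULL) {
  B <- B %||% config$bootstrap_reps
  seed <- seed %||% config$seed
  if (B < 1) abort("bootstrap_optimism needs B >= 1.")
  data <- tibble::as_tibble(data)
  pipeline <- pipeline %||% consensus_pipeline(config)
  forced_fit <- function(d) fit_model(d, config$outcome, config$forced)
  fit0 <- pipeline(data, substream_seed(seed, "pipeline")) %||%
    forced_fit(data)
  apparent <- model_metric(fit0)
  reps <- purrr::map(seq_len(B), function(b) {
    idx <- with_seed(substream_seed(seed, "boot_resample", b),
                     sample.int(nrow(data), replace = TRUE))
    db <- data[idx, , drop = FALSE]
    tryCatch({
      fitb <- pipeline(db, substream_seed(seed, "boot_pipeline", b)) %||%
        forced_fit(db)
      tibble::tibble(b = b, apparent = model_metric(fitb),
                     test = model_metric(fitb, data))
    }, error = function(e) NULL)
  })
  failed <- sum(purrr::map_lgl(reps, is.null))
  replicates <- dplyr::bind_rows(reps)
  if (nrow(replicates) == 0) {
    abort("All bootstrap replicates failed.")
  }
  optimism <- mean(replicates$apparent - replicates$test)
  structure(list(
    family = fit0$family,
    apparent = apparent,
    optimism = optimism,
    corrected = apparent - optimism,
    B = as.integer(B),
    n_failed = as.integer(failed),
    seed = as.integer(seed),
    fit = fit0,
    replicates = replicates
  ), class = "optimism_report")
}

#' @export
print.optimism_report <- function(x, ...) {
  metric <- if (x$family == "linear") "R2_adj" else "c-statistic"
  cat(sprintf(
    "<optimism_report> %s: apparent %.4f, optimism %.4f, corrected %.4f (B = %d, failed %d)\n",
    metric, x$apparent, x$optimism, x$corrected, x$B, x$n_failed))
  invisible(x)
}

#' @method tidy optimism_report
#' @export
tidy.optimism_report <- function(x, ...) x$replicates

#' @method glance optimism_report
#' @export
glance.optimism_report <- function(x, ...) {
  tibble::tibble(
    family = x$family, apparent = x$apparent, optimism = x$optimism,
    corrected = x$corrected, B = x$B, n_failed = x$n_failed
  )
}
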