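#' Run the selection stages (screen, reduce, select, consensus)
#'
#' Executes stages 1-3 of the algorithm on a cohort: bivariable screening
#' with the forced baseline covariates, factor-analytic reduction of the
#' screened set (skipped when fewer than two candidates survive
#' screening), the applicable selection processes (forward, backward,
#' and — for continuous outcomes — the Lasso) on the representatives, and
#' the consensus rule. Returns every intermediate result plus the final
#' multivariable fit (`NULL` with a recorded reason when nothing is
#' retained).
#'
#' @param data Cohort or data frame.
#' @param config A [run_config()].
#' @param seed Seed for the Lasso cross-validation folds (default
#'   `config$seed`).
#' @return A list: `screen`, `groups`, `representatives` (tibble or
#'   `NULL`), `selection_set`, `selections` (list of
#'   `selection_outcome`s), `consensus`, `retained`, `fit`
#'   (`pred_fit` or `NULL`), `family`, `skip_reason` (`NULL` unless a
#'   stage emptied the pipeline).
#' @export
run_selection_stages <- function(data, config, seed = NULL) {
  seed <- seed %||% config$seed
  family <- infer_family(data[[config$outcome]])
  screen <- bivariable_screen(data, config$outcome, config$forced,
                              config$candidates, alpha = config$screen_alpha,
                              family = family)
  screened <- retained_candidates(screen)
  out <- list(screen = screen, groups = NULL, representatives = NULL,
              selection_set = screened, selections = list(),
              consensus = NULL, retained = character(),
              fit = NULL, family = family, skip_reason = NULL)
  if (length(screened) == 0) {
    out$skip_reason <- "no candidate passed bivariable screening"
    return(out)
  }
  if (length(screened) >= 2) {
    out$groups <- factor_decompose(data, screened,
                                   loading_threshold = config$loading_threshold)
    out$representatives <- pick_representatives(out$groups, screen)
    out$selection_set <- attr(out$representatives, "representatives")
  }
  sel_set <- out$selection_set
  selections <- list(
    forward_select(data, config$outcome, config$forced, sel_set,
                   entry_alpha = config$entry_alpha, family = family),
    backward_select(data, config$outcome, config$forced, sel_set,
                    stay_alpha = config$stay_alpha, family = family)
  )
  if (family == "linear") {
    selections <- c(selections, list(
      lasso_select(data, config$outcome, config$forced, sel_set,
                   seed = substream_seed(seed, "lasso"))
    ))
  }
  out$selections <- selections
  out$consensus <- consensus_select(selections,
                                    weak_alpha = config$weak_alpha,
                                    strong_alpha = config$strong_alpha)
  out$retained <- consensus_retained(out$consensus)
  if (length(out$retained) == 0) {
    out$skip_reason <- "consensus retained no predictor"
    return(out)
  }
  out$fit <- fit_model(data, config$outcome, c(config$forced, out$retained),
                       family = family)
  out
}

#' @rdname run_selection_stages
#' @return `consensus_pipeline()` returns a function
#'   `(data, seed) -> pred_fit or NULL`, the resampling unit used by
#'   [bootstrap_optimism()] so the entire selection process is repeated
#'   inside every bootstrap replicate.
#' @export
consensus_pipeline <- function(config) {
  function(data, seed = config$seed) {
    run_selection_stages(data, config, seed = seed)$fit
  }
}

#' Run the full predictor-identification pipeline
#'
#' End-to-end orchestration on one cohort: structural validation, stages
#' 1-3 ([run_selection_stages()]), then — when the consensus retains at
#' least one predictor — model characterization, stepwise reinvestigation
#' of the retained covariates, the robustness check, whole-pipeline
#' bootstrap optimism correction, the prediction equation and the
#' nomogram. Stages after an empty consensus are skipped with the reason
#' recorded in the report. Fixed `config$seed` makes the whole run (CV
#' folds, bootstrap resamples) reproducible.
#'
#' @param data Cohort or data frame.
#' @param config A [run_config()].
#' @return An object of class `run_report`; see [render_report()].
#' @export
run_pipeline <- function(data, config) {
  data <- tibble::as_tibble(data)
  warnings_log <- character()
  validation <- withCallingHandlers(
    validate_cohort(data, config),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  stages <- run_selection_stages(data, config)
  report <- list(
    config = unclass(config),
    n = nrow(data),
    family = stages$family,
    validation = validation,
    screen = stages$screen,
    groups = stages$groups,
    representatives = stages$representatives,
    selection_set = stages$selection_set,
    selections = stages$selections,
    consensus = stages$consensus,
    retained = stages$retained,
    fit = stages$fit,
    skip_reason = stages$skip_reason,
    warnings = warnings_log,
    seed = config$seed
  )
  if (!is.null(stages$fit)) {
    fit <- stages$fit
    report$equation <- format_equation(fit)
    report$standardized <- standardized_estimates(fit)
    report$relevance <- characterize_model(fit,
                                           r2_relevance = config$r2_relevance,
                                           c_relevance = config$c_relevance)
    report$incremental <- incremental_inclusion(
      data, config$outcome, config$forced, stages$retained,
      family = stages$family)
    report$robustness <- tryCatch(
      robustness_check(fit, retention_fraction = config$retention_fraction,
                       r2_relevance = config$r2_relevance,
                       c_relevance = config$c_relevance),
      error = function(e) {
        warnings_log <<- c(warnings_log, conditionMessage(e))
        NULL
      })
    if (config$bootstrap_reps > 0) {
      report$optimism <- bootstrap_optimism(data, config)
    }
    report$nomogram <- build_nomogram(fit)
    report$warnings <- warnings_log
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> outcome `%s` (%s), n = %d, seed = %d\n",
              x$config$outcome, x$family, x$n, x$seed))
  cat(sprintf("  screened: %d/%d candidates; selection set: %d\n",
              sum(x$screen$retained), nrow(x$screen),
              length(x$selection_set)))
  if (is.null(x$fit)) {
    cat("  no final model:", x$skip_reason, "\n")
  } else {
    cat("  consensus retained:", paste(x$retained, collapse = ", "), "\n")
    cat("  ", x$equation, "\n", sep = "")
    v <- x$relevance
    cat(sprintf("  %s = %.3f (%s)", v$metric, v$value,
                if (v$relevant) "relevant" else "irrelevant"))
    if (!is.null(x$optimism)) {
      cat(sprintf("; optimism-corrected = %.3f", x$optimism$corrected))
    }
    cat("\n")
  }
  invisible(x)
}

# Plain-list view of a run report for serialization (model objects and
# environments stripped; every number kept at full precision).
report_as_list <- function(report) {
  tidy_or_null <- function(x) if (is.null(x)) NULL else as.data.frame(x)
  fit_list <- function(fit) {
    if (is.null(fit)) return(NULL)
    list(
      family = fit$family, outcome = fit$outcome, terms = fit$terms,
      n = fit$n, p = fit$p,
      coefficients = as.data.frame(fit$coefficients),
      log_likelihood = fit$log_likelihood,
      residual_variance = fit$residual_variance %||% NULL,
      r2 = fit$r2 %||% NULL, r2_adj = fit$r2_adj %||% NULL,
      c_statistic = fit$c_statistic %||% NULL
    )
  }
  list(
    config = report$config,
    n = report$n,
    family = report$family,
    seed = report$seed,
    validation = tidy_or_null(report$validation),
    screen = tidy_or_null(report$screen),
    factor_groups = tidy_or_null(report$groups),
    representatives = tidy_or_null(report$representatives),
    selection_set = report$selection_set,
    selections = purrr::map(report$selections,
                            ~ as.data.frame(tibble::as_tibble(.x))),
    consensus = tidy_or_null(report$consensus),
    retained = report$retained,
    fit = fit_list(report$fit),
    equation = report$equation,
    standardized = tidy_or_null(report$standardized),
    relevance = tidy_or_null(report$relevance),
    incremental = tidy_or_null(report$incremental),
    robustness = tidy_or_null(report$robustness),
    optimism = if (is.null(report$optimism)) NULL else list(
      summary = as.data.frame(glance(report$optimism)),
      replicates = as.data.frame(report$optimism$replicates)
    ),
    nomogram = if (is.null(report$nomogram)) NULL else list(
      axes = as.data.frame(report$nomogram$axes),
      scale = report$nomogram$scale,
      lp_offset = report$nomogram$lp_offset,
      total_points_max = report$nomogram$total_points_max
    ),
    skip_reason = report$skip_reason,
    warnings = report$warnings
  )
}

#' Write a run report to disk
#'
#' Serializes a [run_pipeline()] report as machine-readable JSON (full
#' precision, reproducibly ordered) and a human-readable Markdown summary
#' with the prediction equation, the standardized-estimate grid and the
#' nomogram table.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`json`, `md`).
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(report_as_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(report_markdown(report), md_path)
  invisible(list(json = json_path, md = md_path))
}

report_markdown <- function(report) {
  md_table <- function(df, digits = 4) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, rows)
  }
  out <- c(
    sprintf("# Predictor identification report: %s", report$config$outcome),
    "",
    sprintf("- family: %s; n = %d; seed = %d", report$family, report$n,
            report$seed),
    sprintf("- candidates offered: %d; screened in: %d; selection set: %d",
            length(report$config$candidates), sum(report$screen$retained),
            length(report$selection_set)),
    ""
  )
  if (length(report$warnings) > 0) {
    out <- c(out, "## Warnings", paste("-", report$warnings), "")
  }
  out <- c(out, "## Bivariable screening", md_table(
    report$screen[, c("candidate", "estimate", "p_value", "retained")]), "")
  if (!is.null(report$consensus)) {
    out <- c(out, "## Consensus", md_table(report$consensus), "")
  }
  if (is.null(report$fit)) {
    out <- c(out, "## Final model",
             sprintf("No final model: %s.", report$skip_reason), "")
  } else {
    out <- c(out,
      "## Final model", "", paste0("    ", report$equation), "",
      "### Standardized estimates", md_table(report$standardized), "",
      "### Relevance", md_table(report$relevance), "")
    if (!is.null(report$incremental)) {
      out <- c(out, "### Incremental inclusion",
               md_table(report$incremental), "")
    }
    if (!is.null(report$robustness)) {
      out <- c(out, "### Robustness", md_table(report$robustness), "")
    }
    if (!is.null(report$optimism)) {
      out <- c(out, "### Bootstrap optimism",
               md_table(glance(report$optimism)), "")
    }
    if (!is.null(report$nomogram)) {
      out <- c(out, "### Nomogram", md_table(report$nomogram$axes),
               sprintf("Total points 0-%.1f map affinely to the %s response.",
                       report$nomogram$total_points_max, report$family), "")
    }
  }
  out
}
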