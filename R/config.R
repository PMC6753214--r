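#' Run configuration for the predictor-identification pipeline
#'
#' Collects every tunable threshold of the staged algorithm in one place so
#' a run is fully described by (cohort, config, seed). Defaults follow the
#' published decision rules: candidates enter the consensus when at least
#' weakly significant (p < `weak_alpha` = 0.05) in two of the three
#' selection processes and highly significant (p < `strong_alpha` = 0.001)
#' in at least one; models with adjusted R-squared below `r2_relevance` =
#' 0.3 (linear) or c-statistic below `c_relevance` = 0.6 (logistic) are
#' regarded as irrelevant; and models should contain fewer variables than
#' `variables_per_case` = 1/20 of the number of cases.
#'
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate covariate names.
#' @param forced Character vector of always-included covariates; must
#'   include the baseline value of the outcome.
#' @param screen_alpha Bivariable screening threshold (default 0.05).
#' @param weak_alpha,strong_alpha Consensus significance levels.
#' @param entry_alpha,stay_alpha Forward-entry / backward-stay thresholds.
#' @param r2_relevance,c_relevance Relevance thresholds for adjusted
#'   R-squared and c-statistic.
#' @param variables_per_case Harrell guard: maximum variables per case.
#' @param loading_threshold Absolute factor loading above which candidates
#'   are grouped as collinear (default 0.6).
#' @param bootstrap_reps Bootstrap replicates `B` for the optimism
#'   estimate (default 200).
#' @param retention_fraction Robustness rule: model is robust when the
#'   after-exclusion metric retains at least this fraction of the
#'   before-exclusion metric (default 0.5).
#' @param seed Integer seed driving every random element (CV folds,
#'   bootstrap resampling) through deterministic per-stage substreams.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outcome,
                       candidates,
                       forced,
                       screen_alpha = 0.05,
                       weak_alpha = 0.05,
                       strong_alpha = 0.001,
                       entry_alpha = 0.05,
                       stay_alpha = 0.05,
                       r2_relevance = 0.3,
                       c_relevance = 0.6,
                       variables_per_case = 1 / 20,
                       loading_threshold = 0.6,
                       bootstrap_reps = 200,
                       retention_fraction = 0.5,
                       seed = 1L) {
  stopifnot(
    is.character(outcome), length(outcome) == 1,
    is.character(candidates), length(candidates) >= 1,
    is.character(forced)
  )
  if (!(strong_alpha > 0 && strong_alpha < weak_alpha && weak_alpha < 1)) {
    abort("Need 0 < strong_alpha < weak_alpha < 1.")
  }
  if (bootstrap_reps < 0) abort("bootstrap_reps must be >= 0.")
  if (!(variables_per_case > 0 && variables_per_case <= 1)) {
    abort("variables_per_case must lie in (0, 1].")
  }
  if (outcome %in% candidates) {
    abort("The outcome cannot be its own candidate predictor.")
  }
  structure(list(
    outcome = outcome, candidates = candidates, forced = forced,
    screen_alpha = screen_alpha,
    weak_alpha = weak_alpha, strong_alpha = strong_alpha,
    entry_alpha = entry_alpha, stay_alpha = stay_alpha,
    r2_relevance = r2_relevance, c_relevance = c_relevance,
    variables_per_case = variables_per_case,
    loading_threshold = loading_threshold,
    bootstrap_reps = as.integer(bootstrap_reps),
    retention_fraction = retention_fraction,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read / write a run configuration file
#'
#' Configurations are stored as YAML key-value text with keys matching the
#' arguments of [run_config()] (`outcome`, `candidates`, `forced`,
#' `screen_alpha`, `weak_alpha`, `strong_alpha`, `r2_relevance`,
#' `c_relevance`, `variables_per_case`, `bootstrap_reps`, `seed`,
#' `robustness` as `retention_fraction`).
#'
#' @param path File path.
#' @return A `run_config` (for `read_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$robustness)) {
    raw$retention_fraction <- raw$robustness
    raw$robustness <- NULL
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}
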