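#' Declare the variables of a trial cohort
#'
#' A variable catalogue describing each column of a subject-level cohort
#' table: its role in the modelling pipeline and its measurement scale.
#' Clinical instruments typical of a chronic-pain trial (NRS-3 pain
#' intensity, painDETECT total and subscores, sleep questionnaire, SF-12
#' component summaries, EQ-5D VAS, HADS subscales, global impressions of
#' change) are all `candidate` covariates on a `continuous` or
#' `quasi_continuous` scale; quasi-continuous scores are modelled as
#' continuous.
#'
#' @param name Character vector of column names.
#' @param role Role of each variable: one of `"id"`, `"outcome"`,
#'   `"candidate"`, `"forced"` (always kept in every model, e.g. the
#'   baseline value of the outcome), or `"arm"`.
#' @param scale Measurement scale: `"continuous"`, `"quasi_continuous"`,
#'   `"binary"` or `"ordinal"`. Recycled if length 1.
#' @param units Free-text units, recycled.
#' @return A tibble with columns `name`, `role`, `scale`, `units`.
#' @examples
#' var_specs(
#'   name  = c("subject", "mcs_response", "mcs_pre", "pdq_total"),
#'   role  = c("id", "outcome", "forced", "candidate"),
#'   scale = c("continuous", "continuous", "continuous", "quasi_continuous")
#' )
#' @export
var_specs <- function(name, role, scale = "continuous", units = "") {
  roles <- c("id", "outcome", "candidate", "forced", "arm")
  scales <- c("continuous", "quasi_continuous", "binary", "ordinal")
  if (!all(role %in% roles)) {
    abort(sprintf("Unknown role(s): %s",
                  paste(setdiff(role, roles), collapse = ", ")))
  }
  if (!all(scale %in% scales)) {
    abort(sprintf("Unknown scale(s): %s",
                  paste(setdiff(scale, scales), collapse = ", ")))
  }
  out <- tibble::tibble(
    name = as.character(name),
    role = role,
    scale = scale,
    units = units
  )
  if (sum(out$role == "id") != 1) {
    abort("Exactly one variable must have role \"id\".")
  }
  if (anyDuplicated(out$name)) {
    abort("Variable names must be unique.")
  }
  out
}

#' Construct a validated cohort table
#'
#' Attaches a variable catalogue to a subject-level data frame and checks
#' the structural invariants: unique subject ids, all declared columns
#' present, binary variables restricted to two coded values. Missing values
#' are kept as `NA` — they are never imputed; each fitted model later drops
#' its own incomplete rows (complete-case analysis per model).
#'
#' @param data A data frame, one row per subject.
#' @param specs A variable catalogue from [var_specs()].
#' @return A tibble of class `conselect_cohort` with the catalogue attached
#'   as the `"specs"` attribute (see [cohort_specs()]).
#' @export
cohort <- function(data, specs) {
  data <- tibble::as_tibble(data)
  check_columns(data, specs$name)
  extra <- setdiff(names(data), specs$name)
  if (length(extra) > 0) {
    abort(sprintf("Columns not declared in specs: %s",
                  paste0("`", extra, "`", collapse = ", ")))
  }
  id_col <- specs$name[specs$role == "id"]
  if (anyDuplicated(data[[id_col]])) {
    abort(sprintf("Duplicate subject ids in `%s`.", id_col))
  }
  for (nm in specs$name[specs$scale == "binary"]) {
    vals <- unique(data[[nm]][!is.na(data[[nm]])])
    if (length(vals) > 2) {
      abort(sprintf("Binary variable `%s` takes %d distinct values.",
                    nm, length(vals)))
    }
  }
  structure(data, specs = specs,
            class = c("conselect_cohort", class(data)))
}

#' @rdname cohort
#' @param x A `conselect_cohort`.
#' @export
cohort_specs <- function(x) attr(x, "specs")

#' Read / write a cohort CSV
#'
#' Cohorts are exchanged as RFC-4180-style CSV (comma separator, dot
#' decimal, UTF-8, mandatory header, missing values as empty fields).
#' `read_cohort()` validates the file against a variable catalogue;
#' `write_cohort()` is its inverse, so `read_cohort(write_cohort(x))`
#' preserves every value.
#'
#' @param path Path of the CSV file.
#' @param specs Variable catalogue from [var_specs()]; every declared
#'   column must be present in the file (a missing one is an error naming
#'   it).
#' @return `read_cohort()`: a validated [cohort()]; `write_cohort()`: the
#'   input, invisibly.
#' @export
read_cohort <- function(path, specs) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c(""), progress = FALSE)
  check_columns(raw, specs$name, where = sprintf("file '%s'", path))
  raw <- raw[specs$name]
  id_col <- specs$name[specs$role == "id"]
  arm_cols <- specs$name[specs$role == "arm"]
  for (nm in setdiff(names(raw), c(id_col, arm_cols))) {
    parsed <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- !is.na(raw[[nm]]) & is.na(parsed)
    if (any(bad)) {
      warn(sprintf("Column `%s`: %d unparsable value(s) set to NA (rows %s).",
                   nm, sum(bad),
                   paste(head(which(bad), 5), collapse = ", ")))
    }
    raw[[nm]] <- parsed
  }
  cohort(raw, specs)
}

#' @rdname read_cohort
#' @param data A cohort (or plain data frame) to write.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, na = "", progress = FALSE)
  invisible(data)
}

#' Structural validation report for a cohort
#'
#' Checks a cohort against a run configuration before modelling: the
#' outcome column must exist (hard error), per-column missingness is
#' tabulated, and the events-per-variable guard is applied — prediction
#' models should contain fewer variables than 1/20 of the number of cases,
#' so offering `k` candidates to a cohort of `n` subjects warns when
#' `k >= n * variables_per_case`.
#'
#' @param data A cohort or data frame.
#' @param config A [run_config()].
#' @return A tibble with one row per declared model variable: `variable`,
#'   `role`, `n_missing`, `prop_missing`; the guard verdict is attached as
#'   attributes `"n"`, `"max_variables"` and `"overfitting_warning"`.
#' @export
validate_cohort <- function(data, config) {
  if (nrow(data) == 0) abort("Cohort has zero rows.")
  if (!config$outcome %in% names(data)) {
    abort(sprintf("Outcome column `%s` absent from cohort.", config$outcome))
  }
  vars <- unique(c(config$outcome, config$forced, config$candidates))
  check_columns(data, vars)
  n <- nrow(data)
  max_vars <- n * config$variables_per_case
  k <- length(config$candidates)
  over <- k >= max_vars
  if (over) {
    warn(sprintf(paste0(
      "%d candidate variables offered but models should contain fewer ",
      "than %.1f variables at n = %d (1 per %d cases); rely on the ",
      "screening/consensus stages and the optimism correction."),
      k, max_vars, n, round(1 / config$variables_per_case)))
  }
  report <- tibble::tibble(
    variable = vars,
    role = dplyr::case_when(
      vars == config$outcome ~ "outcome",
      vars %in% config$forced ~ "forced",
      TRUE ~ "candidate"
    ),
    n_missing = purrr::map_int(vars, ~ sum(is.na(data[[.x]]))),
    prop_missing = .data$n_missing / n
  )
  attr(report, "n") <- n
  attr(report, "max_variables") <- max_vars
  attr(report, "overfitting_warning") <- over
  report
}
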