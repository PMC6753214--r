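#' Classify response to the titration phase
#'
#' During the dose-titration phase every subject receives the medium-dose
#' study drug; the average pain intensity over the last three days (NRS-3,
#' 0 = no pain, 10 = worst imaginable) is scored before and at the end of
#' titration. Subjects are partitioned into three mutually exclusive
#' groups:
#'
#' * `optimal_responder` — end-of-titration NRS-3 below 4 (dramatic pain
#'   reduction); these subjects continue open-label on the medium dose and
#'   are never randomized.
#' * `randomized` — at least a 1-point decrease from baseline with
#'   end-of-titration NRS-3 still at 4 or above (mild response); these
#'   enter the comparative period.
#' * `non_responder` — everyone else.
#'
#' The rules partition the whole (baseline, end) square exhaustively, so
#' every valid score pair receives exactly one label.
#'
#' @param nrs3_baseline,nrs3_end Numeric vectors of NRS-3 scores in
#'   `[0, 10]`. Vectorized; usable inside `dplyr::mutate()`.
#' @return A character vector with values `"optimal_responder"`,
#'   `"randomized"`, `"non_responder"` (`NA` propagates).
#' @examples
#' classify_titration_response(8, 3)   # optimal_responder
#' classify_titration_response(8, 6)   # randomized
#' classify_titration_response(8, 7.5) # non_responder
#' @export
classify_titration_response <- function(nrs3_baseline, nrs3_end) {
  ok <- function(x) is.na(x) | (x >= 0 & x <= 10)
  if (!all(ok(nrs3_baseline)) || !all(ok(nrs3_end))) {
    abort("NRS-3 scores must lie in [0, 10].")
  }
  dplyr::case_when(
    is.na(nrs3_baseline) | is.na(nrs3_end) ~ NA_character_,
    nrs3_end < 4 ~ "optimal_responder",
    (nrs3_baseline - nrs3_end) >= 1 & nrs3_end >= 4 ~ "randomized",
    TRUE ~ "non_responder"
  )
}

#' Classify a painDETECT total score
#'
#' The painDETECT questionnaire (PDQ) screens for neuropathic pain
#' components. The instrument's published cutoffs classify the total score
#' as negative (unlikely neuropathic component), unclear, or positive.
#' The cutoffs are instrument constants, configurable for other versions.
#'
#' @param pdq_total Numeric vector of PDQ total scores.
#' @param cutoffs Named numeric vector: scores `<= cutoffs["negative"]` are
#'   negative, scores `<= cutoffs["unclear"]` unclear, larger positive.
#' @return Character vector: `"negative"`, `"unclear"`, `"positive"`.
#' @export
pdq_classify <- function(pdq_total, cutoffs = c(negative = 12, unclear = 18)) {
  dplyr::case_when(
    is.na(pdq_total) ~ NA_character_,
    pdq_total <= cutoffs[["negative"]] ~ "negative",
    pdq_total <= cutoffs[["unclear"]] ~ "unclear",
    TRUE ~ "positive"
  )
}

#' Apply the trial's inclusion criteria
#'
#' Retains adult subjects (age >= 18 years) with chronic low back pain of
#' at least 3 months' duration, an average baseline pain intensity of at
#' least 6 on the NRS-3, and an "unclear" or "positive" painDETECT
#' evaluation for neuropathic pain components. A missing value in any
#' criterion column excludes the row with reason `"missing"`. Rules are
#' applied in order; each exclusion is counted against the first rule that
#' fails.
#'
#' @param data Cohort or data frame.
#' @param age,duration_months,nrs3_baseline,pdq_class Names (strings) of
#'   the columns holding age in years, pain duration in months, baseline
#'   NRS-3, and the painDETECT class (values among `"negative"`,
#'   `"unclear"`, `"positive"`; see [pdq_classify()]).
#' @return The retained subset as a tibble. The per-rule exclusion counts
#'   are attached as attribute `"exclusions"` (a tibble `reason` / `n`) and
#'   retrievable with `exclusion_counts()`; retained + excluded always sums
#'   to the input rows.
#' @export
apply_inclusion_criteria <- function(data, age = "age",
                                     duration_months = "pain_duration_months",
                                     nrs3_baseline = "nrs3_baseline",
                                     pdq_class = "pdq_class") {
  cols <- c(age, duration_months, nrs3_baseline, pdq_class)
  check_columns(data, cols)
  lv <- data[[pdq_class]]
  bad_class <- !is.na(lv) & !lv %in% c("negative", "unclear", "positive")
  if (any(bad_class)) {
    abort(sprintf("`%s` contains values other than negative/unclear/positive.",
                  pdq_class))
  }
  reason <- dplyr::case_when(
    is.na(data[[age]]) | is.na(data[[duration_months]]) |
      is.na(data[[nrs3_baseline]]) | is.na(lv) ~ "missing",
    data[[age]] < 18 ~ "age_below_18",
    data[[duration_months]] < 3 ~ "duration_below_3_months",
    data[[nrs3_baseline]] < 6 ~ "nrs3_below_6",
    lv == "negative" ~ "pdq_negative",
    TRUE ~ "included"
  )
  kept <- tibble::as_tibble(data)[reason == "included", ]
  excl <- tibble::tibble(reason = reason[reason != "included"]) |>
    dplyr::count(.data$reason)
  attr(kept, "exclusions") <- excl
  kept
}

#' @rdname apply_inclusion_criteria
#' @param x The value returned by `apply_inclusion_criteria()`.
#' @export
exclusion_counts <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(reason = character(), n = integer())
}
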