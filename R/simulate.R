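#' Default candidate catalogue of the simulator
#'
#' Names and instrument ranges for the 46 baseline/randomization clinical
#' parameters a chronic low back pain trial typically records: pain
#' intensity (NRS-3), the painDETECT total and its seven symptom
#' subscores, sleep quality, SF-12 component summaries, EQ-5D VAS, HADS
#' anxiety/depression, global impressions of change, and
#' demographics/vitals; the remainder are generic covariates on a 0-100
#' scale.
#'
#' @param k Number of candidates (default 46).
#' @return A tibble `name`, `min`, `max`.
#' @export
candidate_catalogue <- function(k = 46) {
  named <- tibble::tribble(
    ~name,            ~min, ~max,
    "nrs3_baseline",     0,   10,
    "pdq_total",         0,   38,
    "pdq_burning",       0,    5,
    "pdq_paresthesia",   0,    5,
    "pdq_allodynia",     0,    5,
    "pdq_attacks",       0,    5,
    "pdq_thermal",       0,    5,
    "pdq_numbness",      0,    5,
    "pdq_pressure",      0,    5,
    "sq_score",          0,  100,
    "sf12_mcs",          0,  100,
    "sf12_pcs",          0,  100,
    "eq5d_vas",          0,  100,
    "hads_a",            0,   21,
    "hads_d",            0,   21,
    "pgic",              1,    7,
    "cgic",              1,    7,
    "age",              18,   85,
    "bmi",              16,   45,
    "heart_rate",       45,  120,
    "bp_systolic",      90,  200,
    "bp_diastolic",     50,  120
  )
  if (k <= nrow(named)) return(named[seq_len(k), ])
  extra <- tibble::tibble(
    name = sprintf("covar_%02d", seq_len(k - nrow(named))),
    min = 0, max = 100
  )
  dplyr::bind_rows(named, extra)
}

block_correlation <- function(k, block_size = 4, rho = 0.4) {
  S <- diag(k)
  starts <- seq(1, k, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1, k)
    S[idx, idx] <- rho
    diag(S)[idx] <- 1
  }
  S
}

exchangeable_correlation <- function(k, rho = 0.2) {
  S <- matrix(rho, k, k); diag(S) <- 1; S
}

#' Simulate a titration-to-randomization trial cohort
#'
#' Generates a subject-level cohort that emulates the structure of a
#' randomized analgesic trial with a preceding dose-titration phase:
#' correlated questionnaire covariates, a continuous (or binary) outcome
#' driven by a sparse set of true predictors plus the baseline value of
#' the outcome, titration NRS-3 scores with the derived response labels
#' ([classify_titration_response()]), and arm labels for the randomized
#' subjects. The ground truth (true support, coefficients, noise) is
#' attached so recovery and optimism properties can be tested.
#'
#' Covariates are drawn as correlated Gaussians (block-structured by
#' default, mimicking questionnaire families) and, when `discretize` is
#' `TRUE`, mapped rank-preservingly onto their instrument ranges as
#' bounded integers. Effects are standardized: the outcome is built from
#' unit-variance latent covariates and, when `noise_sd` is `NULL`, the
#' noise is calibrated so the latent outcome has unit variance — an
#' `effects` entry of 0.3 then is (up to discretization) the standardized
#' estimate the model recovers.
#'
#' @param n Number of subjects (default 311: the trial scale of 50
#'   open-label responders plus 261 randomized).
#' @param n_candidates Number of candidate covariates (default 46).
#' @param effects Named numeric vector of standardized true effects on
#'   the outcome; names must be candidate names. Default: a sparse
#'   5-predictor map over questionnaire scores.
#' @param baseline_effect Standardized effect of the baseline outcome
#'   value (default 0.3).
#' @param family `"linear"` or `"logistic"` outcome.
#' @param correlation `"block"` (default), `"exchangeable"` or
#'   `"independent"`; `rho` and `block_size` parameterize it.
#' @param rho,block_size Correlation parameters.
#' @param noise_sd Residual SD; `NULL` calibrates it so the latent
#'   outcome has unit variance.
#' @param discretize Map covariates onto bounded integer instrument
#'   ranges (default `TRUE`).
#' @param arm_split Probability of the TapMono arm among randomized
#'   subjects (default 127/261).
#' @param titration List: `nrs_mean`, `nrs_sd` of baseline NRS-3
#'   (clipped to 6-10 by the inclusion criteria), `drop_mean`,
#'   `drop_sd` of the titration pain decrease.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A [cohort()] with columns: `subject_id`, `arm`,
#'   `titration_label`, `nrs3_end`, the outcome, its baseline value
#'   (`<outcome>_pre`), and the candidates. Ground truth is attached as
#'   attribute `"truth"` (see [ground_truth()]).
#' @export
simulate_cohort <- function(n = 311,
                            n_candidates = 46,
                            effects = NULL,
                            baseline_effect = 0.3,
                            family = c("linear", "logistic"),
                            correlation = c("block", "exchangeable",
                                            "independent"),
                            rho = 0.4, block_size = 4,
                            noise_sd = NULL,
                            discretize = TRUE,
                            arm_split = 127 / 261,
                            titration = list(nrs_mean = 7.5, nrs_sd = 1.2,
                                             drop_mean = 2.2, drop_sd = 1.5),
                            seed = 1L) {
  family <- match.arg(family)
  correlation <- match.arg(correlation)
  catalogue <- candidate_catalogue(n_candidates)
  cand <- catalogue$name
  if (is.null(effects)) {
    effects <- c(pdq_total = 0.35, sq_score = -0.30, sf12_mcs = -0.35,
                 hads_d = -0.25, pdq_numbness = -0.20)
    effects <- effects[names(effects) %in% cand]
  }
  if (!all(names(effects) %in% cand)) {
    abort(sprintf("Unknown effect name(s): %s",
                  paste(setdiff(names(effects), cand), collapse = ", ")))
  }
  S <- switch(correlation,
              block = block_correlation(n_candidates, block_size, rho),
              exchangeable = exchangeable_correlation(n_candidates, rho),
              independent = diag(n_candidates))
  ch <- tryCatch(chol(S),
                 error = function(e) abort("Correlation matrix is not positive definite."))
  b <- setNames(rep(0, n_candidates), cand)
  b[names(effects)] <- effects
  if (is.null(noise_sd)) {
    expl <- as.numeric(t(b) %*% S %*% b) + baseline_effect^2
    noise_sd <- sqrt(max(1 - expl, 0.05))
  }

  with_seed(seed, {
    Z <- matrix(rnorm(n * n_candidates), n) %*% ch
    colnames(Z) <- cand
    z_base <- rnorm(n)
    lp <- baseline_effect * z_base + as.numeric(Z %*% b)
    y <- if (family == "linear") {
      lp + rnorm(n, sd = noise_sd)
    } else {
      # effects read as log-odds per SD around a 30% base prevalence
      rbinom(n, 1, inv_logit(qlogis(0.3) + lp))
    }
    X <- Z
    if (discretize) {
      for (j in seq_len(n_candidates)) {
        lo <- catalogue$min[j]; hi <- catalogue$max[j]
        X[, j] <- pmin(hi, pmax(lo, round((lo + hi) / 2 + Z[, j] * (hi - lo) / 6)))
      }
    }
    # titration scores: baseline NRS-3 rank-linked to its latent score
    z_nrs <- if ("nrs3_baseline" %in% cand) Z[, "nrs3_baseline"] else rnorm(n)
    nrs_base <- pmin(10, pmax(6, round(titration$nrs_mean +
                                         z_nrs * titration$nrs_sd)))
    drop <- rnorm(n, titration$drop_mean, titration$drop_sd)
    nrs_end <- pmin(10, pmax(0, round(nrs_base - drop)))
    if ("nrs3_baseline" %in% cand) X[, "nrs3_baseline"] <- nrs_base
    label <- classify_titration_response(nrs_base, nrs_end)
    arm <- ifelse(label == "optimal_responder", "OpenLabel",
                  ifelse(label == "non_responder", "Discontinued",
                         ifelse(runif(n) < arm_split, "TapMono", "TapPre")))
    out_name <- if (family == "linear") "mcs_response" else "optimal_responder"
    base_name <- paste0(out_name, "_pre")
    base_col <- if (discretize) {
      pmin(100, pmax(0, round(50 + z_base * 10)))
    } else {
      z_base
    }
    d <- tibble::tibble(
      subject_id = sprintf("subj_%04d", seq_len(n)),
      arm = arm,
      titration_label = label,
      nrs3_end = as.numeric(nrs_end)
    )
    d[[out_name]] <- if (family == "linear") y else as.numeric(y)
    d[[base_name]] <- as.numeric(base_col)
    for (v in cand) d[[v]] <- as.numeric(X[, v])

    specs <- var_specs(
      name = c("subject_id", "arm", "titration_label", "nrs3_end",
               out_name, base_name, cand),
      role = c("id", "arm", "arm", "candidate",
               "outcome", "forced", rep("candidate", length(cand))),
      scale = c("continuous", "continuous", "continuous", "quasi_continuous",
                if (family == "linear") "continuous" else "binary",
                "quasi_continuous", rep("quasi_continuous", length(cand)))
    )
    ch_out <- cohort(d, specs)
    attr(ch_out, "truth") <- list(
      effects = tibble::tibble(term = names(effects),
                               effect = as.numeric(effects)),
      baseline_effect = baseline_effect,
      baseline = base_name,
      outcome = out_name,
      candidates = cand,
      noise_sd = noise_sd,
      family = family,
      seed = as.integer(seed)
    )
    ch_out
  })
}

#' @rdname simulate_cohort
#' @param x A simulated cohort.
#' @export
ground_truth <- function(x) attr(x, "truth")

#' Simulate a global-null cohort
#'
#' All candidates (and the baseline value) are independent standard
#' normals unrelated to the outcome — the reference case for type-I-error
#' and optimism suites: screening retention should approach the
#' screening level, consensus retention should be rare, and the
#' optimism-corrected adjusted R-squared should approach zero.
#'
#' @param n Number of subjects (`n >= 10`).
#' @param n_candidates Number of independent candidates.
#' @param seed Integer seed.
#' @return A [cohort()] with columns `subject_id`, outcome `y`, baseline
#'   `y_pre` and candidates `cand_01`, ...; ground truth (empty support)
#'   attached.
#' @export
make_null_cohort <- function(n, n_candidates = 46, seed = 1L) {
  if (n < 10) abort("make_null_cohort needs n >= 10.")
  cand <- sprintf("cand_%02d", seq_len(n_candidates))
  with_seed(seed, {
    d <- tibble::as_tibble(
      setNames(as.data.frame(matrix(rnorm(n * n_candidates), n)), cand)
    )
    d <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("subj_%04d", seq_len(n)),
                     y = rnorm(n), y_pre = rnorm(n)),
      d
    )
    specs <- var_specs(
      name = c("subject_id", "y", "y_pre", cand),
      role = c("id", "outcome", "forced", rep("candidate", n_candidates))
    )
    out <- cohort(d, specs)
    attr(out, "truth") <- list(
      effects = tibble::tibble(term = character(), effect = numeric()),
      baseline_effect = 0, baseline = "y_pre", outcome = "y",
      candidates = cand, noise_sd = 1, family = "linear",
      seed = as.integer(seed)
    )
    out
  })
}
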