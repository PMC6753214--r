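---
title: "Consensus predictor selection and internal validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus predictor selection and internal validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conselect)
```

## The problem

Randomized analgesic trials record dozens of baseline and randomization
covariates — pain intensity ratings (NRS-3), the painDETECT questionnaire
and its symptom subscores, sleep quality, SF-12 component summaries,
EQ-5D VAS, HADS anxiety/depression, global impressions of change,
demographics and vitals — while enrolling only one or two hundred
patients per arm. Regressing an outcome on everything at once would
overfit catastrophically: a sound prediction model at ~130 cases should
carry fewer than 1/20 of the case count in variables, i.e. at most six.
`conselect` implements a staged algorithm that starts from the full
covariate spectrum but ends with a small, internally validated predictor
set, together with a simulator of trial-like cohorts so that every claim
about the algorithm can be tested against known ground truth.

## The staged algorithm

**Stage 1 — bivariable screening** (`bivariable_screen()`). Each
candidate is assessed in a model of the outcome containing only the
baseline value of the outcome (always forced in) and that candidate;
linear regression for continuous or quasi-continuous outcomes, logistic
regression for binary ones. Candidates with a Wald p-value below
`screen_alpha` survive. The screening level defaults to 0.05 — the weak
significance level of the consensus rule — because the sources that
motivate this pipeline leave the screening cutoff unstated.
Alongside the p-value, the shape of each candidate–outcome relationship
is mapped (Pearson r, Spearman rho, a quadratic-term p-value) to judge
whether a linear description is adequate; the resulting flags
(`monotone_nonlinear` when |rho| − |r| > 0.1, `non_monotone` when the
quadratic term is significant while |rho| < 0.3) are advisory and logged,
never automatic exclusions.

**Stage 2 — collinearity reduction** (`factor_decompose()`,
`pick_representatives()`). Questionnaire scores are heavily
inter-correlated, and stepwise procedures behave erratically under
collinearity. A factor analysis of the screened candidates' correlation
matrix — principal-component extraction, Kaiser criterion (eigenvalue
> 1) for the number of factors, varimax rotation — identifies clusters
of collinear variables: a candidate joins the factor on which it loads
most strongly provided |loading| ≥ 0.6. From each cluster only the
most important member (largest absolute loading; ties broken by smaller
bivariable p, then name) continues. Extraction method, factor-count rule
and the 0.6 threshold are conventional defaults in the clinical
literature and are configurable and echoed in every report. We run this
stage on the screening survivors rather than on all candidates: the set
that continues is the intersection of screened and representative
either way, and the representative tie-break uses the screening table.

**Stage 3 — consensus selection** (`forward_select()`,
`backward_select()`, `lasso_select()`, `consensus_select()`). Three
selection processes are applied to the reduced set, each always keeping
the forced baseline covariate:

* forward: add the candidate with the smallest nested-improvement
  p-value (F-change test for linear models, likelihood-ratio test for
  logistic) while it is below `entry_alpha` (0.05);
* backward: from the full model, drop the covariate with the largest
  removal p-value while it is ≥ `stay_alpha` (0.05);
* Lasso (linear outcomes only): L1-penalized fit with the penalty chosen
  by seeded 10-fold cross-validation at minimum CV error; forced
  covariates are unpenalized (`penalty.factor = 0`).

A candidate is retained when it is at least weakly significant
(p < 0.05) in two of the three processes and highly significant
(p < 0.001) in at least one. The Lasso path carries no native p-values,
so its significance is taken from an unpenalized refit on the selected
set — a declared convention, since how the original analyses scored
Lasso significance is unstated. For binary outcomes, where the Lasso
does not apply, the rule degrades to weakly significant in both
remaining processes plus one strong.

**Stage 4 — characterization and internal validation.** The final
multivariable model is characterized by adjusted R² (linear) or the
c-statistic (logistic); values below 0.3 / 0.6 mark the model as
irrelevant, with the thresholds strict-below (a model exactly at the
threshold is relevant). The retained covariates are re-entered one at a
time from most to least influential (by absolute standardized estimate),
each step tested by F-change or likelihood ratio
(`incremental_inclusion()`). Robustness (`robustness_check()`) excludes
aberrant value ranges — by default rows whose predictions fall outside
the 5th–95th percentile or whose standardized residuals exceed 2.5 —
refits, and calls the model robust when the metric retains at least half
its value and stays above the relevance threshold. The retained
fraction of one half is our operationalization of "considerable
decrease": it separates metric collapses such as 0.57 → 0.10 or
0.54 → 0.21 from stable behavior such as 0.34 → 0.34. The original
exclusion criterion was visual; ours is an explicit, configurable rule,
and the percentile window intentionally trims the extreme 10% of
predictions even when nothing is aberrant, which on clean data shaves a
few hundredths off R² through range restriction (the robust verdict is
unaffected).

**Optimism** (`bootstrap_optimism()`). Apparent performance of a model
selected and fitted on the same data overstates its transportable
performance. The whole selection process — screening, reduction, the
three processes, the consensus — is repeated on `B` bootstrap resamples
(default `B = 200`, seeded); each resample's model is scored on the
resample (`apparent_b`) and on the original cohort (`test_b`), both with
the same adjusted-R²/c-statistic functional. The optimism is
`mean(apparent_b − test_b)` and the corrected performance is the
original apparent value minus it. Replicates with an empty consensus
fall back to the forced-only model; replicates that cannot be fit (e.g.
a one-class logistic resample) are dropped and counted.

A limitation worth knowing: with many noise candidates and small n, the
test suite's null simulations show the correction slightly overshooting
below zero (corrected adjusted R² around −0.11 at n = 100 with 40 noise
candidates). Bootstrap resamples duplicate about 37% of rows, which
inflates in-resample significance, so the consensus fires inside
replicates more often than on fresh data and the optimism estimate is
biased upward. We keep the symmetric functional — the same adjusted
metric on both sides — because that is what the correction as described
demands; treat a mildly negative corrected value on null-like data as
"no transportable signal", not as a meaningful magnitude.

## The nomogram

`build_nomogram()` turns the final equation into the classic
points-based chart. Each predictor's influence is
|estimate| × (range width); the largest influence is anchored to span
exactly 0–100 points, every predictor's zero-points end is the covariate
value minimizing its contribution (so all points are non-negative), and
total points map affinely back to the linear predictor. The construction
is exact: a nomogram read-off and the direct equation agree to floating
point on every input inside the declared ranges, which the test suite
verifies on 1000 random points. Ranges default to the observed min/max
of the fitted cohort and can be overridden with instrument ranges (0–10
for an NRS, 0–38 for the painDETECT total, 0–21 for HADS subscales).
Published equations can be encoded directly with
`prediction_equation()`; the evaluator is link-agnostic and reports both
the linear score and its inverse-logit, because printed equations for
binary outcomes do not always say which scale they live on.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a titration-then-
randomization analgesic trial: n = 311 subjects by default (the scale of
50 open-label optimal responders plus 261 randomized patients), 46
candidate covariates named and ranged after the usual instruments,
block-correlated Gaussian latents (blocks of 4 at ρ = 0.4, mimicking
questionnaire families) optionally discretized rank-preservingly onto
bounded integer instrument scales. The outcome is built from a sparse
standardized-effect map plus the baseline value of the outcome
(standardized effect 0.3) with the noise calibrated so the latent
outcome has unit variance — an effect entry of 0.3 is then, up to
discretization, the standardized estimate a correct model recovers.
Titration is modelled as baseline NRS-3 around 7.5 (clipped to the 6–10
eligibility window) minus a Normal(2.2, 1.5) treatment drop; the derived
labels (end < 4: optimal responder; drop ≥ 1 and end ≥ 4: randomized)
yield roughly the trial's published group proportions, and randomized
subjects split ~127:134 between the arms. These values were fixed once
as plausible for a severe chronic low back pain population.

What the generator does **not** emulate: real questionnaire marginals
(floor/ceiling effects, skew), informative missingness (the generator
produces complete data; the pipeline's complete-case behavior is
exercised by tests that remove values), measurement error structure, or
any relationship between the titration response and the candidate
covariates beyond NRS-3 itself. Passing the simulation suites therefore
shows the algorithm's statistical properties under clean, correctly
specified conditions — not that any particular clinical dataset will
yield a stable model.

`make_null_cohort()` is the global-null reference: all candidates and
the baseline independent of the outcome. The test suite uses it to check
that screening retention approaches the screening level, that false
consensus is rare (per-candidate retention ≤ 0.02 across 200 cohorts of
n = 260 with 46 candidates — the strong-significance requirement makes
consensus-level false positives an order of magnitude rarer than the
screening level), and the optimism behavior above. The recovery suite
(100 cohorts, five true standardized effects of 0.3, n = 260,
independent candidates) requires at least 70% of true predictors to be
retained on average. Suite sizes were chosen to keep the full test run
within a few minutes while leaving the binomial noise of each rate well
inside its asserted margin.

## Numerical and degenerate-case choices

* Linear Wald p-values use the t distribution with n − p − 1 degrees of
  freedom (small-sample correctness); logistic Wald tests use the normal
  approximation. Which reference the original tooling used is unstated.
* Logistic fits converge on a relative-deviance tolerance of 1e−10
  (max 100 IRLS iterations); quasi-separation is flagged when any
  per-SD coefficient magnitude exceeds 15.
* Rank-deficient designs are an error naming the dependent columns —
  the collinearity stage exists to prevent them.
* Missing data: complete-case analysis per fitted model; nothing is
  imputed. How missing questionnaire items were handled originally is
  unstated, so the package records missingness per column
  (`validate_cohort()`) and leaves imputation out of scope.
* Identical nested models compare with statistic 0 and p = 1; the
  F-change statistic is floored at 0 against floating-point negatives.
* Factor solutions are made deterministic under column permutation by
  sign-anchoring each rotated factor at its largest-loading variable and
  ordering factors by explained variance.
* Quasi-continuous instrument scores are modelled as continuous
  throughout; ordinal candidates enter the correlation matrix as numeric
  scores.
* One user seed drives everything through deterministic per-stage
  substreams, so changing `B` never perturbs screening or CV folds, and
  a pipeline run is byte-reproducible (the report JSON is identical
  across runs with the same cohort, config and seed).

## Known limitations

Beyond the optimism overshoot discussed above: the pipeline offers no
spline or fractional-polynomial remodeling for candidates flagged as
non-linear (the flags are informational); no oblique factor rotations or
parallel analysis; no elastic net or stability selection; no imputation
and no repeated-measures modelling. Post-selection p-values reported by
the selection outcomes are conditional on selection and optimistic by
construction — they are inputs to the consensus rule, not honest
inferential statements about the final model.
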