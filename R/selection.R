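#' Stepwise and Lasso selection processes
#'
#' Stage 3 applies three selection processes to the screened,
#' collinearity-reduced candidate set, each always keeping the forced
#' covariates (the baseline value of the outcome) in the model:
#'
#' * `forward_select()` starts from the forced-only model and repeatedly
#'   adds the candidate with the smallest nested-improvement p-value
#'   (F-change for linear outcomes, likelihood-ratio for logistic) while
#'   that p-value is below `entry_alpha`.
#' * `backward_select()` starts from the full model and repeatedly removes
#'   the non-forced covariate with the largest removal p-value while that
#'   p-value is at or above `stay_alpha`.
#' * `lasso_select()` fits an L1-penalized linear model (candidates
#'   penalized, forced covariates not) with the penalty chosen by 10-fold
#'   cross-validation at the minimum CV error; candidates with nonzero
#'   penalized coefficients are selected. The Lasso path itself carries no
#'   p-values, so significance for the consensus rule is taken from an
#'   unpenalized refit on the selected set. The Lasso applies to linear
#'   (continuous) outcomes only.
#'
#' All three report, per selected candidate, the Wald p-value and estimate
#' from the final (or refit) unpenalized model; forced covariates appear
#' in every final model but are never counted as selected.
#'
#' @param data Cohort or data frame.
#' @param outcome Outcome column name.
#' @param forced Character vector of always-included covariates.
#' @param candidates Character vector of candidate names.
#' @param entry_alpha,stay_alpha Entry / stay thresholds (default 0.05).
#' @param family `"auto"`, `"linear"` or `"logistic"`.
#' @return A tibble of class `selection_outcome`, one row per selected
#'   candidate: `method`, `term`, `estimate`, `p_value`. Attributes:
#'   `"candidates"` (the offered universe), `"fit"` (the final
#'   `pred_fit`), `"method"`.
#' @export
forward_select <- function(data, outcome, forced, candidates,
                           entry_alpha = 0.05,
                           family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  if (family == "auto") family <- infer_family(data[[outcome]])
  d <- complete_model_frame(data, outcome, unique(c(forced, candidates)))
  selected <- character()
  pool <- setdiff(candidates, forced)
  current <- fit_model(d, outcome, forced, family = family)
  repeat {
    if (length(pool) == 0) break
    ps <- vapply(pool, function(cand) {
      fit <- fit_model(d, outcome, c(forced, selected, cand), family = family)
      nested_p(current, fit, family)
    }, numeric(1))
    best <- which.min(ps)
    if (ps[best] >= entry_alpha) break
    selected <- c(selected, pool[best])
    pool <- pool[-best]
    current <- fit_model(d, outcome, c(forced, selected), family = family)
  }
  selection_outcome("forward", current, selected, candidates)
}

#' @rdname forward_select
#' @export
backward_select <- function(data, outcome, forced, candidates,
                            stay_alpha = 0.05,
                            family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  if (family == "auto") family <- infer_family(data[[outcome]])
  d <- complete_model_frame(data, outcome, unique(c(forced, candidates)))
  selected <- setdiff(candidates, forced)
  current <- fit_model(d, outcome, c(forced, selected), family = family)
  repeat {
    if (length(selected) == 0) break
    ps <- vapply(selected, function(cand) {
      fit <- fit_model(d, outcome, setdiff(c(forced, selected), cand),
                       family = family)
      nested_p(fit, current, family)
    }, numeric(1))
    worst <- which.max(ps)
    if (ps[worst] < stay_alpha) break
    selected <- selected[-worst]
    current <- fit_model(d, outcome, c(forced, selected), family = family)
  }
  selection_outcome("backward", current, selected, candidates)
}

nested_p <- function(reduced, full, family) {
  if (family == "linear") f_change_test(reduced, full)$p_value
  else likelihood_ratio_test(reduced, full)$p_value
}

#' @rdname forward_select
#' @param lambda Optional fixed penalty; `NULL` (default) selects the
#'   penalty by 10-fold cross-validation at minimum CV error.
#' @param seed Integer seed for the cross-validation folds.
#' @export
lasso_select <- function(data, outcome, forced, candidates,
                         lambda = NULL, seed = 1L,
                         family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  if (family == "auto") family <- infer_family(data[[outcome]])
  if (family != "linear") {
    abort("The Lasso process applies to linear (continuous) outcomes only.")
  }
  d <- complete_model_frame(data, outcome, unique(c(forced, candidates)))
  pool <- setdiff(candidates, forced)
  vars <- c(forced, pool)
  x <- as.matrix(d[vars])
  y <- d[[outcome]]
  pf <- c(rep(0, length(forced)), rep(1, length(pool)))
  excl <- integer()
  if (ncol(x) < 2) {
    # glmnet needs >= 2 columns; pad with a hard-excluded dummy
    x <- cbind(x, .dummy = with_seed(substream_seed(seed, "lasso_dummy"),
                                     rnorm(nrow(x))))
    pf <- c(pf, 1)
    excl <- ncol(x)
  }
  if (is.null(lambda)) {
    folds <- with_seed(substream_seed(seed, "lasso_cv"),
                       sample(rep_len(seq_len(10), nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, penalty.factor = pf, foldid = folds,
                            exclude = excl, standardize = TRUE)
    lambda <- cv$lambda.min
    fitnet <- cv$glmnet.fit
  } else {
    fitnet <- glmnet::glmnet(x, y, penalty.factor = pf, exclude = excl,
                             standardize = TRUE)
  }
  b <- as.numeric(coef(fitnet, s = lambda, exact = TRUE, x = x, y = y,
                       penalty.factor = pf, exclude = excl))
  names(b) <- rownames(coef(fitnet, s = lambda))
  selected <- pool[abs(b[pool]) > 1e-10]
  refit <- fit_model(d, outcome, c(forced, selected), family = "linear")
  out <- selection_outcome("lasso", refit, selected, candidates)
  attr(out, "lasso_coef") <- b[setdiff(names(b), ".dummy")]
  attr(out, "lambda") <- lambda
  out
}

selection_outcome <- function(method, fit, selected, candidates) {
  co <- fit$coefficients
  out <- tibble::tibble(
    method = method,
    term = selected,
    estimate = co$estimate[match(selected, co$term)],
    p_value = co$p_value[match(selected, co$term)]
  )
  attr(out, "candidates") <- candidates
  attr(out, "fit") <- fit
  attr(out, "method") <- method
  class(out) <- c("selection_outcome", class(out))
  out
}

#' @rdname forward_select
#' @param x A `selection_outcome`.
#' @export
selection_fit <- function(x) attr(x, "fit")

#' Consensus of the selection processes
#'
#' Combines the per-method selections into the final predictor set using
#' the published consensus rule: a candidate is retained when it is at
#' least weakly significant (p < `weak_alpha`, default 0.05) in two out of
#' the three selection processes and at least highly significant
#' (p < `strong_alpha`, default 0.001) in one. For binary outcomes the
#' Lasso is not applicable, and the rule degrades to weakly significant in
#' both remaining processes plus highly significant in one. A candidate
#' not selected by a method contributes nothing to that method's counts.
#'
#' @param outcomes A list of 2 or 3 `selection_outcome` objects over the
#'   same candidate universe.
#' @param weak_alpha,strong_alpha Significance levels of the rule.
#' @return A tibble of class `consensus_result`, one row per candidate in
#'   the universe: `candidate`, `weak_count`, `strong_count`, `n_methods`,
#'   `retained`, plus one p-value column per method. The retained set is
#'   attached as attribute `"retained"`.
#' @export
consensus_select <- function(outcomes, weak_alpha = 0.05,
                             strong_alpha = 0.001) {
  if (!length(outcomes) %in% c(2L, 3L)) {
    abort("consensus_select expects 2 or 3 selection outcomes.")
  }
  universes <- purrr::map(outcomes, attr, "candidates")
  if (length(unique(purrr::map_chr(universes, paste, collapse = "\r"))) != 1) {
    abort("Selection outcomes cover different candidate universes.")
  }
  universe <- universes[[1]]
  methods <- purrr::map_chr(outcomes, attr, "method")
  if (anyDuplicated(methods)) abort("Duplicate selection methods supplied.")
  n_methods <- length(outcomes)
  pmat <- purrr::map(outcomes, function(o) {
    p <- rep(NA_real_, length(universe))
    p[match(o$term, universe)] <- o$p_value
    p
  })
  names(pmat) <- paste0("p_", methods)
  out <- tibble::as_tibble(c(list(candidate = universe), pmat))
  pm <- as.matrix(out[paste0("p_", methods)])
  weak <- rowSums(pm < weak_alpha, na.rm = TRUE)
  strong <- rowSums(pm < strong_alpha, na.rm = TRUE)
  need_weak <- if (n_methods == 3) 2L else 2L
  out$weak_count <- as.integer(weak)
  out$strong_count <- as.integer(strong)
  out$n_methods <- n_methods
  out$retained <- weak >= need_weak & strong >= 1
  out <- out[, c("candidate", "weak_count", "strong_count", "n_methods",
                 "retained", paste0("p_", methods))]
  attr(out, "retained") <- out$candidate[out$retained]
  class(out) <- c("consensus_result", class(out))
  out
}

#' @rdname consensus_select
#' @param x A `consensus_result`.
#' @export
consensus_retained <- function(x) attr(x, "retained")
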