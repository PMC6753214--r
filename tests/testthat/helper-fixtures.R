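# Shared fixture builders; everything generated in code under fixed seeds.

toy_specs <- function(cands = c("NRS3", "SQ")) {
  var_specs(
    name = c("id", cands),
    role = c("id", rep("candidate", length(cands)))
  )
}

# n x k design with exactly orthonormal columns (t(X) %*% X = I * n)
orthonormal_design <- function(n, k, seed = 1) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(n * (k + 1)), n)))[, seq_len(k), drop = FALSE]
    sweep(Q, 2, sqrt(colSums(Q^2) / n), "/")
  })
}

lin_data <- function(n, beta, noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n)
    colnames(X) <- paste0("x", seq_along(beta))
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- as.numeric(X %*% beta) + rnorm(n, sd = noise_sd)
    d
  })
}

# residual sum of squares of y ~ X[, idx] with intercept
rss_of <- function(d, outcome, terms) {
  m <- lm(conselect:::model_formula(outcome, terms), data = d)
  sum(residuals(m)^2)
}

# best subset of the given size by residual sum of squares (enumeration)
best_subset <- function(d, outcome, candidates, size) {
  if (size == 0) return(character())
  combos <- utils::combn(candidates, size, simplify = FALSE)
  rss <- vapply(combos, function(s) rss_of(d, outcome, s), numeric(1))
  sort(combos[[which.min(rss)]])
}

# hand-built selection outcome for consensus tests
fake_selection <- function(method, terms, p_values, universe) {
  out <- tibble::tibble(method = method, term = terms,
                        estimate = rep(1, length(terms)),
                        p_value = p_values)
  attr(out, "candidates") <- universe
  attr(out, "method") <- method
  class(out) <- c("selection_outcome", class(out))
  out
}
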