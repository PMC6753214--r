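#' Factor-analytic grouping of collinear candidates
#'
#' Stage 2 of the algorithm: a factor analysis of the candidates'
#' correlation matrix identifies variables with a high potential for
#' collinearity. Factors are extracted by principal components, retained
#' by the Kaiser criterion (eigenvalue > 1) by default, and rotated to
#' orthogonal simple structure (varimax). Each candidate is assigned to
#' the factor on which it has its largest absolute loading, provided that
#' loading reaches `loading_threshold`; candidates reaching the threshold
#' on no factor form singleton groups. Groups therefore partition the
#' candidate set, and [pick_representatives()] keeps exactly one variable
#' per group.
#'
#' @param data Cohort or data frame (ordinal candidates enter as numeric
#'   scores).
#' @param candidates Character vector of at least two candidate names.
#' @param loading_threshold Minimum absolute rotated loading for a
#'   candidate to join a factor group (default 0.6).
#' @param n_factors `"kaiser"` (eigenvalue > 1) or an explicit integer.
#' @return A tibble of class `factor_groups`, one row per candidate:
#'   `group`, `member`, `loading` (the member's loading on the group's
#'   factor; for singletons the largest absolute loading across factors),
#'   `singleton`. The full rotated loadings matrix is attached as
#'   attribute `"loadings"`.
#' @export
factor_decompose <- function(data, candidates, loading_threshold = 0.6,
                             n_factors = "kaiser") {
  check_columns(data, candidates)
  if (length(candidates) < 2) {
    abort("factor_decompose needs at least two candidates.")
  }
  d <- tibble::as_tibble(data)[candidates]
  d <- d[complete.cases(d), , drop = FALSE]
  sds <- vapply(candidates, function(v) sd(d[[v]]), numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("Constant candidate(s): %s",
                  paste(candidates[sds == 0], collapse = ", ")))
  }
  if (nrow(d) <= length(candidates)) {
    warn(sprintf(
      "Only %d complete rows for %d candidates; factor solution is unstable.",
      nrow(d), length(candidates)))
  }
  R <- cor(as.matrix(d))
  eig <- eigen(R, symmetric = TRUE)
  k <- if (identical(n_factors, "kaiser")) sum(eig$values > 1)
       else as.integer(n_factors)
  k <- max(min(k, length(candidates)), 1)
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  if (k >= 2) L <- unclass(varimax(L, normalize = TRUE)$loadings)
  # canonical orientation/order so column permutations of the input
  # cannot flip signs or reorder factors
  for (j in seq_len(k)) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  ord <- order(-colSums(L^2))
  L <- L[, ord, drop = FALSE]
  dimnames(L) <- list(candidates, paste0("F", seq_len(k)))

  best_factor <- apply(abs(L), 1, which.max)
  best_loading <- L[cbind(seq_along(candidates), best_factor)]
  joins <- abs(best_loading) >= loading_threshold
  group <- ifelse(joins, paste0("F", best_factor),
                  paste0("singleton_", candidates))
  out <- tibble::tibble(
    group = group,
    member = candidates,
    loading = best_loading,
    singleton = !joins
  )
  # a factor that captured only one member is a singleton group too
  multi <- names(which(table(out$group) > 1))
  out$singleton <- !(out$group %in% multi)
  out <- dplyr::arrange(out, .data$group, dplyr::desc(abs(.data$loading)))
  attr(out, "loadings") <- L
  attr(out, "loading_threshold") <- loading_threshold
  class(out) <- c("factor_groups", class(out))
  out
}

#' Pick one representative per collinearity group
#'
#' Among strongly correlating variables the most important one — the
#' member with the largest absolute factor loading — is selected for
#' further analysis. Ties on the loading are broken by the smaller
#' bivariable screening p-value (when a screening table is supplied),
#' then lexicographically by name.
#'
#' @param groups A `factor_groups` tibble from [factor_decompose()].
#' @param screen Optional [bivariable_screen()] result used for
#'   tie-breaking.
#' @return A tibble, one row per group: `group`, `representative`,
#'   `loading`, `n_members`. The representative set (a character vector in
#'   stable order) is attached as attribute `"representatives"`.
#' @export
pick_representatives <- function(groups, screen = NULL) {
  if (nrow(groups) == 0) abort("Empty group table.")
  p_of <- function(m) {
    if (is.null(screen)) return(rep(0, length(m)))
    idx <- match(m, screen$candidate)
    ifelse(is.na(idx), 1, screen$p_value[idx])
  }
  out <- groups |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(g, key) {
      ord <- order(-abs(g$loading), p_of(g$member), g$member)
      tibble::tibble(
        representative = g$member[ord[1]],
        loading = g$loading[ord[1]],
        n_members = nrow(g)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$representative)
  attr(out, "representatives") <- out$representative
  out
}
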