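# Internal helpers shared across stages.

# Deterministic per-stage substreams from one user-facing seed, so that e.g.
# raising the bootstrap replicate count never perturbs screening or CV folds.
# Keeps derived seeds in [0, 2^31 - 2].
substream_seed <- function(seed, stage, index = 0L) {
  stage_hash <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + stage_hash * 9973 + index) %% 2147483646)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

inv_logit <- function(x) stats::plogis(x)

check_columns <- function(data, cols, where = "cohort") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "Column%s %s not found in %s.",
      if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", "), where
    ))
  }
  invisible(data)
}

# Family inferred from the outcome's values: two distinct values -> logistic.
infer_family <- function(y) {
  vals <- unique(y[!is.na(y)])
  if (length(vals) == 2) "logistic" else "linear"
}
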