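# Internal helpers shared across modules.

# Run `expr` under a local, restorable RNG state when `seed` is given.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Assert that `df` contains columns `cols`; error names the offender.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Fraction in [0, 1] check for vectorised probabilities.
check_fraction <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Average rank with ties, descending by default (rank 1 = largest).
rank_desc <- function(x) rank(-x, ties.method = "average")
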