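# Internal helpers shared across modules.

# Set the RNG locally for the calling frame when `seed` is given; leaves the
# caller's RNG state untouched either way.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
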