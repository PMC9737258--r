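# Run code under a temporary RNG seed; NULL seed uses the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive a per-stage seed from a base seed, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s (got %s).", name, min, x))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  if (x > max) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, max, x))
  }
  invisible(x)
}

require_columns <- function(df, cols, arg) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
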