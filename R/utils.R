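# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is given, without disturbing
# the caller's RNG state; run as-is when seed is NULL.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive an independent per-stage seed from a single global seed. Simple
# documented arithmetic rule (kept below .Machine$integer.max) so pipeline
# stages get distinct, reproducible streams.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) + 7919 * as.double(stage)) %% (2^31 - 1))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (open_lo) x > lo else x >= lo) &&
    all(if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s, got %s.",
      name, if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %g.", name, min))
  }
  invisible(x)
}
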