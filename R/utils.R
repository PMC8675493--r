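# Internal numeric helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Winsorise a numeric vector at the given percentile limits (e.g. c(1, 99)).
# NaN/NA entries are ignored when computing the limits and pass through.
winsorise <- function(x, limits = c(1, 99)) {
  stopifnot(length(limits) == 2L, limits[1] < limits[2])
  ok <- is.finite(x)
  if (!any(ok)) return(x)
  q <- stats::quantile(x[ok], probs = limits / 100, names = FALSE)
  x[ok] <- clamp(x[ok], q[1], q[2])
  x
}

# Deterministic seed derivation: one user seed fans out to per-stage seeds
# without reuse. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483562L
}
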