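# Small shared helpers.

# Population (divide-by-n) standard deviation; the z-normalization of
# conservation scores uses this so the SD-1 invariant holds exactly.
popSD <- function(x) sqrt(mean((x - mean(x))^2))

# Trapezoid integral over possibly non-uniform x.
trapezoid <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

# Deterministic child seed derived from a master seed, kept below 2^31.
deriveSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 2147483L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
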