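# Error function and complement, on the conventional scale
# (erf(x) = 2*Phi(x*sqrt(2)) - 1).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

# Derive a per-day RNG seed from a base seed, staying inside 32-bit range.
derive_seed <- function(seed, day) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(day)) %% 2147483629L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
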