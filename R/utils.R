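# Shared numerical helpers.

#' Trapezoid quadrature weights
#'
#' Weights `w` such that `sum(w * f(t))` approximates the integral of `f`
#' over `[min(t), max(t)]` by the trapezoid rule.
#'
#' @param t Strictly increasing numeric vector of length >= 2.
#' @return Numeric vector of weights, same length as `t`.
#' @keywords internal
trapezoid_weights <- function(t) {
  K <- length(t)
  if (K < 2) stop("need at least two points for trapezoid quadrature")
  dt <- diff(t)
  c(dt[1] / 2, (dt[-(K - 1)] + dt[-1]) / 2, dt[K - 1] / 2)
}

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 100000L) * 10000L + seq_len(n)
}

# Round times to a common key so grid lookups are exact across
# concatenation/sorting round-offs.
time_key <- function(t) round(t, 9)
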