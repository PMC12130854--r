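#' Generalized harmonic number
#'
#' `H_N(x) = sum_{n=1}^{N} n^(-x)`, by direct summation. Converges to the
#' Riemann zeta function `zeta(x)` as `N` grows when `x > 1`.
#'
#' @param x Real exponent (vectorized).
#' @param N Number of terms, at least 1.
#' @return `H_N(x)`, same length as `x`.
#' @export
#' @examples
#' harmonic_number(1, 3) # 11/6
harmonic_number <- function(x, N) {
  stopifnot(N >= 1, N == floor(N))
  n <- as.numeric(seq_len(N))
  vapply(x, function(xi) sum(n^(-xi)), numeric(1))
}

#' Riemann zeta function with an explicit divergence marker
#'
#' For `x > 1` returns `zeta(x)`; for `x <= 1` the defining series diverges
#' and the function returns `Inf`, so callers must handle the divergent
#' branch deliberately (it is a value, not an error).
#'
#' @param x Real argument (vectorized).
#' @return `zeta(x)` for `x > 1`, `Inf` otherwise.
#' @export
#' @examples
#' riemann_zeta(2) # pi^2 / 6
#' riemann_zeta(1) # Inf
riemann_zeta <- function(x) {
  out <- rep(Inf, length(x))
  conv <- x > 1
  if (any(conv)) out[conv] <- Re(pracma::zeta(x[conv]))
  out
}
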