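#' Mean population response (tuning curve) at a stimulus angle
#'
#' The noiseless mean response `m(theta)`: neuron `2n - 1` fires
#' `n^(-alpha/2) * cos(n * theta)` and neuron `2n` fires
#' `n^(-alpha/2) * sin(n * theta)`, over the retained modes of `spec`.
#'
#' @param spec A [code_spec()] with `D = 1`.
#' @param theta Stimulus angle in radians (any real; evaluation is periodic).
#' @return Numeric vector of length `2 * length(spec$modes)`.
#' @export
#' @examples
#' tuning_curve(code_spec(3, alpha = 2), 0)
tuning_curve <- function(spec, theta) {
  check_d1(spec)
  stopifnot(length(theta) == 1, is.finite(theta))
  n <- spec$modes
  amp <- n^(-spec$alpha / 2)
  interleave(amp * cos(n * theta), amp * sin(n * theta))
}

#' Susceptibility of the mean response to the stimulus
#'
#' The exact derivative `mu = d m / d theta` of the tuning curve: neuron
#' `2n - 1` contributes `-n^(1 - alpha/2) * sin(n * theta)` and neuron `2n`
#' contributes `n^(1 - alpha/2) * cos(n * theta)`. Its squared norm is the
#' generalized harmonic number `H_N(alpha - 2)`, which controls both the
#' covariance eigenvalue along `mu` and the Fisher information of the code.
#'
#' @inheritParams tuning_curve
#' @return Numeric vector of length `2 * length(spec$modes)`.
#' @export
susceptibility <- function(spec, theta) {
  check_d1(spec)
  stopifnot(length(theta) == 1, is.finite(theta))
  n <- spec$modes
  amp <- n^(1 - spec$alpha / 2)
  interleave(-amp * sin(n * theta), amp * cos(n * theta))
}

#' Mean-square population activity (energy cost of the code)
#'
#' The stimulus- and noise-averaged total mean-square activity of the
#' retained modes, `sum(n^-alpha)`. For the full code this converges to the
#' Riemann zeta function `zeta(alpha)` as `N` grows; it is the energy term of
#' the energy-aware performance measure.
#'
#' @param spec A [code_spec()].
#' @return Scalar energy in squared response units.
#' @export
#' @examples
#' population_energy(code_spec(1e6, alpha = 2)) # ~ pi^2 / 6
population_energy <- function(spec) {
  stopifnot(inherits(spec, "code_spec"))
  sum(as.numeric(spec$modes)^(-spec$alpha))
}

check_d1 <- function(spec) {
  stopifnot(inherits(spec, "code_spec"))
  if (!identical(spec$D, 1L) && !(is.numeric(spec$D) && spec$D == 1)) {
    abort("Simulation and tuning curves are defined for D = 1 only.")
  }
  invisible(spec)
}

interleave <- function(a, b) {
  out <- numeric(2 * length(a))
  out[c(TRUE, FALSE)] <- a
  out[c(FALSE, TRUE)] <- b
  out
}
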