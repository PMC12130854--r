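#' Critical power-law exponent
#'
#' The exponent `alpha_c = 1 + 2/D` separating smooth (differentiable) from
#' fractal (nondifferentiable) neural manifolds for a `D`-dimensional
#' stimulus; the Fisher information of the code has a kink exactly there, and
#' the energy-aware performance is maximized there. `D = Inf` gives the limit
#' `alpha_c = 1`, the decay exponent expected for effectively
#' infinite-dimensional inputs such as natural images.
#'
#' @param D Input dimension (positive integer or `Inf`; vectorized).
#' @return `1 + 2/D`.
#' @export
#' @examples
#' critical_exponent(1) # 3
#' critical_exponent(Inf) # 1
critical_exponent <- function(D) {
  if (any(!is.infinite(D) & (D < 1 | D != floor(D)))) {
    abort("`D` must be a positive integer or Inf.")
  }
  1 + 2 / D
}

#' Fisher information of the finite power-law code
#'
#' For a population of `2N` neurons with amplitude spectrum `n^(-alpha/2)`,
#' neural noise `sigma0` and input noise `sigma1`, the Fisher information
#' about the stimulus angle is
#' `H_N(alpha - 2) / (sigma0^2 + sigma1^2 * H_N(alpha - 2))` — independent of
#' the stimulus. The input-noise term in the denominator is the
#' information-limiting (differential) correlation: it caps the information
#' at `1 / sigma1^2` no matter how large the population.
#'
#' @param alpha Power-law exponent (vectorized).
#' @param N Number of Fourier modes.
#' @param sigma0,sigma1 Neural- and input-noise standard deviations; at least
#'   one must be positive.
#' @return Fisher information in radians^-2.
#' @export
#' @examples
#' fisher_finite(4, 100, 0.01, 0.01)
fisher_finite <- function(alpha, N, sigma0, sigma1) {
  if (sigma0 == 0 && sigma1 == 0) {
    abort("Degenerate model: with sigma0 = sigma1 = 0 the information is infinite.")
  }
  h <- harmonic_number(alpha - 2, N)
  h / (sigma0^2 + sigma1^2 * h)
}

#' Fisher information in the infinite-population limit
#'
#' The large-`N` limit of the Fisher information for a `D`-dimensional
#' stimulus component:
#' `zeta(alpha - 2/D) / (sigma0^2 * D * V_D^(2/D) / 4 + sigma_i^2 * zeta(alpha - 2/D))`,
#' with `V_D = pi^(D/2) / Gamma(D/2 + 1)` the unit-ball volume. For
#' `alpha <= alpha_c(D)` the zeta factor diverges and the information takes
#' its exact analytic plateau value `1 / sigma_i^2`, independent of the
#' neural noise `sigma0` — the code does not degrade even where the neural
#' manifold is fractal. `D = Inf` uses the dedicated limit with denominator
#' `e * pi * sigma0^2 / 2 + sigma_i^2 * zeta(alpha)`. The function is
#' continuous in `alpha` with a kink (one-sided slope discontinuity) at
#' `alpha_c`.
#'
#' @param alpha Power-law exponent (vectorized).
#' @param D Input dimension (positive integer or `Inf`).
#' @param sigma0 Neural-noise standard deviation.
#' @param sigma_i Input-noise standard deviation on the decoded component;
#'   must be positive (with `sigma_i = 0` the plateau diverges).
#' @return Fisher information in radians^-2, same length as `alpha`.
#' @export
#' @examples
#' fisher_limit(2, 1, 0.01, 0.01)  # plateau: 1 / 0.01^2
#' fisher_limit(4, 1, 0.01, 0.01)
fisher_limit <- function(alpha, D, sigma0, sigma_i) {
  stopifnot(length(D) == 1)
  if (sigma_i <= 0) {
    abort("Degenerate model: `sigma_i` must be positive (the plateau value is 1/sigma_i^2).")
  }
  z <- riemann_zeta(alpha - if (is.infinite(D)) 0 else 2 / D)
  denom_neural <- if (is.infinite(D)) {
    exp(1) * pi * sigma0^2 / 2
  } else {
    # D * V_D^(2/D) / 4 via log-gamma, finite for any D
    sigma0^2 * D * exp((2 / D) * ((D / 2) * log(pi) - lgamma(D / 2 + 1))) / 4
  }
  out <- ifelse(is.infinite(z),
                1 / sigma_i^2,
                z / (denom_neural + sigma_i^2 * z))
  out
}

#' Covariance eigenvalue along the susceptibility direction
#'
#' The response covariance `Sigma = sigma0^2 I + sigma1^2 mu mu^T` has the
#' susceptibility `mu` as an eigenvector; its eigenvalue is
#' `lambda = sigma0^2 + sigma1^2 * H_N(alpha - 2)`.
#'
#' @inheritParams fisher_finite
#' @return The eigenvalue `lambda`, in squared response units.
#' @export
eigenvalue_lambda <- function(alpha, N, sigma0, sigma1) {
  sigma0^2 + sigma1^2 * harmonic_number(alpha - 2, N)
}

#' Energy-aware coding performance
#'
#' `J_D(alpha) = I_D(alpha) - gamma * E(alpha)`: Fisher information minus a
#' metabolic penalty proportional to the mean-square population activity,
#' which is `zeta(alpha)` for an infinite population and `H_N(alpha)` for a
#' finite one. Because the information is flat below the critical exponent
#' while the energy cost keeps falling as `alpha` grows, the optimum sits
#' exactly at `alpha_c = 1 + 2/D` for any sufficiently small `gamma > 0`.
#'
#' @inheritParams fisher_limit
#' @param gamma Regularization weight of the energy term; must be positive.
#' @param N `Inf` (default) for the zeta-function energy term (requires
#'   `alpha > 1`), or a finite mode count for `H_N(alpha)`.
#' @return `J_D(alpha)`, same length as `alpha`.
#' @export
#' @examples
#' energy_aware_performance(3, 1, 0.01, 0.01, gamma = 1e-3)
energy_aware_performance <- function(alpha, D, sigma0, sigma_i, gamma,
                                     N = Inf) {
  if (gamma <= 0) abort("The regularization weight must satisfy gamma > 0.")
  if (is.infinite(N)) {
    if (any(alpha <= 1)) {
      abort("With an infinite population the energy term zeta(alpha) requires alpha > 1.")
    }
    energy <- riemann_zeta(alpha)
    info <- fisher_limit(alpha, D, sigma0, sigma_i)
  } else {
    energy <- harmonic_number(alpha, N)
    info <- if (is.infinite(D)) fisher_limit(alpha, D, sigma0, sigma_i)
            else fisher_finite(alpha, N, sigma0, sigma_i)
  }
  info - gamma * energy
}

#' Fisher information of a mode-restricted code
#'
#' Replacing the full harmonic sum by the restricted sum
#' `H_S = sum_{n in modes} n^(2 - alpha)` gives the theoretical Fisher
#' information available to a decoder that only sees the retained modes'
#' neuron pairs: `H_S / (sigma0^2 + sigma1^2 * H_S)`. Low-frequency modes
#' dominate `H_S` whenever `alpha > 2`, which is why ablating them is far
#' more damaging than ablating high-frequency modes.
#'
#' @param subset A [neuron_subset()] or integer vector of retained modes.
#' @param alpha Power-law exponent.
#' @param sigma0,sigma1 Noise standard deviations.
#' @return Fisher information in radians^-2.
#' @export
subset_fisher <- function(subset, alpha, sigma0, sigma1) {
  modes <- if (inherits(subset, "neuron_subset")) subset$modes else subset
  if (length(modes) == 0) abort("Mode subset must be nonempty.")
  h <- sum(as.numeric(modes)^(2 - alpha))
  h / (sigma0^2 + sigma1^2 * h)
}

#' Fisher information under a broken power-law spectrum
#'
#' Reanalyses of cortical data suggest the eigenspectrum is better described
#' by two decay regimes: a shallow exponent `alpha1` up to mode `n_break`
#' (about the first ten eigenvalues, `alpha1 ~ 0.5`) and a steeper `alpha2`
#' beyond (`alpha2 ~ 1.2`). The amplitude spectrum is `n^(-alpha1/2)` for
#' `n <= n_break` and `c_b * n^(-alpha2/2)` above, with
#' `c_b = n_break^((alpha2 - alpha1)/2)` enforcing amplitude continuity at
#' the break. The Fisher information is the usual ratio with the harmonic
#' sum replaced by the two-segment sum.
#'
#' @param alpha1,alpha2 Exponents below and above the break.
#' @param n_break Last mode of the first segment, in `1..N`.
#' @param N Total number of modes.
#' @param sigma0,sigma1 Noise standard deviations.
#' @return Fisher information in radians^-2.
#' @export
#' @examples
#' broken_power_fisher(0.5, 1.2, 10, 1000, 0.01, 0.01)
broken_power_fisher <- function(alpha1, alpha2, n_break, N, sigma0, sigma1) {
  if (n_break < 1 || n_break > N) abort("`n_break` must lie in 1..N.")
  n1 <- as.numeric(seq_len(n_break))
  cb2 <- n_break^(alpha2 - alpha1)          # c_b^2
  h <- sum(n1^(2 - alpha1))
  if (n_break < N) {
    n2 <- as.numeric(seq.int(n_break + 1, N))
    h <- h + cb2 * sum(n2^(2 - alpha2))
  }
  h / (sigma0^2 + sigma1^2 * h)
}

#' Mutual information implied by the Fisher information
#'
#' In the large-population limit the mutual information between stimulus and
#' response is the stimulus entropy minus the average of
#' `0.5 * log(2 * pi * e / I(theta))`. The Fisher information of this code is
#' stimulus-independent, so for a uniform prior on `[0, 2pi)` the average is
#' exact: `log(2 * pi) - 0.5 * log(2 * pi * e / I)`. A general prior density
#' is integrated numerically (here too `I` is constant, so only the entropy
#' term changes). Monotonically increasing in `I`.
#'
#' @param fisher_value Fisher information, positive (vectorized for the
#'   uniform prior).
#' @param prior Either `"uniform"` or a density function on `[0, 2pi)`.
#' @return Mutual information in nats.
#' @export
#' @examples
#' mutual_information_from_fisher(1e4)
mutual_information_from_fisher <- function(fisher_value, prior = "uniform") {
  if (any(fisher_value <= 0)) abort("`fisher_value` must be positive.")
  half_log <- 0.5 * log(2 * pi * exp(1) / fisher_value)
  if (identical(prior, "uniform")) {
    return(log(2 * pi) - half_log)
  }
  stopifnot(is.function(prior))
  z <- integrate(prior, 0, 2 * pi)$value
  entropy <- integrate(function(t) {
    p <- prior(t) / z
    ifelse(p > 0, -p * log(p), 0)
  }, 0, 2 * pi)$value
  entropy - half_log
}
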