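# Independent oracles used across the suite. These deliberately re-derive
# quantities by routes different from the package implementation.

# Riemann zeta by partial sum plus Euler-Maclaurin correction.
zeta_em <- function(x, N = 1e4) {
  n <- seq_len(N)
  sum(n^(-x)) + N^(1 - x) / (x - 1) - 0.5 * N^(-x) + x * N^(-x - 1) / 12
}

# Brute-force trapezoid quadrature of the posterior integral: for each theta,
# integrate the Gaussian input-noise kernel against the neural-noise profile
# on an independent phi grid (shifted by a half step relative to any power
# of two), in log space.
oracle_log_posterior <- function(samples, spec, thetas, n_grid = 6000) {
  samples <- if (is.null(dim(samples))) matrix(samples, nrow = 1)
             else as.matrix(samples)
  phi <- 2 * pi * (seq_len(n_grid) - 0.5) / n_grid
  dphi <- 2 * pi / n_grid
  m_phi <- t(vapply(phi, function(p) tuning_curve(spec, p),
                    numeric(2 * length(spec$modes))))
  p <- ncol(samples)
  vapply(thetas, function(th) {
    total <- 0
    for (s in seq_len(nrow(samples))) {
      r <- samples[s, ]
      lg <- -colSums((t(m_phi) - r)^2) / (2 * spec$sigma0^2)
      d <- wrap_error(phi, th)
      le <- lg - d^2 / (2 * spec$sigma1^2)
      mx <- max(le)
      total <- total + mx + log(sum(exp(le - mx))) + log(dphi) -
        0.5 * log(2 * pi * spec$sigma1^2) -
        p / 2 * log(2 * pi * spec$sigma0^2)
    }
    total
  }, numeric(1))
}

# Phase estimate for a single-sinusoid code from summed quadrature readout.
oracle_phase_estimate <- function(samples) {
  (atan2(sum(samples[, 2]), sum(samples[, 1]))) %% (2 * pi)
}
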