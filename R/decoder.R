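#' Signed angular error on the circle
#'
#' Minimal-magnitude signed difference between an estimate and the true
#' angle, mapped to `(-pi, pi]`.
#'
#' @param estimate,truth Angles in radians (vectorized).
#' @return Wrapped errors in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_error(2 * pi - 0.1, 0) # -0.1
wrap_error <- function(estimate, truth) {
  d <- (estimate - truth) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Precompute the decoding grid: mean responses on a uniform angle grid, the
# circular Gaussian kernel of the input noise, and the gather indices of its
# window. grid_size defaults to max(4096, 16 N) so both the width-sigma1
# kernel and the mode-N oscillations of the neural-noise profile are
# resolved.
decoder_workspace <- function(spec, grid_size = NULL) {
  check_d1(spec)
  if (spec$sigma0 <= 0) {
    abort("Degenerate likelihood: `sigma0` must be positive.")
  }
  G <- if (is.null(grid_size)) max(4096L, 16L * spec$N) else as.integer(grid_size)
  phi <- 2 * pi * (seq_len(G) - 1) / G
  n <- spec$modes
  amp <- n^(-spec$alpha / 2)
  p <- 2L * length(n)
  m_grid <- matrix(0, G, p)
  phase <- outer(phi, n)
  m_grid[, c(TRUE, FALSE)] <- cos(phase) * rep(amp, each = G)
  m_grid[, c(FALSE, TRUE)] <- sin(phase) * rep(amp, each = G)
  energy <- sum(amp^2)
  dphi <- 2 * pi / G

  ws <- list(G = G, phi = phi, dphi = dphi, m_grid = m_grid, energy = energy,
             spec = spec)
  if (spec$sigma1 > 0) {
    half <- min(ceiling(10 * spec$sigma1 / dphi), (G - 1L) %/% 2L)
    offs <- seq.int(-half, half)
    ws$klog <- -(offs * dphi)^2 / (2 * spec$sigma1^2) -
      0.5 * log(2 * pi * spec$sigma1^2) + log(dphi)
    ws$idx <- outer(seq_len(G) - 1L, offs, function(j, o) (j + o) %% G) + 1L
    # full-length wrapped kernel spectrum for the FFT fast path
    d <- pmin(seq_len(G) - 1L, G - (seq_len(G) - 1L)) * dphi
    kern <- exp(-d^2 / (2 * spec$sigma1^2)) * dphi /
      sqrt(2 * pi * spec$sigma1^2)
    ws$kern_fft <- fft(kern)
  }
  ws
}

# Shared first stage: G x M matrix of per-observation log neural-noise
# profiles, plus the theta-independent additive constant.
ll_profiles <- function(samples, ws, shared_input_noise) {
  s0sq <- ws$spec$sigma0^2
  const <- -nrow(samples) * ncol(samples) / 2 * log(2 * pi * s0sq)
  lg <- ws$m_grid %*% t(samples) / s0sq
  lg <- sweep(lg, 2, (rowSums(samples^2) + ws$energy) / (2 * s0sq))
  if (shared_input_noise) {
    # one shared input-noise draw: profiles multiply under a single integral
    lg <- matrix(rowSums(lg), ncol = 1)
  }
  list(lg = lg, const = const)
}

# Fast evaluation for the estimator: exp-space circular convolution by FFT
# after a per-observation global max subtraction. Tail values that underflow
# are floored; they are hundreds of log-units below the peak and cannot
# affect the argmax.
ll_curve_fft <- function(samples, ws, shared_input_noise = FALSE) {
  pr <- ll_profiles(samples, ws, shared_input_noise)
  if (ws$spec$sigma1 == 0) {
    return(rowSums(pr$lg) + pr$const)
  }
  cmax <- apply(pr$lg, 2, max)
  p <- exp(sweep(pr$lg, 2, cmax))
  conv <- Re(stats::mvfft(stats::mvfft(p) * ws$kern_fft,
                          inverse = TRUE)) / ws$G
  rowSums(log(pmax(conv, 1e-310))) + sum(cmax) + pr$const
}

# Exact log-space evaluation of the posterior integral on the grid: the
# neural-noise profile g_r(phi) = -||r - m(phi)||^2 / (2 sigma0^2) is
# circularly smoothed by the Gaussian input-noise kernel via a windowed
# log-sum-exp (trapezoid quadrature on the periodic grid). Finite everywhere.
ll_curve_impl <- function(samples, ws, shared_input_noise = FALSE) {
  pr <- ll_profiles(samples, ws, shared_input_noise)
  if (ws$spec$sigma1 == 0) {
    return(rowSums(pr$lg) + pr$const)
  }
  total <- numeric(ws$G)
  for (s in seq_len(ncol(pr$lg))) {
    a <- matrix(pr$lg[, s][ws$idx], nrow = ws$G)
    a <- sweep(a, 2, ws$klog, `+`)
    rm <- a[cbind(seq_len(ws$G), max.col(a, ties.method = "first"))]
    total <- total + rm + log(rowSums(exp(a - rm)))
  }
  total + pr$const
}

as_sample_matrix <- function(samples) {
  if (is.null(dim(samples))) matrix(samples, nrow = 1) else as.matrix(samples)
}

#' Log-likelihood of the stimulus angle over a uniform grid
#'
#' Evaluates `log p(r_1, ..., r_M; theta)` on a uniform grid on `[0, 2pi)`
#' by exact log-space quadrature of the posterior integral: the Gaussian
#' neural-noise profile of each observation is circularly convolved with the
#' Gaussian input-noise kernel of width `sigma1`, and the per-observation
#' log-likelihoods are summed (independent observations). With
#' `shared_input_noise = TRUE` the observations share a single input-noise
#' draw and the profiles are multiplied before the convolution.
#'
#' @param samples Matrix of `M` response vectors (rows), or a single vector.
#' @param spec A [code_spec()] with `D = 1` and `sigma0 > 0` (use
#'   [restrict_code()] first for ablated codes).
#' @param grid_size Number of grid points; default `max(4096, 16 N)`.
#' @param shared_input_noise Likelihood convention for multiple observations.
#' @return A `likelihood_grid`: list with `theta_grid`, `log_values` (finite,
#'   2pi-periodic), `spec`, `M`.
#' @export
log_likelihood_curve <- function(samples, spec, grid_size = NULL,
                                 shared_input_noise = FALSE) {
  samples <- as_sample_matrix(samples)
  ws <- decoder_workspace(spec, grid_size)
  stopifnot(ncol(samples) == ncol(ws$m_grid))
  structure(
    list(theta_grid = ws$phi,
         log_values = ll_curve_impl(samples, ws, shared_input_noise),
         spec = spec, M = nrow(samples)),
    class = "likelihood_grid"
  )
}

# Argmax plus three-point quadratic refinement on the circular grid.
ml_estimate_impl <- function(samples, ws, shared_input_noise = FALSE) {
  lv <- ll_curve_fft(samples, ws, shared_input_noise)
  if (diff(range(lv)) < .Machine$double.eps * 10) return(NA_real_)
  j <- which.max(lv)
  G <- ws$G
  lm_ <- lv[if (j == 1L) G else j - 1L]
  lp <- lv[if (j == G) 1L else j + 1L]
  l0 <- lv[j]
  denom <- lm_ - 2 * l0 + lp
  delta <- if (denom < 0) 0.5 * (lm_ - lp) / denom else 0
  wrap_angle(ws$phi[j] + delta * ws$dphi)
}

#' Maximum-likelihood estimate of the stimulus angle
#'
#' Argmax of [log_likelihood_curve()] followed by a local three-point
#' quadratic refinement around the peak. Returns `NA` (estimation failure)
#' if the likelihood is flat.
#'
#' @inheritParams log_likelihood_curve
#' @return Estimated angle in `[0, 2pi)`.
#' @export
ml_estimate <- function(samples, spec, grid_size = NULL,
                        shared_input_noise = FALSE) {
  samples <- as_sample_matrix(samples)
  ws <- decoder_workspace(spec, grid_size)
  ml_estimate_impl(samples, ws, shared_input_noise)
}

#' Monte-Carlo decoding experiment
#'
#' Repeats, `n_trials` times: draw a stimulus angle, generate `M` noisy
#' population responses, decode by maximum likelihood, and record the
#' wrapped error. Reports the inverse error variance both raw (`1/Var`) and
#' per observation (`1/(M Var)`); the latter is the quantity that converges
#' to the closed-form Fisher information of the code. Trials with an
#' absolute error above `pi/2` are counted but never discarded.
#'
#' @param spec A [code_spec()] with `D = 1`.
#' @param M Observations per estimate. Default 10.
#' @param n_trials Number of decoding trials (>= 100). Default 1000.
#' @param seed Integer seed; all randomness derives from it.
#' @param subset Optional [neuron_subset()] restricting the code.
#' @param theta_policy `"fixed_random"` (one angle per experiment, drawn from
#'   the seed; the information is stimulus-independent), `"fixed"` (use
#'   `theta`), or `"uniform"` (fresh uniform angle per trial).
#' @param theta Stimulus angle for `theta_policy = "fixed"`.
#' @param shared_input_noise If `TRUE`, the `M` observations of a trial share
#'   one input-noise draw, and the decoder uses the matching likelihood.
#' @param grid_size Decoder grid size override.
#' @return A `decoding_summary`; see [tidy.decoding_summary()] and
#'   [glance.decoding_summary()].
#' @export
#' @examples
#' ds <- decoding_experiment(code_spec(10, 3), M = 5, n_trials = 100, seed = 1)
#' glance(ds)
decoding_experiment <- function(spec, M = 10, n_trials = 1000, seed = 1,
                                subset = NULL,
                                theta_policy = c("fixed_random", "fixed",
                                                 "uniform"),
                                theta = NULL, shared_input_noise = FALSE,
                                grid_size = NULL) {
  theta_policy <- arg_match(theta_policy)
  if (n_trials < 100) abort("`n_trials` must be at least 100.")
  if (!is.null(subset)) spec <- restrict_code(spec, subset)
  ws <- decoder_workspace(spec, grid_size)
  p <- 2L * length(spec$modes)

  if (theta_policy == "fixed_random") {
    set.seed(trial_seed(seed, 0L))
    theta_fixed <- stats::runif(1, 0, 2 * pi)
  } else if (theta_policy == "fixed") {
    if (is.null(theta)) abort("`theta` is required for theta_policy = \"fixed\".")
    theta_fixed <- wrap_angle(theta)
  }

  true_theta <- numeric(n_trials)
  estimates <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    th <- if (theta_policy == "uniform") {
      set.seed(trial_seed(seed, -t))
      stats::runif(1, 0, 2 * pi)
    } else theta_fixed
    samples <- if (shared_input_noise) {
      set.seed(trial_seed(seed, t))
      eta <- rnorm(1, 0, spec$sigma1)
      xi <- matrix(rnorm(M * p, 0, spec$sigma0), M, p)
      matrix(tuning_curve(spec, th + eta), M, p, byrow = TRUE) + xi
    } else {
      sample_responses(spec, th, M, trial_seed(seed, t))$responses
    }
    true_theta[t] <- th
    estimates[t] <- ml_estimate_impl(samples, ws, shared_input_noise)
  }
  errors <- wrap_error(estimates, true_theta)
  v <- var(errors)
  structure(
    list(
      trials = tibble(trial = seq_len(n_trials), true_theta = true_theta,
                      estimate = estimates, wrapped_error = errors),
      M = M, n_trials = n_trials, seed = as.integer(seed),
      inverse_variance = 1 / v,
      inverse_variance_per_obs = 1 / (M * v),
      inverse_variance_rel_se = sqrt(2 / (n_trials - 1)),
      large_error_count = sum(abs(errors) > pi / 2),
      shared_input_noise = shared_input_noise,
      spec = spec
    ),
    class = "decoding_summary"
  )
}

#' @describeIn decoding_experiment Per-trial tibble: `trial`, `true_theta`,
#'   `estimate`, `wrapped_error`.
#' @param x A `decoding_summary`.
#' @param ... Unused.
#' @export
tidy.decoding_summary <- function(x, ...) x$trials

#' @describeIn decoding_experiment One-row summary: inverse error variances
#'   (raw and per observation), their relative Monte-Carlo standard error,
#'   and the count of errors exceeding `pi/2`.
#' @export
glance.decoding_summary <- function(x, ...) {
  tibble(
    n_trials = x$n_trials, M = x$M,
    inverse_variance = x$inverse_variance,
    inverse_variance_per_obs = x$inverse_variance_per_obs,
    inverse_variance_rel_se = x$inverse_variance_rel_se,
    large_error_count = x$large_error_count,
    n_modes = length(x$spec$modes)
  )
}

#' @export
print.decoding_summary <- function(x, ...) {
  cat(sprintf("<decoding_summary> %d trials, M = %d, %d modes\n",
              x$n_trials, x$M, length(x$spec$modes)))
  cat(sprintf("  1/Var = %.4g, 1/(M Var) = %.4g (rel. MC se %.1f%%), |err| > pi/2: %d\n",
              x$inverse_variance, x$inverse_variance_per_obs,
              100 * x$inverse_variance_rel_se, x$large_error_count))
  invisible(x)
}

#' @export
autoplot.decoding_summary <- function(object, ...) {
  ggplot2::ggplot(object$trials, ggplot2::aes(.data$wrapped_error)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::labs(x = "wrapped error (rad)", y = "trials") +
    ggplot2::theme_minimal()
}

#' Serialize a decoding summary to CSV plus a JSON sidecar
#'
#' @param summary A `decoding_summary`.
#' @param path CSV path for the per-trial table; the JSON summary goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_decoding_summary <- function(summary, path) {
  stopifnot(inherits(summary, "decoding_summary"))
  readr::write_csv(summary$trials, path)
  meta <- list(
    M = summary$M, n_trials = summary$n_trials, seed = summary$seed,
    inverse_variance = summary$inverse_variance,
    inverse_variance_per_obs = summary$inverse_variance_per_obs,
    large_error_count = summary$large_error_count,
    shared_input_noise = summary$shared_input_noise,
    modes = summary$spec$modes,
    spec = summary$spec[c("N", "alpha", "sigma0", "sigma1")]
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
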