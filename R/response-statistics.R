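#' Unbiased sample covariance of a response ensemble
#'
#' @param ensemble A `response_ensemble` with at least 2 trials.
#' @return A `covariance_estimate`: list with `matrix` (2N x 2N), `n_samples`,
#'   `theta`, `spec`.
#' @export
empirical_covariance <- function(ensemble) {
  stopifnot(inherits(ensemble, "response_ensemble"))
  n <- nrow(ensemble$responses)
  if (n < 2) abort("Covariance estimation needs at least 2 trials.")
  structure(
    list(matrix = cov(ensemble$responses), n_samples = n,
         theta = ensemble$theta, spec = ensemble$spec),
    class = "covariance_estimate"
  )
}

#' Analytic small-noise covariance of the code
#'
#' `Sigma = sigma0^2 I + sigma1^2 mu mu^T` at a given stimulus — the
#' susceptibility-variance relationship. The rank-one term is the
#' differential correlation induced by shared input noise.
#'
#' @param spec A [code_spec()] with `D = 1`.
#' @param theta Stimulus angle in radians.
#' @return A 2N x 2N matrix.
#' @export
analytic_covariance <- function(spec, theta) {
  mu <- susceptibility(spec, theta)
  diag(spec$sigma0^2, length(mu)) + spec$sigma1^2 * tcrossprod(mu)
}

#' Scatter of covariance elements against susceptibility outer products
#'
#' Pairs each element of an empirical covariance `Sigma_hat_ij` with the
#' corresponding element of `(mu mu^T)_ij` and fits ordinary least squares
#' separately for diagonal and off-diagonal elements. Under the
#' susceptibility-variance relationship the off-diagonal slope recovers
#' `sigma1^2` (zero intercept) and the diagonal fit recovers slope `sigma1^2`
#' with intercept `sigma0^2`.
#'
#' @param spec A [code_spec()] with `D = 1`.
#' @param theta Stimulus angle; if `NULL`, drawn uniformly using `seed` (the
#'   identity holds for every angle).
#' @param n_samples Trials used for the empirical covariance (>= 100), unless
#'   `covariance` is supplied.
#' @param seed Integer seed.
#' @param covariance Optional covariance matrix to use instead of sampling
#'   (e.g. [analytic_covariance()] for an exactness check).
#' @return A `scatter_fit` object; see [tidy.scatter_fit()] and
#'   [glance.scatter_fit()].
#' @export
#' @examples
#' fit <- susceptibility_variance_scatter(code_spec(20, 3), n_samples = 500,
#'                                        seed = 1)
#' glance(fit)
susceptibility_variance_scatter <- function(spec, theta = NULL,
                                            n_samples = 1e4, seed = 1,
                                            covariance = NULL) {
  check_d1(spec)
  if (is.null(theta)) {
    set.seed(trial_seed(seed, 0L))
    theta <- stats::runif(1, 0, 2 * pi)
  }
  if (is.null(covariance)) {
    if (n_samples < 100) abort("`n_samples` must be at least 100.")
    ens <- sample_responses(spec, theta, n_samples, seed)
    covariance <- empirical_covariance(ens)$matrix
  }
  mu <- susceptibility(spec, theta)
  outer_mu <- tcrossprod(mu)
  p <- length(mu)
  is_diag <- as.vector(diag(TRUE, p))
  pairs <- tibble(
    x = as.vector(outer_mu), y = as.vector(covariance),
    group = ifelse(is_diag, "diagonal", "off_diagonal")
  )
  fit_group <- function(g) {
    d <- pairs[pairs$group == g, ]
    coef(lm(y ~ x, data = d))
  }
  cd <- fit_group("diagonal")
  co <- fit_group("off_diagonal")
  structure(
    list(pairs = pairs,
         slope_diag = unname(cd[2]), intercept_diag = unname(cd[1]),
         slope_off = unname(co[2]), intercept_off = unname(co[1]),
         spec = spec, theta = theta, n_samples = n_samples, seed = seed),
    class = "scatter_fit"
  )
}

#' @describeIn susceptibility_variance_scatter One row per covariance element:
#'   `x = (mu mu^T)_ij`, `y = Sigma_hat_ij`, `group`.
#' @param x A `scatter_fit`.
#' @param ... Unused.
#' @export
tidy.scatter_fit <- function(x, ...) x$pairs

#' @describeIn susceptibility_variance_scatter One-row summary of the fits
#'   with the noise variances they are expected to recover.
#' @export
glance.scatter_fit <- function(x, ...) {
  tibble(
    slope_diag = x$slope_diag, intercept_diag = x$intercept_diag,
    slope_off = x$slope_off, intercept_off = x$intercept_off,
    sigma0_sq = x$spec$sigma0^2, sigma1_sq = x$spec$sigma1^2,
    n_samples = x$n_samples, theta = x$theta
  )
}

#' @export
autoplot.scatter_fit <- function(object, ...) {
  s0 <- object$spec$sigma0^2
  s1 <- object$spec$sigma1^2
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = s1, intercept = s0) +
    ggplot2::geom_abline(slope = s1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression((mu * mu^T)[ij]),
                  y = expression(hat(Sigma)[ij]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Check that the susceptibility is an eigenvector of the covariance
#'
#' Reports the relative residual `||Sigma mu - lambda mu|| / (lambda ||mu||)`
#' and the Rayleigh quotient `mu^T Sigma mu / mu^T mu`, which should equal
#' `lambda = sigma0^2 + sigma1^2 H_N(alpha - 2)`.
#'
#' @param cov A `covariance_estimate` or a bare covariance matrix.
#' @param mu Susceptibility vector (nonzero), matching dimension.
#' @param lam Reference eigenvalue `lambda`.
#' @return A one-row tibble with `residual`, `rayleigh`, `lambda`.
#' @export
covariance_eigencheck <- function(cov, mu, lam) {
  m <- if (inherits(cov, "covariance_estimate")) cov$matrix else cov
  stopifnot(nrow(m) == length(mu))
  mu_norm <- sqrt(sum(mu^2))
  if (mu_norm == 0) abort("`mu` must be nonzero.")
  sm <- as.vector(m %*% mu)
  tibble(
    residual = sqrt(sum((sm - lam * mu)^2)) / (lam * mu_norm),
    rayleigh = sum(mu * sm) / sum(mu^2),
    lambda = lam
  )
}

#' Eigenspectrum of the stimulus-marginalized response covariance
#'
#' Pools responses across stimulus angles covering `[0, 2pi)`, computes the
#' covariance of the pooled ensemble about its grand mean, and returns the
#' eigenvalues in descending order. For this code the expectation is a
#' paired spectrum `n^(-alpha) / 2 + sigma0^2` (each mode contributes a
#' cosine and a sine direction of equal marginal variance) — the power-law
#' premise. `method = "analytic"` returns that exact spectrum; `"sampled"`
#' estimates it by Monte Carlo.
#'
#' @param spec A [code_spec()] with `D = 1`.
#' @param n_theta Number of stimulus angles pooled (>= 8). For the grid
#'   policy, exact discrete orthogonality needs `n_theta > 2 N`.
#' @param trials_per_theta Noise draws per angle.
#' @param seed Integer seed.
#' @param method `"sampled"` (default) or `"analytic"`.
#' @param theta_sampling `"grid"` (deterministic uniform grid, default) or
#'   `"random"` (uniform draws).
#' @return A tibble of class `eigenspectrum` with columns `rank`,
#'   `eigenvalue`.
#' @export
#' @examples
#' marginal_eigenspectrum(code_spec(10, 2), method = "analytic")
marginal_eigenspectrum <- function(spec, n_theta = 64, trials_per_theta = 50,
                                   seed = 1,
                                   method = c("sampled", "analytic"),
                                   theta_sampling = c("grid", "random")) {
  check_d1(spec)
  method <- arg_match(method)
  theta_sampling <- arg_match(theta_sampling)
  if (method == "analytic") {
    n <- as.numeric(spec$modes)
    ev <- sort(rep(n^(-spec$alpha) / 2 + spec$sigma0^2, each = 2L),
               decreasing = TRUE)
  } else {
    if (n_theta < 8) abort("`n_theta` must be at least 8.")
    thetas <- if (theta_sampling == "grid") {
      2 * pi * (seq_len(n_theta) - 1) / n_theta
    } else {
      set.seed(trial_seed(seed, 0L))
      stats::runif(n_theta, 0, 2 * pi)
    }
    pooled <- purrr::map(seq_along(thetas), function(k) {
      sample_responses(spec, thetas[k], trials_per_theta,
                       trial_seed(seed, k))$responses
    })
    pooled <- do.call(rbind, pooled)
    pooled <- sweep(pooled, 2, colMeans(pooled))
    cv <- crossprod(pooled) / (nrow(pooled) - 1)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  }
  new_tibble(tibble(rank = seq_along(ev), eigenvalue = ev),
             spec = spec, method = method, class = "eigenspectrum")
}

#' Power-law slope of an eigenspectrum
#'
#' Averages each successive (cosine, sine) eigenvalue pair into a per-mode
#' variance, subtracts the neural-noise floor `sigma0^2`, and regresses
#' `log(eigenvalue)` on `log(mode)` by ordinary least squares. For a
#' power-law code the slope estimates `-alpha`.
#'
#' @param spectrum An `eigenspectrum` tibble (descending eigenvalues).
#' @param sigma0 Noise floor subtracted before the log-log fit. Default 0.
#' @param modes Which mode ranks enter the fit; default all modes whose
#'   noise-subtracted eigenvalue is positive.
#' @return A one-row tibble with `slope`, `intercept`, `n_modes`.
#' @export
spectrum_slope <- function(spectrum, sigma0 = 0, modes = NULL) {
  ev <- spectrum$eigenvalue
  n_modes_total <- length(ev) %/% 2L
  per_mode <- (ev[2 * seq_len(n_modes_total) - 1] +
               ev[2 * seq_len(n_modes_total)]) / 2 - sigma0^2
  if (is.null(modes)) modes <- which(per_mode > 0)
  per_mode <- per_mode[modes]
  if (any(per_mode <= 0)) {
    abort("Noise-subtracted eigenvalues must be positive on the fitted modes.")
  }
  fit <- lm(log(per_mode) ~ log(modes))
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_modes = length(modes))
}

#' @export
autoplot.eigenspectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rank, .data$eigenvalue)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "eigenvalue") +
    ggplot2::theme_minimal()
}
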