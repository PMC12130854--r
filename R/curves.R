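#' Fisher-information curve over a grid of exponents
#'
#' Evaluates the closed-form Fisher information on an exponent grid, for one
#' or several input dimensions, and returns a tidy tibble ready for plotting
#' or serialization.
#'
#' @param alphas Numeric grid of exponents. Default `seq(1.05, 6, by = 0.01)`.
#' @param D Input dimensions (vector; entries may be `Inf`).
#' @param sigma0,sigma_i Noise standard deviations.
#' @param N `Inf` for the limit formulas (default) or a finite mode count
#'   (finite `N` is defined for `D = 1` only).
#' @return A tibble of class `fisher_curve` with columns `alpha`, `D`,
#'   `fisher`, and attribute metadata.
#' @export
#' @examples
#' fc <- fisher_curve(D = c(1, 2, 5, Inf))
#' head(fc)
fisher_curve <- function(alphas = seq(1.05, 6, by = 0.01), D = 1,
                         sigma0 = 0.01, sigma_i = 0.01, N = Inf) {
  rows <- purrr::map(D, function(d) {
    vals <- if (is.infinite(N)) {
      fisher_limit(alphas, d, sigma0, sigma_i)
    } else {
      if (!identical(as.numeric(d), 1)) {
        abort("Finite-N Fisher curves are defined for D = 1 only.")
      }
      fisher_finite(alphas, N, sigma0, sigma_i)
    }
    tibble(alpha = alphas, D = d, fisher = vals)
  })
  out <- dplyr::bind_rows(rows)
  new_tibble(out, sigma0 = sigma0, sigma_i = sigma_i, N = N,
             class = "fisher_curve")
}

#' Energy-aware performance curve over a grid of exponents
#'
#' Evaluates `J_D(alpha) = I_D(alpha) - gamma * zeta(alpha)` (or the
#' finite-`N` analogue) on a grid and flags the argmax per dimension.
#'
#' @inheritParams fisher_curve
#' @param gamma Positive regularization weight. Default `1e-3`, small enough
#'   that the energy term never overwhelms the information term.
#' @return A tibble of class `energy_curve` with columns `alpha`, `D`,
#'   `performance`.
#' @export
#' @examples
#' ec <- energy_curve(D = c(1, 2))
#' glance(ec)
energy_curve <- function(alphas = seq(1.05, 6, by = 0.01), D = 1,
                         sigma0 = 0.01, sigma_i = 0.01, gamma = 1e-3,
                         N = Inf) {
  rows <- purrr::map(D, function(d) {
    tibble(alpha = alphas, D = d,
           performance = energy_aware_performance(alphas, d, sigma0, sigma_i,
                                                  gamma, N))
  })
  out <- dplyr::bind_rows(rows)
  new_tibble(out, sigma0 = sigma0, sigma_i = sigma_i, gamma = gamma, N = N,
             class = "energy_curve")
}

#' @describeIn energy_curve One row per input dimension with the grid argmax
#'   of the performance and the theoretical critical exponent.
#' @param x An `energy_curve`.
#' @param ... Unused.
#' @export
glance.energy_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$D) |>
    dplyr::summarise(
      alpha_opt = .data$alpha[which.max(.data$performance)],
      performance_max = max(.data$performance),
      .groups = "drop"
    ) |>
    dplyr::mutate(alpha_critical = critical_exponent(.data$D),
                  gamma = attr(x, "gamma"))
}

#' Locate the kink of a Fisher-information curve
#'
#' The limiting Fisher information is continuous in `alpha` but its one-sided
#' slopes disagree at the critical exponent. On a uniform grid the kink is
#' detected as the interior point with the largest jump between adjacent
#' secant slopes.
#'
#' @param alphas Uniform, increasing exponent grid.
#' @param values Curve values on the grid.
#' @return A list with `alpha` (kink location), `slope_left`, `slope_right`,
#'   and `jump` (their absolute difference).
#' @export
#' @examples
#' a <- seq(2, 4, by = 0.005)
#' detect_kink(a, fisher_limit(a, 1, 0.01, 0.01))$alpha # 3
detect_kink <- function(alphas, values) {
  stopifnot(length(alphas) == length(values), length(alphas) >= 3)
  slopes <- diff(values) / diff(alphas)
  jumps <- abs(diff(slopes))
  k <- which.max(jumps) + 1L
  list(alpha = alphas[k], slope_left = slopes[k - 1L],
       slope_right = slopes[k], jump = jumps[k - 1L])
}

#' @export
autoplot.fisher_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$alpha, .data$fisher,
                               colour = factor(.data$D))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = unique(critical_exponent(object$D)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(alpha), y = "Fisher information",
                  colour = "D") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.energy_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$alpha, .data$performance,
                               colour = factor(.data$D))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = unique(critical_exponent(object$D)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression(alpha), y = expression(J[D](alpha)),
                  colour = "D") +
    ggplot2::theme_minimal()
}
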