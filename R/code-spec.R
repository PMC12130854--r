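#' Specify a power-law population code
#'
#' A code spec describes a population of `2N` neurons with Fourier receptive
#' fields: mode `n` contributes a cosine neuron and a sine neuron whose common
#' amplitude decays as `n^(-alpha/2)`. Responses to a stimulus angle `theta`
#' are perturbed by a single input-noise draw `eta ~ N(0, sigma1^2)` shared by
#' the whole population, and by independent neural noise `xi_i ~ N(0, sigma0^2)`
#' per neuron. Mode indexing is 1-based: mode `n` occupies neurons `2n - 1`
#' (cosine) and `2n` (sine).
#'
#' The rotation and overall scale of the general model are fixed to the
#' identity and 1; they carry no information and are not parameters. The input
#' dimension `D` enters the closed-form theory only; simulation requires
#' `D = 1`.
#'
#' @param N Number of Fourier modes (population size is `2N`). Positive integer.
#' @param alpha Power-law exponent of the variance spectrum (amplitudes decay
#'   as `n^(-alpha/2)`).
#' @param sigma0 Neural-noise standard deviation, in response units.
#'   Default 0.01.
#' @param sigma1 Input-noise standard deviation, in radians. Default 0.01.
#' @param D Input dimension for the closed-form theory. Default 1.
#' @param modes Optional strictly increasing subset of `1:N` of retained modes;
#'   defaults to all modes. Usually set via [restrict_code()].
#'
#' @return An object of class `code_spec`.
#' @seealso [tuning_curve()], [sample_responses()], [restrict_code()]
#' @export
#' @examples
#' spec <- code_spec(N = 100, alpha = 3)
#' spec
code_spec <- function(N, alpha, sigma0 = 0.01, sigma1 = 0.01, D = 1L,
                      modes = NULL) {
  stopifnot(length(N) == 1, length(alpha) == 1, length(sigma0) == 1,
            length(sigma1) == 1, length(D) == 1)
  if (!is.numeric(N) || N < 1 || N != floor(N)) {
    abort("`N` must be a positive integer.")
  }
  if (sigma0 < 0 || sigma1 < 0) {
    abort("Noise strengths `sigma0` and `sigma1` must be non-negative.")
  }
  if (!is.infinite(D) && (D < 1 || D != floor(D))) {
    abort("`D` must be a positive integer (or Inf).")
  }
  N <- as.integer(N)
  if (is.null(modes)) modes <- seq_len(N)
  modes <- validate_modes(modes, N)
  structure(
    list(N = N, alpha = as.numeric(alpha), sigma0 = as.numeric(sigma0),
         sigma1 = as.numeric(sigma1), D = D, modes = modes),
    class = "code_spec"
  )
}

validate_modes <- function(modes, N) {
  if (length(modes) == 0) abort("Mode subset must be nonempty.")
  if (!is.numeric(modes) || any(modes != floor(modes)) ||
      any(modes < 1) || any(modes > N)) {
    abort("`modes` must be integers in 1..N.")
  }
  modes <- as.integer(modes)
  if (is.unsorted(modes, strictly = TRUE)) {
    abort("`modes` must be strictly increasing.")
  }
  modes
}

#' @export
print.code_spec <- function(x, ...) {
  restricted <- length(x$modes) < x$N
  cat(sprintf(
    "<code_spec> %d Fourier modes (%d neurons)%s\n",
    x$N, 2L * length(x$modes),
    if (restricted) sprintf(", %d modes retained", length(x$modes)) else ""
  ))
  cat(sprintf("  alpha = %g, sigma0 = %g, sigma1 = %g, D = %s\n",
              x$alpha, x$sigma0, x$sigma1, format(x$D)))
  invisible(x)
}

#' Define an ordered subset of Fourier modes for ablation experiments
#'
#' Each retained mode keeps both its cosine and its sine neuron. The two
#' removal policies mirror ablating neurons from the high-frequency end
#' (`descending_removal`: after `k` removals the modes `1..N-k` remain) or
#' from the low-frequency end (`ascending_removal`: modes `k+1..N` remain).
#'
#' @param modes Strictly increasing integer vector of retained mode indices.
#' @param order_tag One of `"descending_removal"`, `"ascending_removal"`,
#'   `"custom"`. Metadata describing how the subset arose.
#' @return An object of class `neuron_subset`.
#' @export
#' @examples
#' neuron_subset(1:25, "descending_removal")
neuron_subset <- function(modes,
                          order_tag = c("custom", "descending_removal",
                                        "ascending_removal")) {
  order_tag <- arg_match(order_tag)
  if (length(modes) == 0) abort("Mode subset must be nonempty.")
  structure(list(modes = as.integer(modes), order_tag = order_tag),
            class = "neuron_subset")
}

#' Mode subsets for sequential removal experiments
#'
#' @param N Total number of modes.
#' @param k Number of modes removed.
#' @param from Which end of the spectrum is removed first: `"high"` removes
#'   the highest-frequency modes (retaining `1..N-k`), `"low"` removes the
#'   lowest (retaining `k+1..N`).
#' @return A [neuron_subset()].
#' @export
removal_subset <- function(N, k, from = c("high", "low")) {
  from <- arg_match(from)
  if (k < 0 || k >= N) abort("`k` must satisfy 0 <= k < N.")
  if (from == "high") {
    neuron_subset(seq_len(N - k), "descending_removal")
  } else {
    neuron_subset(seq.int(k + 1L, N), "ascending_removal")
  }
}

#' Restrict a code to a subset of its Fourier modes
#'
#' Returns a view of the code in which only the retained modes' neuron pairs
#' exist. [tuning_curve()], [susceptibility()], [sample_responses()] and
#' [population_energy()] on the restricted spec operate on `2 * length(modes)`
#' neurons, ordered by increasing mode index.
#'
#' @param spec A [code_spec()].
#' @param subset A [neuron_subset()] (or bare integer vector of modes).
#' @return A `code_spec` with the `modes` field restricted.
#' @export
#' @examples
#' spec <- code_spec(N = 10, alpha = 2)
#' tuning_curve(restrict_code(spec, removal_subset(10, 9, "high")), 0.3)
restrict_code <- function(spec, subset) {
  stopifnot(inherits(spec, "code_spec"))
  modes <- if (inherits(subset, "neuron_subset")) subset$modes else subset
  spec$modes <- validate_modes(modes, spec$N)
  spec
}

# Canonicalize angles to [0, 2*pi)
wrap_angle <- function(theta) {
  theta %% (2 * pi)
}
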