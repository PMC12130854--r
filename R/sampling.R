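#' Draw noisy population responses at a fixed stimulus
#'
#' Each trial draws one shared input-noise perturbation
#' `eta ~ N(0, sigma1^2)` and independent neural noise
#' `xi_i ~ N(0, sigma0^2)` per neuron; the response is
#' `tuning_curve(theta + eta) + xi`. Trial `t` is generated from a stream
#' seeded by a deterministic mix of `(seed, t)`, so the same `(spec, theta,
#' trials, seed)` always reproduces the identical ensemble, and disjoint trial
#' ranges could be generated independently without changing the result.
#'
#' @param spec A [code_spec()] with `D = 1`.
#' @param theta Stimulus angle in radians.
#' @param trials Number of trials (rows), at least 1.
#' @param seed Integer seed.
#' @return A `response_ensemble`: list with `responses` (trials x 2N matrix,
#'   cosine neuron of mode n in column `2n - 1`, sine neuron in column `2n`),
#'   `theta`, `seed`, `spec`.
#' @export
#' @examples
#' ens <- sample_responses(code_spec(5, 2), theta = 1, trials = 4, seed = 1)
#' dim(ens$responses)
sample_responses <- function(spec, theta, trials, seed) {
  check_d1(spec)
  if (trials < 1) abort("`trials` must be at least 1.")
  trials <- as.integer(trials)
  theta <- wrap_angle(theta)
  n <- spec$modes
  p <- 2L * length(n)
  amp <- n^(-spec$alpha / 2)

  eta <- numeric(trials)
  xi <- matrix(0, trials, p)
  for (t in seq_len(trials)) {
    set.seed(trial_seed(seed, t))
    eta[t] <- rnorm(1L, 0, spec$sigma1)
    xi[t, ] <- rnorm(p, 0, spec$sigma0)
  }

  phase <- outer(theta + eta, n)        # trials x modes
  mean_part <- matrix(0, trials, p)
  mean_part[, c(TRUE, FALSE)] <- cos(phase) * rep(amp, each = trials)
  mean_part[, c(FALSE, TRUE)] <- sin(phase) * rep(amp, each = trials)

  structure(
    list(responses = mean_part + xi, theta = theta, seed = as.integer(seed),
         spec = spec),
    class = "response_ensemble"
  )
}

# Deterministic per-trial seed: Lehmer-style mix kept below 2^31 and within
# exact double-precision integer arithmetic.
trial_seed <- function(seed, t) {
  m <- 2147483647
  a <- (as.numeric(seed) %% m + m) %% m
  as.integer((a * 48271 + as.numeric(t) * 16807) %% m)
}

#' @export
print.response_ensemble <- function(x, ...) {
  cat(sprintf("<response_ensemble> %d trials x %d neurons at theta = %.4f (seed %d)\n",
              nrow(x$responses), ncol(x$responses), x$theta, x$seed))
  invisible(x)
}

#' @describeIn sample_responses Long-format view: one row per (trial,
#'   neuron_index) with the response value, the mode index and the component
#'   (`"cos"` or `"sin"`).
#' @param x A `response_ensemble`.
#' @param ... Unused.
#' @export
as_tibble.response_ensemble <- function(x, ...) {
  r <- x$responses
  modes <- x$spec$modes
  tibble(
    trial = rep(seq_len(nrow(r)), times = ncol(r)),
    neuron_index = rep(seq_len(ncol(r)), each = nrow(r)),
    mode = rep(rep(modes, each = 2L), each = nrow(r)),
    component = rep(rep(c("cos", "sin"), length(modes)), each = nrow(r)),
    value = as.vector(r)
  )
}

#' Write / read a response ensemble as CSV plus a JSON sidecar
#'
#' The CSV holds `trial, neuron_index, value`; the sidecar `<path>.json`
#' records the code spec, stimulus and seed so the ensemble is fully
#' reproducible from metadata alone.
#'
#' @param ensemble A `response_ensemble`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "response_ensemble"))
  tbl <- as_tibble(ensemble)[, c("trial", "neuron_index", "value")]
  readr::write_csv(tbl, path)
  meta <- list(
    spec = ensemble$spec[c("N", "alpha", "sigma0", "sigma1", "D", "modes")],
    theta = ensemble$theta,
    seed = ensemble$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @param path CSV file path written by [write_ensemble()].
#' @export
read_ensemble <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- code_spec(meta$spec$N, meta$spec$alpha, meta$spec$sigma0,
                    meta$spec$sigma1,
                    D = if (is.character(meta$spec$D)) Inf else meta$spec$D,
                    modes = meta$spec$modes)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  p <- 2L * length(spec$modes)
  r <- matrix(tbl$value[order(tbl$neuron_index, tbl$trial)],
              nrow = max(tbl$trial), ncol = p)
  structure(list(responses = r, theta = meta$theta,
                 seed = as.integer(meta$seed), spec = spec),
            class = "response_ensemble")
}
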