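test_that("wrap_error returns the minimal signed angular difference", {
  expect_equal(wrap_error(0.1, 0), 0.1)
  expect_equal(wrap_error(2 * pi - 0.1, 0), -0.1)
  expect_equal(wrap_error(pi + 0.2, 0), -pi + 0.2)
  expect_equal(wrap_error(pi, 0), pi)
  expect_true(all(abs(wrap_error(runif(50, -10, 10), runif(50, -10, 10)))
                  <= pi))
})

test_that("likelihood reduces to the squared-distance profile without input noise", {
  spec <- code_spec(5, 2, sigma0 = 0.3, sigma1 = 0)
  set.seed(11)
  r <- tuning_curve(spec, 2.0) + rnorm(10, 0, 0.3)
  lg <- log_likelihood_curve(r, spec, grid_size = 512)
  expect_true(all(is.finite(lg$log_values)))
  closed <- vapply(lg$theta_grid, function(th)
    -sum((r - tuning_curve(spec, th))^2) / (2 * 0.3^2), numeric(1))
  # equal up to the theta-independent normalization
  diffs <- lg$log_values - closed
  expect_lt(diff(range(diffs)), 1e-9)
})

test_that("likelihood curve matches brute-force quadrature of the posterior integral", {
  spec <- code_spec(10, 2.2, sigma0 = 0.25, sigma1 = 0.15)
  set.seed(21)
  for (i in 1:3) {
    th <- runif(1, 0, 2 * pi)
    samples <- sample_responses(spec, th, 2, seed = 100 + i)$responses
    lg <- log_likelihood_curve(samples, spec, grid_size = 4096)
    probe <- sample.int(4096, 5)
    got <- lg$log_values[probe]
    want <- oracle_log_posterior(samples, spec, lg$theta_grid[probe])
    # relative error of the posterior density values
    expect_lt(max(abs(exp(got - want) - 1)), 1e-6)
  }
})

test_that("likelihood curve is periodic and finite with small noise", {
  spec <- code_spec(8, 3)
  samples <- sample_responses(spec, 1.2, 3, seed = 5)$responses
  lg <- log_likelihood_curve(samples, spec)
  expect_true(all(is.finite(lg$log_values)))
  # the grid covers [0, 2pi); shifting all samples by a full period is a no-op
  expect_equal(log_likelihood_curve(samples, spec)$log_values, lg$log_values)
  expect_error(log_likelihood_curve(samples, code_spec(8, 3, sigma0 = 0)),
               "sigma0")
})

test_that("ML estimate is exact on noiseless data and unbiased under noise", {
  spec <- code_spec(10, 2, sigma0 = 1e-3, sigma1 = 0)
  r <- tuning_curve(spec, 1.0)
  expect_equal(ml_estimate(r, spec), 1.0, tolerance = 1e-6)

  # flat likelihood flags failure
  flat <- ml_estimate(matrix(0, 1, 2), code_spec(1, 0, sigma0 = 1, sigma1 = 0),
                      grid_size = 64)
  expect_true(is.na(flat))

  ds <- decoding_experiment(code_spec(20, 3), M = 5, n_trials = 300, seed = 8)
  errs <- tidy(ds)$wrapped_error
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("single-mode decoding matches the phase-regression oracle", {
  spec <- restrict_code(code_spec(10, 2, sigma0 = 0.05, sigma1 = 0),
                        neuron_subset(1L))
  samples <- sample_responses(spec, 2.7, 200, seed = 12)$responses
  expect_equal(ml_estimate(samples, spec), oracle_phase_estimate(samples),
               tolerance = 1e-5)
})

test_that("estimation near the origin wraps instead of exploding", {
  spec <- code_spec(10, 3)
  ds <- decoding_experiment(spec, M = 5, n_trials = 100, seed = 13,
                            theta_policy = "fixed", theta = 0.005)
  expect_lt(max(abs(tidy(ds)$wrapped_error)), 0.2)
})

test_that("inverse error variance tracks the Fisher information across N", {
  for (N in c(10, 25)) {
    ds <- decoding_experiment(code_spec(N, 4), M = 10, n_trials = 500,
                              seed = 20 + N)
    theory <- fisher_finite(4, N, 0.01, 0.01)
    expect_equal(ds$inverse_variance_per_obs, theory, tolerance = 0.15)
    # Cramer-Rao: never significantly above the bound
    expect_lt(ds$inverse_variance_per_obs,
              theory * (1 + 3 * sqrt(2 / 499)))
  }
})

test_that("restricted decoding matches the subset Fisher prediction and ordering", {
  spec <- code_spec(20, 3)
  lo_keep <- removal_subset(20, 10, "high")   # keep modes 1..10
  hi_keep <- removal_subset(20, 10, "low")    # keep modes 11..20
  ds_lo <- decoding_experiment(spec, M = 10, n_trials = 1000, seed = 31,
                               subset = lo_keep)
  ds_hi <- decoding_experiment(spec, M = 10, n_trials = 1000, seed = 32,
                               subset = hi_keep)
  expect_gt(ds_lo$inverse_variance, ds_hi$inverse_variance)
  expect_equal(ds_lo$inverse_variance_per_obs,
               subset_fisher(lo_keep, 3, 0.01, 0.01), tolerance = 0.15)
  expect_equal(ds_hi$inverse_variance_per_obs,
               subset_fisher(hi_keep, 3, 0.01, 0.01), tolerance = 0.15)
})

test_that("shared input noise changes the effective information per trial", {
  spec <- code_spec(10, 4)
  ds <- decoding_experiment(spec, M = 5, n_trials = 300, seed = 41,
                            shared_input_noise = TRUE)
  g <- glance(ds)
  expect_true(all(c("inverse_variance", "inverse_variance_per_obs")
                  %in% names(g)))
  # with eta shared, averaging M responses cannot defeat the input noise:
  # the raw inverse variance stays near 1/sigma1^2 rather than M/sigma1^2
  expect_lt(ds$inverse_variance, 2.5 / 0.01^2)
  expect_equal(ds$n_trials, 300)
})

test_that("decoding summaries serialize to CSV plus JSON", {
  ds <- decoding_experiment(code_spec(5, 2), M = 3, n_trials = 100, seed = 2)
  path <- file.path(withr::local_tempdir(), "dec.csv")
  write_decoding_summary(ds, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_trials, 100)
  expect_equal(meta$inverse_variance, ds$inverse_variance)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 100)
  expect_equal(back$wrapped_error, tidy(ds)$wrapped_error)
})
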