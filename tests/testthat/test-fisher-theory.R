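test_that("harmonic numbers and zeta agree with independent oracles", {
  expect_equal(harmonic_number(0, 5), 5)
  expect_equal(harmonic_number(1, 3), 11 / 6)
  expect_equal(harmonic_number(2, 1e6), pi^2 / 6, tolerance = 1e-5)

  for (x in c(1.01, 1.5, 2, 3.5)) {
    expect_equal(riemann_zeta(x), zeta_em(x), tolerance = 1e-10)
  }
  expect_equal(riemann_zeta(2), pi^2 / 6, tolerance = 1e-12)
  expect_equal(riemann_zeta(50), 1, tolerance = 1e-12)
  expect_identical(riemann_zeta(1), Inf)
  expect_identical(riemann_zeta(0.2), Inf)
})

test_that("critical exponent is 1 + 2/D with the right limits", {
  expect_identical(critical_exponent(1), 3)
  expect_identical(critical_exponent(2), 2)
  expect_identical(critical_exponent(Inf), 1)
  expect_error(critical_exponent(0), "positive")
})

test_that("finite-N Fisher information matches the harmonic-sum ratio", {
  # sigma1 = 0 reduces to H_N / sigma0^2
  expect_equal(fisher_finite(3, 50, 0.1, 0), harmonic_number(1, 50) / 0.01)

  # direct-summation oracle
  h <- sum((1:100)^-2)
  expect_equal(fisher_finite(4, 100, 0.01, 0.01),
               h / (1e-4 + 1e-4 * h), tolerance = 1e-12)
  expect_equal(h, 1.634984, tolerance = 1e-6)

  # differential correlations cap the information at 1/sigma1^2
  expect_equal(fisher_finite(2, 1e5, 0.01, 0.01), 1e4, tolerance = 1e-3)

  expect_error(fisher_finite(3, 10, 0, 0), "Degenerate")
})

test_that("limiting Fisher information: plateau, kink at alpha_c, large-N convergence", {
  # D = 1 denominator factor is exactly 1, so alpha = 4 gives the zeta ratio
  z2 <- riemann_zeta(2)
  expect_equal(fisher_limit(4, 1, 0.01, 0.01),
               z2 / (1e-4 + 1e-4 * z2), tolerance = 1e-12)

  # plateau at 1/sigma_i^2 below alpha_c, independent of sigma0
  for (s0 in c(0.001, 0.01, 0.1)) {
    expect_equal(fisher_limit(c(1.5, 2, 2.99, 3), 1, s0, 0.01),
                 rep(1 / 0.01^2, 4))
  }
  # above alpha_c the neural noise matters
  expect_false(fisher_limit(4, 1, 0.1, 0.01) == fisher_limit(4, 1, 0.01, 0.01))

  # strictly decreasing above alpha_c for several dimensions
  for (D in c(1, 2, 5, Inf)) {
    a <- seq(critical_exponent(D) + 0.05, 6, by = 0.05)
    expect_true(all(diff(fisher_limit(a, D, 0.01, 0.01)) < 0))
  }

  # D = Inf uses the dedicated denominator e*pi*sigma0^2/2
  expect_equal(fisher_limit(2, Inf, 0.01, 0.01),
               z2 / (exp(1) * pi * 1e-4 / 2 + 1e-4 * z2), tolerance = 1e-12)

  # finite-N information is non-decreasing in N and converges to the limit
  vals <- vapply(c(10, 100, 1000, 10000), function(n)
    fisher_finite(4, n, 0.01, 0.01), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[4], fisher_limit(4, 1, 0.01, 0.01), tolerance = 1e-3)

  expect_error(fisher_limit(2, 1, 0.01, 0), "sigma_i")
})

test_that("covariance eigenvalue lambda matches the susceptibility norm", {
  expect_equal(eigenvalue_lambda(3, 100, 0.2, 0), 0.04)
  expect_equal(eigenvalue_lambda(4, 1e6, 0.01, 0.01),
               1e-4 * (1 + pi^2 / 6), tolerance = 1e-5)
  mu <- susceptibility(code_spec(30, 3.5), 0.9)
  expect_equal(eigenvalue_lambda(3.5, 30, 0.01, 0.01),
               1e-4 + 1e-4 * sum(mu^2), tolerance = 1e-12)
})

test_that("energy-aware performance peaks at the critical exponent", {
  # both zeta terms -> 1 as alpha grows
  expect_equal(energy_aware_performance(50, 1, 0.01, 0.01, gamma = 1e-3),
               1 / 2e-4 - 1e-3, tolerance = 1e-6)

  grid <- seq(1.05, 6, by = 0.01)
  j <- energy_aware_performance(grid, 1, 0.01, 0.01, gamma = 1e-3)
  expect_equal(grid[which.max(j)], 3, tolerance = 1e-9)

  # information is flat below alpha_c but the energy cost is larger at 2
  expect_lt(energy_aware_performance(2, 1, 0.01, 0.01, 1e-3),
            energy_aware_performance(3, 1, 0.01, 0.01, 1e-3))

  # argmax is invariant to gamma over two orders of magnitude, for several D
  for (D in c(1, 2, 5)) {
    for (g in c(1e-5, 1e-4, 1e-3)) {
      jd <- energy_aware_performance(grid, D, 0.01, 0.01, gamma = g)
      expect_equal(grid[which.max(jd)], critical_exponent(D),
                   tolerance = 1e-9)
    }
  }

  # finite-N energy term uses the harmonic number
  expect_equal(energy_aware_performance(2, 1, 0.01, 0.01, 1e-2, N = 100),
               fisher_finite(2, 100, 0.01, 0.01) -
                 1e-2 * harmonic_number(2, 100))

  expect_error(energy_aware_performance(3, 1, 0.01, 0.01, gamma = 0),
               "gamma > 0")
  expect_error(energy_aware_performance(0.9, 1, 0.01, 0.01, gamma = 1e-3),
               "alpha > 1")
})

test_that("subset Fisher information follows the restricted harmonic sum", {
  expect_equal(subset_fisher(1:20, 3.2, 0.01, 0.01),
               fisher_finite(3.2, 20, 0.01, 0.01))
  expect_equal(subset_fisher(neuron_subset(1L), 2, 0.03, 0.04),
               1 / (0.03^2 + 0.04^2))
  # low modes carry more information than high modes at alpha = 3
  expect_gt(subset_fisher(1:10, 3, 0.01, 0.01),
            subset_fisher(11:20, 3, 0.01, 0.01))
  expect_error(subset_fisher(integer(0), 3, 0.01, 0.01), "nonempty")
})

test_that("broken power-law Fisher matches a direct spectrum-sum oracle", {
  expect_equal(broken_power_fisher(2.5, 2.5, 7, 40, 0.01, 0.01),
               fisher_finite(2.5, 40, 0.01, 0.01))
  expect_equal(broken_power_fisher(1.8, 3.3, 40, 40, 0.01, 0.01),
               fisher_finite(1.8, 40, 0.01, 0.01))

  # oracle: build the amplitude spectrum explicitly and sum n^2 a_n^2
  a1 <- 0.5; a2 <- 1.2; nb <- 10; N <- 1000
  amp <- c((1:nb)^(-a1 / 2),
           nb^((a2 - a1) / 2) * ((nb + 1):N)^(-a2 / 2))
  h <- sum((1:N)^2 * amp^2)
  expect_equal(broken_power_fisher(a1, a2, nb, N, 0.01, 0.01),
               h / (1e-4 + 1e-4 * h), tolerance = 1e-12)

  # information increases as either exponent decreases
  expect_gt(broken_power_fisher(0.4, 1.2, 10, 1000, 0.01, 0.01),
            broken_power_fisher(0.5, 1.2, 10, 1000, 0.01, 0.01))
  expect_gt(broken_power_fisher(0.5, 1.1, 10, 1000, 0.01, 0.01),
            broken_power_fisher(0.5, 1.2, 10, 1000, 0.01, 0.01))

  expect_error(broken_power_fisher(0.5, 1.2, 0, 10, 0.01, 0.01), "n_break")
})

test_that("mutual information is the entropy minus the half-log Fisher term", {
  # arithmetic oracle for the uniform prior
  expect_equal(mutual_information_from_fisher(1e4),
               log(2 * pi) - 0.5 * log(2 * pi * exp(1) / 1e4))
  # algebraic cancellation point: 2*pi*e/I = (2*pi)^2
  expect_equal(mutual_information_from_fisher(exp(1) / (2 * pi)), 0,
               tolerance = 1e-12)
  # monotone in the Fisher information
  expect_gt(mutual_information_from_fisher(1e4),
            mutual_information_from_fisher(1e3))
  # a uniform density passed as a function reproduces the closed form
  expect_equal(
    mutual_information_from_fisher(500, prior = function(t) rep(1, length(t))),
    mutual_information_from_fisher(500), tolerance = 1e-6)
  expect_error(mutual_information_from_fisher(0), "positive")
})

test_that("fisher and energy curves are tidy and know their optima", {
  fc <- fisher_curve(seq(2, 4, 0.5), D = c(1, 2), sigma0 = 0.01,
                     sigma_i = 0.01)
  expect_s3_class(fc, "fisher_curve")
  expect_equal(nrow(fc), 10)
  expect_equal(fc$fisher[fc$D == 1],
               fisher_limit(seq(2, 4, 0.5), 1, 0.01, 0.01))

  ec <- energy_curve(D = c(1, 2, 5))
  g <- glance(ec)
  expect_equal(g$alpha_opt, g$alpha_critical, tolerance = 1e-9)

  # kink detection on the default noise scale
  a <- seq(2, 4, by = 0.005)
  k <- detect_kink(a, fisher_limit(a, 1, 0.01, 0.01))
  expect_lte(abs(k$alpha - 3), 0.005 + 1e-12)
  expect_gt(abs(k$slope_right - k$slope_left), 1e3)
})
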