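# powerlawcoding

Tools for analysing **power-law neural population codes**: how well a
population of neurons whose covariance eigenspectrum decays as `n^(-alpha)`
encodes a circular stimulus, why the information does not degrade even in
the fractal regime below the critical exponent `alpha_c = 1 + 2/D`, and why
an energy–information trade-off nevertheless makes the critical exponent
the optimal operating point. The package is aimed at computational
neuroscientists studying population coding, neural manifolds, and efficient
coding.

## The model and its theory

A population of `2N` neurons encodes an angle `theta` through Fourier
receptive fields with power-law amplitudes, under shared input noise and
independent neural noise:

    r[2n-1] = n^(-alpha/2) cos(n(theta + eta)) + xi[2n-1]
    r[2n]   = n^(-alpha/2) sin(n(theta + eta)) + xi[2n]

with `eta ~ N(0, sigma1^2)` (one draw per response, shared by all neurons)
and `xi_i ~ N(0, sigma0^2)` i.i.d. In the small-noise limit the response
covariance is `Sigma = sigma0^2 I + sigma1^2 mu mu'` where
`mu = dm/dtheta` is the susceptibility — the rank-one term is the
differential (information-limiting) correlation — and the Fisher
information is stimulus-independent and closed-form:

    I = H_N(alpha - 2) / (sigma0^2 + sigma1^2 H_N(alpha - 2)),
    H_N(x) = sum_{n=1}^{N} n^(-x)

As `N -> infinity` (and for a `D`-dimensional stimulus) the harmonic number
becomes `zeta(alpha - 2/D)`; below `alpha_c = 1 + 2/D` the zeta factor
diverges and the information sits exactly on the plateau `1/sigma1^2`,
independent of the neural noise. Adding a metabolic cost proportional to
the mean-square activity `zeta(alpha)` gives the energy-aware performance
`J_D(alpha) = I_D(alpha) - gamma * zeta(alpha)`, maximized exactly at
`alpha_c`. A maximum-likelihood decoder built by numerical integration of
the exact posterior verifies the theory by Monte Carlo.

## Worked example

```r
library(powerlawcoding)

# 50 Fourier modes (100 neurons), supercritical exponent, 1% noise
spec <- code_spec(N = 50, alpha = 4, sigma0 = 0.01, sigma1 = 0.01)

# closed-form Fisher information of the finite code
fisher_finite(4, 50, 0.01, 0.01)
#> [1] 6190.669

# Monte-Carlo ML decoding: the per-observation inverse error variance
# should land on the Fisher information (Cramér–Rao from below)
ds <- decoding_experiment(spec, M = 10, n_trials = 1000, seed = 1)
ds
#> <decoding_summary> 1000 trials, M = 10, 50 modes
#>   1/Var = 5.801e+04, 1/(M Var) = 5801 (rel. MC se 4.5%), |err| > pi/2: 0

# the energy-aware optimum lies at alpha_c = 1 + 2/D for every dimension
glance(energy_curve(D = c(1, 2, 5, Inf)))
#> # A tibble: 4 × 5
#>       D alpha_opt performance_max alpha_critical gamma
#>   <dbl>     <dbl>           <dbl>          <dbl> <dbl>
#> 1     1      3             10000.            3   0.001
#> 2     2      2             10000.            2   0.001
#> 3     5      1.4           10000.            1.4 0.001
#> 4   Inf      1.05           8282.            1   0.001
```

The decoding summary says the 1000-trial inverse error variance per
observation (5801) lies within the Monte-Carlo band of the closed form
(6191); the energy table says the grid argmax of `J_D` equals the critical
exponent for each dimension (for `D = Inf` the optimum `alpha_c = 1` sits
at the zeta pole, so the argmax is the nearest grid point, 1.05).

Other entry points: `susceptibility_variance_scatter()` (recovers
`sigma0^2`, `sigma1^2` from sampled covariances), `marginal_eigenspectrum()`
and `spectrum_slope()` (the power-law premise), `removal_subset()` +
`subset_fisher()` (mode-ablation theory and experiments),
`broken_power_fisher()` (two-exponent spectra), `run_experiment()`
(YAML-configured pipelines writing CSV + JSON). Result objects support
`tidy()`, `glance()` and `autoplot()`. See the vignette
(`vignettes/power-law-coding.Rmd`) for the full methods account.

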