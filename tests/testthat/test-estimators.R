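test_that("BAR solves the crossing point of degenerate distributions", {
  fwd <- work_set(rep(5, 20), "forward")
  rev <- work_set(rep(-5, 20), "reverse")
  expect_equal(bar_estimate(fwd, rev)$value, 5, tolerance = 1e-8)
})

test_that("BAR agrees with the likelihood-maximization oracle", {
  for (seed in 1:5) {
    p <- sample_gaussian_pair(dG = 10, sigma = 2, n = 200, seed = seed)
    got <- bar_estimate(p$forward, p$reverse)$value
    expect_equal(got, bar_loglik_oracle(p$forward, p$reverse),
                 tolerance = 1e-6)
  }
  # unbalanced design exercises the Bennett constant C = RT ln(nf/nr)
  set.seed(42)
  fwd <- work_set(rnorm(300, 13.4, 2), "forward")
  rev <- work_set(rnorm(80, -6.6, 2), "reverse")
  expect_equal(bar_estimate(fwd, rev)$value, bar_loglik_oracle(fwd, rev),
               tolerance = 1e-6)
})

test_that("BAR recovers the truth on a Crooks-consistent Gaussian pair", {
  p <- sample_gaussian_pair(dG = 10, sigma = 2, n = 5000, seed = 3)
  est <- bar_estimate(p$forward, p$reverse)
  bc <- bootstrap_ci(bar_estimate, p$forward, p$reverse, n_boot = 1000,
                     seed = 4)
  expect_lt(abs(est$value - 10), 3 * bc$se)
})

test_that("BAR is antisymmetric under direction swap with sign flip", {
  p <- sample_gaussian_pair(dG = 8, sigma = 3, n = 300, seed = 9)
  ab <- bar_estimate(p$forward, p$reverse)$value
  swapped_fwd <- work_set(p$reverse$works, "forward",
                          temperature_K = p$reverse$temperature_K)
  swapped_rev <- work_set(p$forward$works, "reverse",
                          temperature_K = p$forward$temperature_K)
  ba <- bar_estimate(swapped_fwd, swapped_rev)$value
  expect_equal(ba, -ab, tolerance = 1e-7)
})

test_that("BAR rejects mismatched temperatures and reports bracket failure", {
  fwd <- work_set(rnorm(20, 5), "forward", temperature_K = 298.15)
  rev <- work_set(rnorm(20, -5), "reverse", temperature_K = 310)
  expect_error(bar_estimate(fwd, rev), "temperature")
})

test_that("Jarzynski reduces to the value for degenerate works and to the
           Gaussian limit for normal works", {
  expect_equal(jarzynski_estimate(work_set(rep(3.2, 10), "forward"))$value,
               3.2)
  set.seed(21)
  ws <- work_set(rnorm(1e6, 13.372, 2), "forward")
  expect_equal(jarzynski_estimate(ws)$value, 10.0, tolerance = 0.1)
})

test_that("Jarzynski at n = 50 is biased positive in the process direction", {
  # dissipation beta sigma^2 / 2 = 3.38 kcal/mol >> RT: the low-work tail
  # dominating the exponential average is undersampled at n = 50
  errs <- vapply(1:200, function(seed) {
    p <- sample_gaussian_pair(dG = 10, sigma = 2, n = 50, seed = seed)
    jarzynski_estimate(p$forward)$value - 10
  }, numeric(1))
  expect_gt(mean(errs), 0)
  expect_gt(mean(errs) / (sd(errs) / sqrt(length(errs))), 3) # >3 MC-SE
})

test_that("Gaussian estimate evaluates <W> - beta sigma^2/2 on exact moments
           and is unbiased for normal work", {
  ws <- work_set(rep(4.2, 10), "forward")
  expect_equal(gaussian_estimate(ws, gate = "none")$value, 4.2)

  x <- sample_with_moments(50, mean = 20, var = 4, seed = 2)
  g <- gaussian_estimate(work_set(x, "forward"), gate = "none")
  expect_equal(g$value, 20 - 4 / (2 * RT298), tolerance = 1e-9)
  expect_equal(g$value, 16.625, tolerance = 1e-3)

  reps <- vapply(1:500, function(seed) {
    p <- sample_gaussian_pair(10, 2, 50, seed = seed + 400)
    gaussian_estimate(p$forward, gate = "none")$value
  }, numeric(1))
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 10), 2 * mc_se)

  expect_error(gaussian_estimate(work_set(c(1, 2), "forward")), ">= 3")
})

test_that("the Anderson-Darling gate flags non-normal work distributions", {
  set.seed(5)
  ws <- work_set(rexp(100, 0.2), "forward")
  g <- gaussian_estimate(ws, gate = "ad")
  expect_false(g$applicable)
  expect_true(is.finite(g$value))  # value still reported, mirroring "n/a"
})

test_that("mean Jarzynski brackets and tracks BAR", {
  fwd <- work_set(rep(7, 10), "forward")
  rev <- work_set(rep(-7, 10), "reverse")
  expect_equal(jarzynski_mean(fwd, rev)$value, 7)

  p <- sample_gaussian_pair(dG = 10, sigma = 2, n = 20000, seed = 6)
  expect_equal(jarzynski_mean(p$forward, p$reverse)$value, 10,
               tolerance = 0.15)

  # low overlap: wide distributions, 50 works per side
  p2 <- sample_gaussian_pair(dG = 10, sigma = 3.5, n = 50, seed = 7)
  bar <- bar_estimate(p2$forward, p2$reverse)
  jm <- jarzynski_mean(p2$forward, p2$reverse)
  ci <- bootstrap_ci(bar_estimate, p2$forward, p2$reverse, n_boot = 1000,
                     seed = 8)$halfwidth +
    bootstrap_ci(jarzynski_mean, p2$forward, p2$reverse, n_boot = 1000,
                 seed = 9)$halfwidth
  expect_lt(abs(bar$value - jm$value), ci)
})

test_that("EM mixture fit has the exact one-component closed form and
           recovers two separated components", {
  set.seed(10)
  x <- rnorm(100, 3, 2)
  f1 <- fit_mixture_em(x, n_g = 1)
  expect_equal(f1$means, mean(x))
  expect_equal(f1$variances, mean((x - mean(x))^2))

  set.seed(11)
  x2 <- c(rnorm(2500, 0, 1), rnorm(2500, 8, 1))
  f2 <- fit_mixture_em(x2, n_g = 2, seed = 12)
  expect_true(f2$converged)
  expect_lt(max(abs(f2$means - c(0, 8))), 0.15)
  expect_lt(max(abs(f2$weights - 0.5)), 0.05)

  expect_error(fit_mixture_em(rnorm(8), n_g = 2), "n >= 5")
})

test_that("EM log-likelihood matches the mclust oracle", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  set.seed(13)
  x <- c(rnorm(600, 0, 1), rnorm(400, 6, 1.5))
  fit <- fit_mixture_em(x, n_g = 2, seed = 14)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("EM fits are deterministic given a seed", {
  set.seed(15)
  x <- c(rnorm(200), rnorm(200, 5))
  f1 <- fit_mixture_em(x, n_g = 2, seed = 99)
  f2 <- fit_mixture_em(x, n_g = 2, seed = 99)
  expect_identical(f1, f2)
})

test_that("mixture free energy reduces to the Gaussian form and matches the
           Crooks-integral oracle", {
  # one component: exactly mu - beta sigma^2 / 2
  f <- gmix_fit(1, 13.372, 4)
  expect_equal(mixture_free_energy(f, 298.15)$value,
               13.372 - 4 / (2 * RT298))
  expect_equal(mixture_free_energy(f, 298.15)$value, 10.0,
               tolerance = 2e-3)

  # two identical components degenerate to one
  f2 <- gmix_fit(c(0.5, 0.5), c(13.372, 13.372), c(4, 4))
  expect_equal(mixture_free_energy(f2, 298.15)$value,
               mixture_free_energy(f, 298.15)$value)

  # oracle: dG = -RT ln int P_f(W) e^{-beta W} dW by numeric quadrature
  w <- c(0.5, 0.5); mu <- c(10, 14); s2 <- c(1, 1)
  b <- 1 / RT298
  dens <- function(x) w[1] * dnorm(x, mu[1], 1) + w[2] * dnorm(x, mu[2], 1)
  num <- integrate(function(x) dens(x) * exp(-b * (x - 10)), -40, 60,
                   rel.tol = 1e-12)$value
  oracle <- 10 - RT298 * log(num)   # shifted integrand for stability
  got <- mixture_free_energy(gmix_fit(w, mu, s2), 298.15)$value
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("empirical convolution is the full cross-sum", {
  expect_equal(convolve_unbound_bound(2.5, -1)$works, 1.5)
  cs <- convolve_unbound_bound(rnorm(50), rnorm(50))
  expect_length(cs$works, 2500L)

  set.seed(16)
  bw <- rnorm(400, 3, 1.5); uw <- rnorm(400, -1, 0.8)
  cs2 <- convolve_unbound_bound(bw, uw)
  expect_equal(mean(cs2$works), mean(bw) + mean(uw), tolerance = 1e-9)
  # population (1/n) variances add exactly under the full cross-sum
  vm <- function(x) mean((x - mean(x))^2)
  expect_equal(vm(cs2$works), vm(bw) + vm(uw), tolerance = 1e-9)
})
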