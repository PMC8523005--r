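test_that("dissipation arithmetic and identities hold", {
  fwd <- work_set(rep(25, 10), "forward", k_rstr = 10)
  d <- dissipation(fwd, 11.3 + 7.52)
  expect_equal(d$w_diss, 6.18)

  # reversible limit
  expect_equal(dissipation(work_set(rep(18.82, 5), "forward"), 18.82)$w_diss,
               0)

  # W_d,F + W_d,R = <W>_F + <W>_R independent of the reference
  set.seed(40)
  f <- work_set(rnorm(30, 20, 2), "forward")
  r <- work_set(rnorm(30, -12, 2), "reverse")
  for (ref in c(0, 5, 18.8)) {
    tot <- dissipation(f, ref)$w_diss + dissipation(r, ref)$w_diss
    expect_equal(tot, mean(f$works) + mean(r$works), tolerance = 1e-12)
  }
})

test_that("lambda profiles yield mean work and beta sigma^2/2 per grid point", {
  lam <- seq(0, 1, length.out = 11)
  # identical trajectories: variance term is zero everywhere
  m <- rbind(2 * lam, 2 * lam, 2 * lam)
  p <- lambda_work_profile(lam, m, "forward")
  st <- lambda_profile_stats(p)
  expect_equal(st$mean_work, 2 * lam)
  expect_equal(st$half_beta_var, rep(0, 11))

  # W_i(lam) = a_i lam with a_i ~ N(mu_a, sd_a^2):
  # variance term = beta sd_a^2 lam^2 / 2
  set.seed(41)
  a <- rnorm(4000, 10, 2)
  p2 <- lambda_work_profile(lam, outer(a, lam), "forward")
  st2 <- lambda_profile_stats(p2, 298.15)
  b <- 1 / RT298
  expect_equal(st2$half_beta_var, b * var(a) * lam^2 / 2, tolerance = 1e-9)
  expect_equal(st2$half_beta_var[11], b * 4 * 1 / 2, tolerance = 0.15)

  # profile endpoint consistency with the final works
  expect_equal(st2$mean_work[11], mean(a))

  expect_error(lambda_profile_stats(
    lambda_work_profile(lam, matrix(2 * lam, nrow = 1), "forward")),
    ">= 2 trajectories")
  expect_error(lambda_work_profile(lam, outer(a[1:3], lam + 0.1)),
               "lambda = 0|\\[0, 1\\]")
  expect_error(lambda_work_profile(c(0, 0.5, 0.5, 1), matrix(0, 2, 4)),
               "strictly increasing")
})

test_that("skewness is the third standardized moment", {
  expect_equal(skewness_mu3(c(-1, 0, 1)), 0)
  set.seed(42)
  x <- rexp(1e6)
  expect_equal(skewness_mu3(x), 2.0, tolerance = 0.02)
  expect_equal(skewness_mu3(-x), -skewness_mu3(x))
  expect_error(skewness_mu3(rep(1, 10)), "zero variance")
})

test_that("skewness matches the e1071 oracle", {
  skip_if_not_installed("e1071")
  set.seed(43)
  x <- rgamma(500, 2)
  expect_equal(skewness_mu3(x), e1071::skewness(x, type = 1),
               tolerance = 1e-12)
})

test_that("Anderson-Darling statistic matches the nortest oracle", {
  skip_if_not_installed("nortest")
  set.seed(44)
  for (x in list(rnorm(50), rexp(80), runif(40))) {
    got <- ad_normality_test(x)
    ref <- nortest::ad.test(x)
    expect_equal(got$A2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$pass, ref$p.value > 0.05)
  }
})

test_that("Anderson-Darling test rejects clearly non-normal samples and
           errors on degenerate input", {
  set.seed(45)
  expect_false(ad_normality_test(runif(1000))$pass)
  expect_true(ad_normality_test(rnorm(1000, 5, 2))$pass)
  expect_error(ad_normality_test(rep(1, 20)), "degenerate")
  expect_error(ad_normality_test(rnorm(5)), ">= 8")
  expect_error(ad_normality_test(rnorm(50), alpha = 0.5), "alpha")
})

test_that("bootstrap half-width is zero for degenerate works and
           deterministic given a seed", {
  ws <- work_set(rep(2, 30), "forward")
  bc <- bootstrap_ci(function(w) mean(w$works), ws, n_boot = 1000, seed = 1)
  expect_equal(bc$halfwidth, 0)

  p <- sample_gaussian_pair(10, 2, 50, seed = 46)
  b1 <- bootstrap_ci(bar_estimate, p$forward, p$reverse, n_boot = 1000,
                     seed = 2)
  b2 <- bootstrap_ci(bar_estimate, p$forward, p$reverse, n_boot = 1000,
                     seed = 2)
  expect_identical(b1$estimates, b2$estimates)

  # two independent seeds agree at large n_boot
  b3 <- bootstrap_ci(function(w) mean(w$works), p$forward,
                     n_boot = 10000, seed = 3)
  b4 <- bootstrap_ci(function(w) mean(w$works), p$forward,
                     n_boot = 10000, seed = 4)
  expect_lt(abs(b3$halfwidth / b4$halfwidth - 1), 0.05)

  # estimators failing on too many resamples raise a diagnostic error
  flaky <- local({
    k <- 0
    function(w) { k <<- k + 1; if (k %% 2) stop("boom") else 1 }
  })
  expect_error(bootstrap_ci(flaky, p$forward, n_boot = 100, seed = 5),
               "failed on")
})

test_that("Crooks residuals recover beta slope on consistent pairs and
           respond linearly to a reference shift", {
  p <- sample_gaussian_pair(10, 2, 20000, seed = 47)
  r <- ct_residuals(p$forward, p$reverse, 10, bins = 0.5)
  b <- 1 / RT298
  expect_lt(abs(r$slope / b - 1), 0.05)
  expect_lt(abs(mean(r$table$residual)), 0.1)

  r2 <- ct_residuals(p$forward, p$reverse, 11, bins = 0.5)
  expect_equal(mean(r2$table$residual) - mean(r$table$residual), b,
               tolerance = 1e-9)

  # disjoint distributions: no shared bins
  f <- work_set(rnorm(100, 50, 0.5), "forward")
  rv <- work_set(rnorm(100, 40, 0.5), "reverse")
  expect_error(ct_residuals(f, rv, 10), "insufficient overlap")

  # fixed 2 kcal/mol binning is supported
  r3 <- ct_residuals(p$forward, p$reverse, 10, bins = 2)
  expect_true(all(abs(diff(r3$table$mid) %% 2) < 1e-9))
})
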