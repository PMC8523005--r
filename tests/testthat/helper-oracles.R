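# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

RT298 <- rt_kcal(298.15)

# BAR as direct maximization of the Crooks maximum-likelihood objective
# (logistic log-likelihood in dG), instead of the package's root solve of
# the self-consistent equation.
bar_loglik_oracle <- function(forward, reverse) {
  wf <- forward$works; wr <- reverse$works
  b <- 1 / rt_kcal(forward$temperature_K)
  M <- log(length(wf) / length(wr))
  ll <- function(dG)
    sum(stats::plogis(b * (wf - dG) + M, log.p = TRUE)) +
      sum(stats::plogis(b * (wr + dG) - M, log.p = TRUE))
  stats::optimize(ll, c(min(-wr) - 60, max(wf) + 60), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Stiff-spring restraint free energy by direct 1-D quadratures of the
# factorized six-coordinate configuration integral:
#   Z = [int r^2 e^{-bK(r-d1)^2/2} dr] [int sin(t) e^{-bK(t-t0)^2/2} dt]^2*
#       [int_{-pi}^{pi} e^{-bK phi^2/2} dphi]^3
# and dA = RT ln(V0 * 8 pi^2 / Z) with V0 = 1661 A^3.
boresch_quadrature_oracle <- function(g) {
  rt <- rt_kcal(g$temperature_K)
  bk <- g$k_rstr / rt
  Ir <- stats::integrate(function(r) r^2 * exp(-bk * (r - g$d1_A)^2 / 2),
                         max(0, g$d1_A - 12 / sqrt(bk)),
                         g$d1_A + 12 / sqrt(bk), rel.tol = 1e-10)$value
  Itheta <- function(t0)
    stats::integrate(function(t) sin(t) * exp(-bk * (t - t0)^2 / 2),
                     0, pi, rel.tol = 1e-10)$value
  Iphi <- stats::integrate(function(p) exp(-bk * p^2 / 2), -pi, pi,
                           rel.tol = 1e-10)$value
  Z <- Ir * Itheta(g$theta2) * Itheta(g$theta3) * Iphi^3
  rt * log(1661 * 8 * pi^2 / Z)
}

# sample with exactly prescribed first two moments
sample_with_moments <- function(n, mean, var, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  as.numeric(scale(x)) * sqrt(var) + mean
}
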