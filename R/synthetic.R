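# Exactly Crooks-consistent synthetic work generators.
#
# Every generator enforces the Crooks theorem P_f(W)/P_r(-W) = e^{beta (W-dG)}
# analytically (componentwise Gaussian mapping), so generated pairs are valid
# inputs for every estimator and pass the CT-residual diagnostic by
# construction.

#' Crooks-consistent Gaussian forward/reverse work pair
#'
#' The unique same-variance Gaussian pair satisfying the Crooks theorem for a
#' given free energy: forward `W ~ N(dG + beta sigma^2/2, sigma^2)` and
#' reverse `W ~ N(-dG + beta sigma^2/2, sigma^2)`. The common dissipation is
#' `beta sigma^2 / 2`.
#'
#' @param dG true dissociation free energy, kcal/mol.
#' @param sigma work standard deviation, kcal/mol (> 0).
#' @param n number of trajectories per direction (>= 2).
#' @param temperature_K temperature in kelvin.
#' @param seed optional integer seed (bit-reproducible given seed).
#' @param tau_ns,k_rstr protocol tags stored on the work sets.
#' @return a list with `forward` and `reverse` [work_set]s and `dG`.
#' @export
#' @examples
#' p <- sample_gaussian_pair(dG = 10, sigma = 2, n = 50, seed = 1)
#' mean(p$forward$works) # near 13.37: dG + beta sigma^2 / 2
sample_gaussian_pair <- function(dG, sigma, n, temperature_K = 298.15,
                                 seed = NULL, tau_ns = 1, k_rstr = 0) {
  stopifnot(sigma > 0, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  b <- .beta(temperature_K)
  d <- b * sigma^2 / 2
  fwd <- stats::rnorm(n, dG + d, sigma)
  rev <- stats::rnorm(n, -dG + d, sigma)
  list(forward = work_set(fwd, "forward", tau_ns, k_rstr, temperature_K),
       reverse = work_set(rev, "reverse", tau_ns, k_rstr, temperature_K),
       dG = dG)
}

#' Specification of a Gaussian-mixture forward work distribution
#'
#' @param weights positive component weights summing to 1.
#' @param means component means, kcal/mol.
#' @param variances component variances (> 0), kcal^2/mol^2.
#' @param temperature_K temperature in kelvin.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(weights, means, variances,
                         temperature_K = 298.15) {
  stopifnot(length(weights) == length(means),
            length(means) == length(variances))
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(variances <= 0)) stop("variances must be > 0")
  structure(list(weights = as.numeric(weights), means = as.numeric(means),
                 variances = as.numeric(variances),
                 temperature_K = temperature_K),
            class = "mixture_spec")
}

# closed-form implied free energy of a mixture forward distribution
.mixture_implied_dG <- function(spec) {
  b <- .beta(spec$temperature_K)
  -.logsumexp(log(spec$weights) -
                b * (spec$means - b * spec$variances / 2)) / b
}

# CT map of a forward Gaussian mixture to its reverse-work mixture:
# component i -> mean -(mu_i - beta sigma_i^2), same variance,
# weight proportional to c_i exp(-beta (mu_i - beta sigma_i^2 / 2))
.ct_reverse_spec <- function(spec) {
  b <- .beta(spec$temperature_K)
  lw <- log(spec$weights) - b * (spec$means - b * spec$variances / 2)
  mixture_spec(exp(lw - .logsumexp(lw)),
               -(spec$means - b * spec$variances),
               spec$variances, spec$temperature_K)
}

.sample_mixture <- function(spec, n) {
  comp <- sample.int(length(spec$weights), n, replace = TRUE,
                     prob = spec$weights)
  stats::rnorm(n, spec$means[comp], sqrt(spec$variances[comp]))
}

#' Crooks-consistent samples from a Gaussian-mixture work distribution
#'
#' Draws forward works from the given mixture and reverse works from the
#' mixture implied by the Crooks theorem, derived componentwise: component
#' `i` maps to mean `-(mu_i - beta sigma_i^2)` with unchanged variance and
#' weight proportional to `c_i exp(-beta (mu_i - beta sigma_i^2 / 2))`
#' (renormalized). The implied free energy is computed in closed form from
#' the mixture estimator identity.
#'
#' @param spec a [mixture_spec] for the forward work distribution.
#' @param n trajectories per direction.
#' @param seed optional integer seed.
#' @param tau_ns,k_rstr protocol tags stored on the work sets.
#' @return a list with `forward`, `reverse` ([work_set]s), `implied_dG`
#'   (kcal/mol, dissociation) and `reverse_spec`.
#' @export
sample_ct_mixture <- function(spec, n, seed = NULL, tau_ns = 1, k_rstr = 0) {
  stopifnot(inherits(spec, "mixture_spec"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  rspec <- .ct_reverse_spec(spec)
  fwd <- .sample_mixture(spec, n)
  rev <- .sample_mixture(rspec, n)
  list(forward = work_set(fwd, "forward", tau_ns, k_rstr,
                          spec$temperature_K),
       reverse = work_set(rev, "reverse", tau_ns, k_rstr,
                          spec$temperature_K),
       implied_dG = .mixture_implied_dG(spec),
       reverse_spec = rspec)
}

#' Scenario specification for restrained double-system switching ensembles
#'
#' Knobs of the phenomenological emulator behind [dssb_scenario()]; the
#' dissipation laws are explicit toys (the real dependence on restraint
#' strength and switching time is system-specific), chosen only to reproduce
#' the qualitative pattern of restrained switching experiments: forward
#' dissipation growing strongly with the restraint strength, reverse
#' dissipation nearly restraint-independent with a mild growth in switching
#' time.
#'
#' @param dG_alch nominal dissociation free energy of the switched process,
#'   kcal/mol (default 18.6, a typical restrained host-guest value).
#' @param k_rstr restraint force constant (equal-K convention; default 10).
#' @param tau_ns switching time in ns (default 1).
#' @param diss0 baseline (restraint-free) dissipation at tau = 1 ns,
#'   kcal/mol.
#' @param a_k restraint-dissipation coefficient: the forward tail component
#'   sits `a_k log(1 + k_rstr) / sqrt(tau_ns)` above the baseline.
#' @param b_tau mild switching-time growth of the baseline dissipation:
#'   `diss0 (1 + b_tau log(tau_ns))`.
#' @param w_tail weight of the high-dissipation forward component.
#' @param n_traj trajectories per direction (>= 2; default 50).
#' @param n_lambda lambda grid points of the generated work profiles.
#' @param temperature_K temperature in kelvin.
#' @param seed optional integer seed.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(dG_alch = 18.6, k_rstr = 10, tau_ns = 1,
                          diss0 = 3, a_k = 4, b_tau = 0.3, w_tail = 0.5,
                          n_traj = 50, n_lambda = 51,
                          temperature_K = 298.15, seed = NULL) {
  stopifnot(n_traj >= 2, tau_ns > 0, k_rstr >= 0, diss0 > 0,
            w_tail > 0, w_tail < 1, n_lambda >= 2)
  structure(as.list(environment()), class = "scenario_spec")
}

#' Generate a restrained double-system switching scenario
#'
#' Builds an exactly Crooks-consistent forward/reverse work pair whose
#' population statistics mimic restrained nonequilibrium switching: the
#' forward work distribution is a two-component mixture of a relaxed,
#' CT-symmetric baseline component (dissipation `d0`, variance `2 d0 / beta`)
#' and a restraint-dissipation tail shifted up by
#' `a_k log(1 + k_rstr) / sqrt(tau_ns)`. Because the tail keeps the baseline
#' variance, the Crooks map suppresses it exponentially in the reverse
#' direction, so reverse dissipation stays near `d0` regardless of the
#' restraint — the asymmetry seen in restrained switching experiments.
#' Cumulative work profiles are smooth monotone curves ending at the sampled
#' work values.
#'
#' @param spec a [scenario_spec].
#' @return a list with `forward`, `reverse` ([work_set]s),
#'   `profile_forward`, `profile_reverse` ([lambda_work_profile]s),
#'   `implied_dG` (the scenario's reference crossing point, kcal/mol),
#'   `forward_spec` (the underlying [mixture_spec]) and population
#'   moments `pop_mean_fwd`, `pop_var_fwd`, `diss_fwd`, `diss_rev`.
#' @export
dssb_scenario <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  b <- .beta(spec$temperature_K)
  d0 <- spec$diss0 * (1 + spec$b_tau * log(spec$tau_ns))
  if (d0 <= 0) stop("baseline dissipation must stay positive; reduce b_tau")
  dK <- spec$a_k * log1p(spec$k_rstr) / sqrt(spec$tau_ns)
  s2 <- 2 * d0 / b
  fwd_spec <- mixture_spec(
    weights = c(1 - spec$w_tail, spec$w_tail),
    means = spec$dG_alch + d0 + c(0, dK),
    variances = c(s2, s2),
    temperature_K = spec$temperature_K)
  draw <- sample_ct_mixture(fwd_spec, spec$n_traj, seed = spec$seed,
                            tau_ns = spec$tau_ns, k_rstr = spec$k_rstr)
  # smooth monotone cumulative profiles ending at the sampled works
  lam <- seq(0, 1, length.out = spec$n_lambda)
  shape <- lam^2 * (3 - 2 * lam)  # smoothstep, 0 -> 1
  prof <- function(ws) lambda_work_profile(
    lam, outer(ws$works, shape), direction = ws$direction)
  mu_pop <- sum(fwd_spec$weights * fwd_spec$means)
  var_pop <- sum(fwd_spec$weights * (fwd_spec$variances +
                                       fwd_spec$means^2)) - mu_pop^2
  rspec <- draw$reverse_spec
  mu_rev <- sum(rspec$weights * rspec$means)
  c(draw[c("forward", "reverse", "implied_dG")],
    list(profile_forward = prof(draw$forward),
         profile_reverse = prof(draw$reverse),
         forward_spec = fwd_spec,
         pop_mean_fwd = mu_pop, pop_var_fwd = var_pop,
         diss_fwd = mu_pop - draw$implied_dG,
         diss_rev = mu_rev + draw$implied_dG))
}

#' Write synthetic dhdl.xvg files with prescribed work targets
#'
#' Writes one GROMACS-style xvg file per target work value: a linear lambda
#' schedule over `[0, tau_ns]`, constant dH/dlambda equal to the target
#' (sign-adjusted so that [work_from_dhdl()] with the direction's sign
#' recovers the target), plus optional white noise whose trapezoidal
#' integral vanishes in expectation. Files carry `#` and `@` header lines.
#'
#' @param target_work numeric vector of target work values, kcal/mol.
#' @param n_points grid points per file (>= 2).
#' @param noise_sd standard deviation of per-point dhdl noise (0 = exact).
#' @param seed optional integer seed.
#' @param out_dir output directory (created if missing).
#' @param tau_ns switching time in ns.
#' @param direction `"forward"` or `"reverse"` (sets the sign convention of
#'   the stored dH/dlambda).
#' @param unit unit in which the files are written; `"kcal/mol"` (default)
#'   or `"kJ/mol"` (values multiplied by 4.184, as GROMACS would write).
#' @return character vector of file paths, invisibly.
#' @export
synth_dhdl_files <- function(target_work, n_points = 101, noise_sd = 0,
                             seed = NULL, out_dir = tempdir(), tau_ns = 1,
                             direction = c("forward", "reverse"),
                             unit = c("kcal/mol", "kJ/mol")) {
  direction <- match.arg(direction)
  unit <- match.arg(unit)
  stopifnot(n_points >= 2)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  if (!is.null(seed)) set.seed(seed)
  sgn <- if (direction == "forward") 1 else -1
  tt <- seq(0, tau_ns, length.out = n_points)
  lam <- tt / tau_ns
  paths <- character(length(target_work))
  for (i in seq_along(target_work)) {
    dhdl <- sgn * target_work[i] + stats::rnorm(n_points, 0, noise_sd)
    if (unit == "kJ/mol") dhdl <- dhdl * .KJ_PER_KCAL
    path <- file.path(out_dir, sprintf("dhdl_%s_%04d.xvg", direction, i))
    con <- file(path, "w")
    writeLines(c(
      "# synthetic dhdl file (neqfe::synth_dhdl_files)",
      sprintf("# direction = %s, tau_ns = %g, unit = %s", direction,
              tau_ns, unit),
      "@    title \"dH/d\\xl\\f{}\"",
      "@    xaxis  label \"Time (ns)\"",
      sprintf("@    yaxis  label \"dH/dl (%s)\"", unit)), con)
    utils::write.table(
      data.frame(t = formatC(tt, digits = 12, format = "g"),
                 dhdl = formatC(dhdl, digits = 12, format = "g"),
                 lam = formatC(lam, digits = 12, format = "g")),
      con, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
    paths[i] <- path
  }
  invisible(paths)
}

#' Isotropic Gaussian COM-COM displacement samples
#'
#' Emulates the host-guest center-of-mass displacement distribution sampled
#' in the fully coupled unrestrained bound state, from which the
#' binding-site volume is estimated. For an isotropic Gaussian of standard
#' deviation `sigma` the true site volume is `(2 pi sigma^2)^{3/2}`.
#'
#' @param sigma_A isotropic standard deviation in angstroms (> 0).
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return a list with `displacements` (n x 3 matrix, angstroms) and
#'   `v_site_true` (cubic angstroms).
#' @export
sample_com_displacements <- function(sigma_A, n, seed = NULL) {
  stopifnot(sigma_A > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  list(displacements = matrix(stats::rnorm(3 * n, 0, sigma_A), ncol = 3L),
       v_site_true = (2 * pi * sigma_A^2)^(3 / 2))
}
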