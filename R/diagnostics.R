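# Dissipation, distribution-shape, normality, overlap and bootstrap
# diagnostics: the quantities that decide whether a unidirectional estimate
# can be trusted.

#' Dissipated work of a nonequilibrium ensemble
#'
#' Dissipation is the gap between the mean nonequilibrium work and the free
#' energy of the process: `W_d = <W>_F - dG_ref` for the forward direction
#' and `W_d = <W>_R + dG_ref` for the reverse (with `dG_ref` the reference
#' dissociation free energy, e.g. a converged BAR value for the same
#' restraint strength).
#'
#' @param ws a [work_set].
#' @param dG_ref reference dissociation free energy in kcal/mol.
#' @return an object of class `dissipation_result` with fields `direction`,
#'   `w_diss`, `mean_work`, `dG_ref`.
#' @export
dissipation <- function(ws, dG_ref) {
  ws <- .as_work_set(ws)
  if (!is.finite(dG_ref)) stop("'dG_ref' must be finite")
  mw <- mean(ws$works)
  wd <- if (ws$direction == "forward") mw - dG_ref else mw + dG_ref
  structure(list(direction = ws$direction, w_diss = wd, mean_work = mw,
                 dG_ref = dG_ref),
            class = "dissipation_result")
}

#' @export
print.dissipation_result <- function(x, ...) {
  cat(sprintf("<dissipation> %s: W_d = %.3f kcal/mol (<W> = %.3f, ref = %.3f)\n",
              x$direction, x$w_diss, x$mean_work, x$dG_ref))
  invisible(x)
}

#' Per-trajectory cumulative work on a lambda grid
#'
#' @param lam_grid strictly increasing lambda values in [0, 1].
#' @param works_matrix matrix of cumulative work, one row per trajectory and
#'   one column per grid point; the first column (lambda = 0) must be zero.
#' @param direction `"forward"` or `"reverse"`.
#' @return an object of class `lambda_work_profile`.
#' @export
lambda_work_profile <- function(lam_grid, works_matrix,
                                direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  works_matrix <- as.matrix(works_matrix)
  if (any(diff(lam_grid) <= 0)) stop("'lam_grid' must be strictly increasing")
  if (any(lam_grid < 0 | lam_grid > 1)) stop("'lam_grid' must lie in [0, 1]")
  if (ncol(works_matrix) != length(lam_grid))
    stop("'works_matrix' must have one column per grid point")
  if (lam_grid[1L] == 0 && any(abs(works_matrix[, 1L]) > 1e-9))
    stop("cumulative work must be 0 at lambda = 0")
  structure(list(lam_grid = lam_grid, works_matrix = works_matrix,
                 direction = direction),
            class = "lambda_work_profile")
}

#' Mean-work and dissipation-related profiles along lambda
#'
#' Per lambda grid point, the sample mean of the cumulative work and the
#' dissipation-related term `beta sigma^2(lambda) / 2` (unbiased variance);
#' for near-Gaussian work both grow together as dissipation accumulates.
#'
#' @param profile a [lambda_work_profile] with >= 2 trajectories.
#' @param temperature_K temperature in kelvin.
#' @return a data.frame with columns `lam`, `mean_work`,
#'   `half_beta_var` (kcal/mol).
#' @export
lambda_profile_stats <- function(profile, temperature_K = 298.15) {
  stopifnot(inherits(profile, "lambda_work_profile"))
  m <- profile$works_matrix
  if (nrow(m) < 2L)
    stop("variance undefined: need >= 2 trajectories")
  b <- .beta(temperature_K)
  data.frame(lam = profile$lam_grid,
             mean_work = colMeans(m),
             half_beta_var = b * apply(m, 2L, stats::var) / 2)
}

#' Skewness (third standardized moment) of a work sample
#'
#' `mu_3 = m_3 / m_2^{3/2}` with central sample moments. A markedly nonzero
#' skewness flags a non-normal work distribution, invalidating the Gaussian
#' estimator even when a normality test fails to reject.
#'
#' @param works numeric vector (n >= 3, nonzero variance) or [work_set].
#' @return dimensionless skewness.
#' @export
skewness_mu3 <- function(works) {
  if (is_work_set(works)) works <- works$works
  x <- as.numeric(works)
  if (length(x) < 3L) stop("need >= 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero variance: skewness undefined")
  mean((x - m)^3) / m2^1.5
}

# Stephens critical values for the composite normality case
# (mean and variance estimated from the sample)
.ad_critical <- c(`0.1` = 0.631, `0.05` = 0.752, `0.025` = 0.873,
                  `0.01` = 1.035)

#' Anderson-Darling composite normality test
#'
#' Computes the Anderson-Darling statistic against a normal distribution
#' with mean and variance estimated from the sample, applies the Stephens
#' small-sample correction `A*^2 = A^2 (1 + 0.75/n + 2.25/n^2)`, and
#' compares it to the Stephens critical value for the chosen significance
#' level (0.752 at alpha = 0.05). Used as the applicability gate of the
#' Gaussian estimator.
#'
#' @param works numeric vector (n >= 8) or [work_set].
#' @param alpha significance level; one of 0.1, 0.05, 0.025, 0.01.
#' @return an object of class `ad_test` with fields `A2`, `A2_star`,
#'   `critical`, `alpha`, `pass`, `n`.
#' @export
ad_normality_test <- function(works, alpha = 0.05) {
  if (is_work_set(works)) works <- works$works
  x <- sort(as.numeric(works))
  n <- length(x)
  if (n < 8L) stop("need >= 8 values for the Anderson-Darling test")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: all values equal")
  key <- as.character(alpha)
  if (!key %in% names(.ad_critical))
    stop("'alpha' must be one of ",
         paste(names(.ad_critical), collapse = ", "))
  z <- stats::pnorm((x - mean(x)) / s)
  z <- pmin(pmax(z, 1e-15), 1 - 1e-15)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  A2_star <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  structure(list(A2 = A2, A2_star = A2_star,
                 critical = unname(.ad_critical[key]), alpha = alpha,
                 pass = A2_star < .ad_critical[[key]], n = n),
            class = "ad_test")
}

#' @export
print.ad_test <- function(x, ...) {
  cat(sprintf("<ad_test> A^2 = %.4f, A*^2 = %.4f, critical = %.3f (alpha = %g): %s\n",
              x$A2, x$A2_star, x$critical, x$alpha,
              if (x$pass) "normality not rejected" else "normality rejected"))
  invisible(x)
}

#' Bootstrap 95% confidence-interval half-width of an estimator
#'
#' Percentile bootstrap with independent per-direction resampling at the
#' original sample size: each replicate resamples the work values with
#' replacement, re-runs the estimator, and the half-width is
#' `(q_97.5 - q_2.5) / 2` of the replicate estimates. Deterministic given
#' `seed`.
#'
#' @param estimator a function of one [work_set] (unidirectional) or of a
#'   forward and reverse [work_set] (bidirectional) returning an
#'   [fe_estimate] or a number.
#' @param forward [work_set] (or the single work set for unidirectional
#'   estimators).
#' @param reverse optional reverse [work_set] for bidirectional estimators.
#' @param n_boot number of bootstrap replicates (>= 1000 recommended;
#'   default 10000).
#' @param seed optional integer seed.
#' @param max_fail_frac maximum tolerated fraction of failed replicates.
#' @return an object of class `boot_ci` with fields `halfwidth`, `quantiles`,
#'   `se` (replicate standard deviation), `estimates`, `n_failed`.
#' @export
bootstrap_ci <- function(estimator, forward, reverse = NULL, n_boot = 10000,
                         seed = NULL, max_fail_frac = 0.05) {
  forward <- .as_work_set(forward)
  if (!is.null(reverse)) reverse <- .as_work_set(reverse, "reverse")
  if (n_boot < 1L) stop("'n_boot' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  resample <- function(ws) {
    ws$works <- ws$works[sample.int(length(ws$works), replace = TRUE)]
    ws
  }
  est <- vapply(seq_len(n_boot), function(i) {
    f <- resample(forward)
    val <- tryCatch({
      e <- if (is.null(reverse)) estimator(f)
           else estimator(f, resample(reverse))
      if (inherits(e, "fe_estimate")) e$value else as.numeric(e)
    }, error = function(e) NA_real_)
    val
  }, numeric(1))
  n_failed <- sum(!is.finite(est))
  if (n_failed > max_fail_frac * n_boot)
    stop("estimator failed on ", n_failed, " of ", n_boot,
         " bootstrap resamples (> ", 100 * max_fail_frac, "%)")
  ok <- est[is.finite(est)]
  q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(list(halfwidth = (q[2L] - q[1L]) / 2, quantiles = q,
                 se = stats::sd(ok), estimates = est, n_failed = n_failed),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("<boot_ci> 95%% half-width = %.4f kcal/mol (se = %.4f, %d failed)\n",
              x$halfwidth, x$se, x$n_failed))
  invisible(x)
}

#' Crooks-theorem residuals of a bidirectional work pair
#'
#' The Crooks theorem requires `ln[P_f(W) / P_r(-W)] = beta (W - dG)`. This
#' diagnostic histograms the forward works and the negated reverse works on
#' shared bins, keeps bins with at least `min_count` counts on both sides,
#' and reports per-bin residuals
#' `r_j = ln[P_f(W_j)/P_r(-W_j)] - beta (W_j - dG)` together with the
#' regression slope of the log-ratio against `W` (target: `beta`). The
#' regression is inverse-variance weighted with the Poisson approximation
#' `var(ln ratio_j) ~ 1/n_f,j + 1/n_r,j`, so sparsely populated tail bins do
#' not dominate the slope.
#'
#' @param forward forward [work_set].
#' @param reverse reverse [work_set].
#' @param dG reference dissociation free energy, kcal/mol.
#' @param bins `"fd"` for Freedman-Diaconis binning of the pooled sample
#'   (default), a single number giving a fixed bin width in kcal/mol
#'   (e.g. 2), or a numeric vector of break points.
#' @param min_count minimum per-bin count on each side (default 5).
#' @return an object of class `ct_residuals`: a list with a per-bin
#'   data.frame (`mid`, `count_f`, `count_r`, `log_ratio`, `residual`),
#'   `slope`, `intercept`, `beta`, `dG`.
#' @export
ct_residuals <- function(forward, reverse, dG, bins = "fd", min_count = 5) {
  forward <- .as_work_set(forward, "forward")
  reverse <- .as_work_set(reverse, "reverse")
  .check_same_temperature(forward, reverse)
  b <- .beta(forward$temperature_K)
  x <- forward$works
  y <- -reverse$works
  pooled <- c(x, y)
  rng <- range(pooled)
  if (identical(bins, "fd")) {
    h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    if (h <= 0) h <- diff(rng) / 30
    breaks <- seq(rng[1L] - h, rng[2L] + h, by = h)
  } else if (is.numeric(bins) && length(bins) == 1L) {
    breaks <- seq(floor(rng[1L] / bins) * bins,
                  ceiling(rng[2L] / bins) * bins + bins, by = bins)
  } else if (is.numeric(bins)) {
    breaks <- bins
  } else stop("invalid 'bins'")
  cf <- graphics::hist(x[x >= min(breaks) & x <= max(breaks)],
                       breaks = breaks, plot = FALSE)
  cr <- graphics::hist(y[y >= min(breaks) & y <= max(breaks)],
                       breaks = breaks, plot = FALSE)
  keep <- cf$counts >= min_count & cr$counts >= min_count
  if (sum(keep) < 3L)
    stop("insufficient overlap: fewer than 3 shared bins with >= ",
         min_count, " counts per side")
  width <- diff(breaks)[keep]
  pf <- cf$counts[keep] / (length(x) * width)
  pr <- cr$counts[keep] / (length(y) * width)
  mid <- cf$mids[keep]
  lr <- log(pf / pr)
  resid <- lr - b * (mid - dG)
  wts <- 1 / (1 / cf$counts[keep] + 1 / cr$counts[keep])
  fit <- stats::lm.wfit(cbind(1, mid), lr, wts)
  structure(list(table = data.frame(mid = mid, count_f = cf$counts[keep],
                                    count_r = cr$counts[keep],
                                    log_ratio = lr, residual = resid),
                 slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 beta = b, dG = dG),
            class = "ct_residuals")
}

#' @export
print.ct_residuals <- function(x, ...) {
  cat(sprintf("<ct_residuals> %d shared bins, slope = %.4f (beta = %.4f), mean residual = %.4f\n",
              nrow(x$table), x$slope, x$beta, mean(x$table$residual)))
  invisible(x)
}
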