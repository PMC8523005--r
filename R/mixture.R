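# One-dimensional Gaussian-mixture fit (EM) and the Crooks-theorem
# mixture free-energy estimator built on it.

#' Fit a one-dimensional Gaussian mixture by expectation-maximization
#'
#' Standard 1-D EM with maximum-likelihood (1/n) variances. Initial means are
#' placed at evenly spaced sample quantiles with random jitter, the best of
#' `restarts` initializations by log-likelihood is kept, and components whose
#' variance collapses below `var_floor` abort the restart. Two components are
#' the practical maximum for 50-work ensembles; the fit becomes ill-defined
#' beyond that.
#'
#' @param works numeric vector of work values (or a [work_set]).
#' @param n_g number of components (>= 1); require `n >= 5 n_g`.
#' @param seed optional integer seed making the fit deterministic.
#' @param restarts number of random initializations.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per restart.
#' @param var_floor minimum allowed component variance (kcal^2/mol^2).
#' @return an object of class `gmix_fit` with fields `weights`, `means`,
#'   `variances`, `loglik`, `converged`, `n_g`, `n`.
#' @export
#' @examples
#' x <- c(rnorm(300), rnorm(300, 8))
#' fit_mixture_em(x, n_g = 2, seed = 1)
fit_mixture_em <- function(works, n_g = 2, seed = NULL, restarts = 20,
                           tol = 1e-10, max_iter = 500, var_floor = 1e-6) {
  if (is_work_set(works)) works <- works$works
  x <- as.numeric(works)
  n <- length(x)
  if (n_g < 1L) stop("'n_g' must be >= 1")
  if (n < 5L * n_g) stop("need n >= 5 * n_g work values (n = ", n, ")")
  if (!is.null(seed)) set.seed(seed)
  if (n_g == 1L) {
    mu <- mean(x)
    s2 <- max(mean((x - mu)^2), var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
    return(.gmix_fit(1, mu, s2, ll, TRUE, n))
  }
  sdx <- stats::sd(x)
  if (sdx == 0) stop("degenerate sample: zero variance")
  qmeans <- stats::quantile(x, probs = (seq_len(n_g) - 0.5) / n_g,
                            names = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- qmeans + stats::rnorm(n_g, 0, sdx / (2 * n_g))
    s2 <- rep((sdx / n_g)^2, n_g)
    w <- rep(1 / n_g, n_g)
    ll_old <- -Inf
    converged <- FALSE
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      lw <- vapply(seq_len(n_g), function(k)
        log(w[k]) + stats::dnorm(x, mu[k], sqrt(s2[k]), log = TRUE),
        numeric(n))
      rls <- .row_logsumexp(lw)
      resp <- exp(lw - rls)
      ll <- sum(rls)
      nk <- colSums(resp)
      if (any(nk < 1e-10)) { degenerate <- TRUE; break }
      w <- nk / n
      mu <- colSums(resp * x) / nk
      s2 <- vapply(seq_len(n_g), function(k)
        sum(resp[, k] * (x - mu[k])^2) / nk[k], numeric(1))
      if (any(s2 < var_floor)) { degenerate <- TRUE; break }
      if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    if (degenerate) next
    if (is.null(best) || ll > best$loglik)
      best <- .gmix_fit(w, mu, s2, ll, converged, n)
  }
  if (is.null(best))
    stop("all ", restarts, " EM restarts collapsed below the variance floor")
  # sort components by mean for stable reporting
  o <- order(best$means)
  best$weights <- best$weights[o]
  best$means <- best$means[o]
  best$variances <- best$variances[o]
  best
}

.gmix_fit <- function(weights, means, variances, loglik, converged, n) {
  structure(list(weights = as.numeric(weights), means = as.numeric(means),
                 variances = as.numeric(variances), loglik = loglik,
                 converged = converged, n_g = length(means), n = n),
            class = "gmix_fit")
}

#' Construct a Gaussian-mixture fit from known parameters
#'
#' Useful to evaluate the mixture free-energy estimator on moments obtained
#' elsewhere (e.g. the sample mean and unbiased variance for a one-component
#' "fit").
#'
#' @param weights positive weights summing to 1.
#' @param means component means, kcal/mol.
#' @param variances component variances, kcal^2/mol^2.
#' @return a `gmix_fit` object.
#' @export
gmix_fit <- function(weights, means, variances) {
  stopifnot(length(weights) == length(means),
            length(means) == length(variances))
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(variances <= 0)) stop("variances must be positive")
  .gmix_fit(weights, means, variances, NA_real_, NA, NA_integer_)
}

#' @export
print.gmix_fit <- function(x, ...) {
  cat(sprintf("<gmix_fit> %d component(s), n = %s, loglik = %s\n", x$n_g,
              format(x$n), format(x$loglik)))
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  invisible(x)
}

#' Crooks-theorem free energy from a Gaussian-mixture work distribution
#'
#' If the forward work distribution is a mixture
#' `P(W) = sum_i c_i n(mu_i, sigma_i^2)`, the Crooks theorem gives the free
#' energy in closed form:
#' `dG = -RT ln[ sum_i c_i exp(-beta (mu_i - beta sigma_i^2 / 2)) ]`,
#' evaluated here in log space. With one component this reduces exactly to
#' the Gaussian estimator `mu - beta sigma^2 / 2`.
#'
#' @param fit a `gmix_fit` (from [fit_mixture_em()] or [gmix_fit()]).
#' @param temperature_K temperature in kelvin.
#' @return an [fe_estimate] with `method = "EM"`, in the direction of the
#'   fitted works.
#' @export
mixture_free_energy <- function(fit, temperature_K = 298.15) {
  stopifnot(inherits(fit, "gmix_fit"))
  b <- .beta(temperature_K)
  lterms <- log(fit$weights) - b * (fit$means - b * fit$variances / 2)
  val <- -.logsumexp(lterms) / b
  fe_estimate("EM", val, n = fit$n, temperature_K = temperature_K,
              notes = sprintf("%d-component mixture", fit$n_g))
}
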