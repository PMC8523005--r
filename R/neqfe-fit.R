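#' Fit free-energy estimators to nonequilibrium work ensembles
#'
#' The central entry point of the package. Given a forward (A to B,
#' dissociation) work ensemble and optionally a reverse (B to A) one, it runs
#' the requested estimators, attaches bootstrap 95% confidence intervals,
#' gates the Gaussian estimators with the Anderson-Darling normality test,
#' and collects the shape diagnostics (skewness, dissipation against the BAR
#' value when available). All estimates are stored on the dissociation
#' convention; `summary()` and the reporting layer can flip to the binding
#' convention.
#'
#' @param forward forward [work_set] (or numeric vector of forward works).
#' @param reverse optional reverse [work_set]; required by the bidirectional
#'   estimators (`"bar"`, `"jarzynski_mean"`).
#' @param estimators subset of `c("bar", "jarzynski", "gaussian",
#'   "jarzynski_mean", "em")`. Unidirectional estimators are applied to each
#'   supplied direction.
#' @param n_g mixture components of the EM estimator.
#' @param ad_alpha significance level of the Anderson-Darling gate.
#' @param n_boot bootstrap replicates per confidence interval (0 disables
#'   bootstrapping).
#' @param seed optional integer seed driving all resampling.
#' @param em_restarts EM restarts (see [fit_mixture_em()]).
#' @return an object of class `neqfe`: a list with `estimates` (named list of
#'   [fe_estimate]s, names like `"BAR"`, `"Jarzynski.forward"`),
#'   `diagnostics`, the input work sets and the call. Methods: `print`,
#'   `summary`, `coef`, `confint`, `plot`, `simulate`, `residuals`.
#' @export
#' @examples
#' p <- sample_gaussian_pair(dG = 10, sigma = 2, n = 50, seed = 7)
#' fit <- neqfe(p$forward, p$reverse, n_boot = 200, seed = 1)
#' fit
#' coef(fit)
neqfe <- function(forward, reverse = NULL,
                  estimators = c("bar", "jarzynski", "gaussian",
                                 "jarzynski_mean", "em"),
                  n_g = 2, ad_alpha = 0.05, n_boot = 1000, seed = NULL,
                  em_restarts = 20) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  forward <- .as_work_set(forward, "forward")
  if (!is.null(reverse)) {
    reverse <- .as_work_set(reverse, "reverse")
    .check_same_temperature(forward, reverse)
  }
  directions <- c(list(forward = forward),
                  if (!is.null(reverse)) list(reverse = reverse))
  temperature_K <- forward$temperature_K

  est <- list()
  boots <- list()
  next_seed <- if (is.null(seed)) function() NULL else local({
    k <- 0L
    function() { k <<- k + 1L; seed + 1000L * k }
  })
  add <- function(name, e, fun, uni_ws = NULL) {
    if (n_boot > 0) {
      bc <- tryCatch({
        if (is.null(uni_ws))
          bootstrap_ci(fun, forward, reverse, n_boot = n_boot,
                       seed = next_seed())
        else bootstrap_ci(fun, uni_ws, n_boot = n_boot, seed = next_seed())
      }, error = function(err) NULL)
      if (!is.null(bc)) {
        e$ci95 <- bc$halfwidth
        boots[[name]] <<- bc
      }
    }
    est[[name]] <<- e
  }

  failed <- function(method, err, convention = "dissociation")
    fe_estimate(method, NA_real_, applicable = FALSE,
                convention = convention, temperature_K = temperature_K,
                notes = paste("estimator failed:", conditionMessage(err)))

  if ("bar" %in% estimators && !is.null(reverse)) {
    e <- tryCatch(bar_estimate(forward, reverse), error = function(err) err)
    if (inherits(e, "error")) est[["BAR"]] <- failed("BAR", e)
    else add("BAR", e, bar_estimate)
  }
  if ("jarzynski_mean" %in% estimators && !is.null(reverse))
    add("JarzynskiMean", jarzynski_mean(forward, reverse), jarzynski_mean)
  for (dn in names(directions)) {
    ws <- directions[[dn]]
    if ("jarzynski" %in% estimators)
      add(paste0("Jarzynski.", dn), jarzynski_estimate(ws),
          jarzynski_estimate, uni_ws = ws)
    if ("gaussian" %in% estimators && length(ws$works) >= 3L)
      add(paste0("Gaussian.", dn),
          gaussian_estimate(ws, gate = "ad", alpha = ad_alpha),
          function(w) gaussian_estimate(w, gate = "none"), uni_ws = ws)
    if ("em" %in% estimators && length(ws$works) >= 5L * n_g) {
      em_seed <- next_seed()
      fit <- tryCatch(fit_mixture_em(ws$works, n_g = n_g, seed = em_seed,
                                     restarts = em_restarts),
                      error = function(err) err)
      if (inherits(fit, "error")) {
        est[[paste0("EM.", dn)]] <- failed(
          "EM", fit, convention = if (ws$direction == "forward")
            "dissociation" else "binding")
      } else {
        e <- mixture_free_energy(fit, temperature_K)
        if (ws$direction == "reverse") e$convention <- "binding"
        # bootstrap replicates use the ambient RNG stream (seeding each
        # replicate's EM would collapse the resampling) and a cheaper EM
        # (fewer restarts, looser tolerance) than the headline fit
        add(paste0("EM.", dn), e,
            function(w) mixture_free_energy(
              fit_mixture_em(w$works, n_g = n_g, restarts = 3L,
                             tol = 1e-6, max_iter = 200L),
              temperature_K),
            uni_ws = ws)
      }
    }
  }
  # normalize every estimate to the dissociation convention
  est <- lapply(est, fe_convention, convention = "dissociation")

  diag <- list()
  for (dn in names(directions)) {
    ws <- directions[[dn]]
    diag[[dn]] <- list(
      n = length(ws$works),
      mean_work = mean(ws$works),
      sd_work = stats::sd(ws$works),
      skewness = if (length(ws$works) >= 3L && stats::sd(ws$works) > 0)
        skewness_mu3(ws$works) else NA_real_,
      ad = if (length(ws$works) >= 8L)
        tryCatch(ad_normality_test(ws$works, alpha = ad_alpha),
                 error = function(e) NULL) else NULL)
  }
  if (!is.null(est$BAR)) {
    for (dn in names(directions))
      diag[[dn]]$dissipation <- dissipation(directions[[dn]],
                                            est$BAR$value)
  }

  structure(list(estimates = est, diagnostics = diag, bootstraps = boots,
                 forward = forward, reverse = reverse,
                 temperature_K = temperature_K, n_boot = n_boot,
                 seed = seed, call = match.call()),
            class = "neqfe")
}

#' Estimates of a fitted `neqfe` object as a data.frame
#'
#' @param object a `neqfe` fit.
#' @param convention sign convention of the `value` column.
#' @return data.frame with columns `method`, `value`, `ci95`, `applicable`.
#' @export
estimates_table <- function(object,
                            convention = c("dissociation", "binding")) {
  convention <- match.arg(convention)
  stopifnot(inherits(object, "neqfe"))
  es <- lapply(object$estimates, fe_convention, convention = convention)
  data.frame(method = names(es),
             value = vapply(es, `[[`, numeric(1), "value"),
             ci95 = vapply(es, `[[`, numeric(1), "ci95"),
             applicable = vapply(es, `[[`, logical(1), "applicable"),
             row.names = NULL)
}

#' @export
print.neqfe <- function(x, digits = 3, ...) {
  cat("Nonequilibrium work free-energy fit (dissociation convention)\n")
  cat(sprintf("  forward: n = %d%s, T = %g K\n", length(x$forward$works),
              if (is.null(x$reverse)) " (unidirectional)"
              else sprintf(", reverse: n = %d", length(x$reverse$works)),
              x$temperature_K))
  tab <- estimates_table(x)
  tab$value <- round(tab$value, digits)
  tab$ci95 <- round(tab$ci95, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.neqfe <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "value")
}

#' @export
confint.neqfe <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only the bootstrap 95% interval is stored")
  tab <- estimates_table(object)
  m <- cbind(tab$value - tab$ci95, tab$value + tab$ci95)
  dimnames(m) <- list(tab$method, c("2.5 %", "97.5 %"))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
summary.neqfe <- function(object, ...) {
  structure(list(fit = object, table = estimates_table(object)),
            class = "summary.neqfe")
}

#' @export
print.summary.neqfe <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nDiagnostics:\n")
  for (dn in names(x$fit$diagnostics)) {
    d <- x$fit$diagnostics[[dn]]
    cat(sprintf("  %s: <W> = %.*f, sd = %.*f, skewness = %.*f\n", dn,
                digits, d$mean_work, digits, d$sd_work, digits, d$skewness))
    if (!is.null(d$ad))
      cat(sprintf("    AD A*^2 = %.*f (%s at alpha = %g)\n", digits,
                  d$ad$A2_star, if (d$ad$pass) "pass" else "fail",
                  d$ad$alpha))
    if (!is.null(d$dissipation))
      cat(sprintf("    dissipation vs BAR = %.*f kcal/mol\n", digits,
                  d$dissipation$w_diss))
  }
  invisible(x)
}

#' Mirror work-histogram plot of a bidirectional fit
#'
#' Plots the forward work distribution `P_f(W)` and the negated reverse
#' distribution `P_r(-W)`; under the Crooks theorem the two cross at the
#' free energy, marked by the BAR estimate when present.
#'
#' @param x a `neqfe` fit with both directions.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.neqfe <- function(x, breaks = "FD", ...) {
  if (is.null(x$reverse))
    stop("mirror plot needs both directions")
  wf <- x$forward$works
  wr <- -x$reverse$works
  hf <- graphics::hist(wf, breaks = breaks, plot = FALSE)
  hr <- graphics::hist(wr, breaks = breaks, plot = FALSE)
  xlim <- range(hf$breaks, hr$breaks)
  ylim <- c(0, max(hf$density, hr$density))
  graphics::plot(hf$mids, hf$density, type = "s", col = "black",
                 xlim = xlim, ylim = ylim, xlab = "W (kcal/mol)",
                 ylab = "density",
                 main = "Forward P_f(W) and reverse P_r(-W)", ...)
  graphics::lines(hr$mids, hr$density, type = "s", col = "red")
  if (!is.null(x$estimates$BAR))
    graphics::abline(v = x$estimates$BAR$value, lty = 2)
  graphics::legend("topright", legend = c("forward", "reverse (negated)"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate Crooks-consistent work pairs from a fitted object
#'
#' Draws new forward/reverse work ensembles from the Gaussian pair implied
#' by the fitted BAR free energy and the pooled work standard deviation —
#' a parametric bootstrap of the experiment at the fitted operating point.
#'
#' @param object a `neqfe` fit with a BAR estimate.
#' @param nsim number of simulated pairs.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` lists, each with `forward` and `reverse`
#'   [work_set]s of the original sizes.
#' @export
simulate.neqfe <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$estimates$BAR))
    stop("simulate() needs a BAR estimate (bidirectional fit)")
  if (!is.null(seed)) set.seed(seed)
  dG <- object$estimates$BAR$value
  sigma <- mean(c(stats::sd(object$forward$works),
                  stats::sd(object$reverse$works)))
  nf <- length(object$forward$works)
  nr <- length(object$reverse$works)
  lapply(seq_len(nsim), function(i) {
    p <- sample_gaussian_pair(dG, sigma, max(nf, nr),
                              temperature_K = object$temperature_K)
    p$forward$works <- p$forward$works[seq_len(nf)]
    p$reverse$works <- p$reverse$works[seq_len(nr)]
    p[c("forward", "reverse")]
  })
}

#' Crooks-theorem residuals of a bidirectional fit
#'
#' @param object a `neqfe` fit with both directions and a BAR estimate.
#' @param bins binning rule passed to [ct_residuals()].
#' @param min_count minimum per-bin count.
#' @param ... unused.
#' @return a [ct_residuals] object.
#' @export
residuals.neqfe <- function(object, bins = "fd", min_count = 5, ...) {
  if (is.null(object$reverse) || is.null(object$estimates$BAR))
    stop("residuals need a bidirectional fit with a BAR estimate")
  ct_residuals(object$forward, object$reverse, object$estimates$BAR$value,
               bins = bins, min_count = min_count)
}
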