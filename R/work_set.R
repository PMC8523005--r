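#' Tagged ensemble of nonequilibrium work values
#'
#' A `work_set` is the currency of the package: a set of work values (kcal/mol)
#' from repeated nonequilibrium switching trajectories in one direction
#' (`"forward"` = A to B, bound ligand decoupled; `"reverse"` = B to A,
#' restrained decoupled ligand recoupled), annotated with the switching time,
#' restraint strength and temperature of the protocol.
#'
#' @param works numeric vector of work values in kcal/mol; non-empty, finite.
#' @param direction `"forward"` (A to B) or `"reverse"` (B to A).
#' @param tau_ns switching time of each trajectory in ns (> 0).
#' @param k_rstr restraint force constant in the equal-K convention
#'   (kcal/mol/A^2, kcal/mol/rad^2, kcal/mol); 0 means no restraint.
#' @param temperature_K temperature in kelvin.
#' @param label free-text label.
#' @return an object of class `work_set`.
#' @export
#' @examples
#' ws <- work_set(rnorm(50, 20, 2), "forward", tau_ns = 2, k_rstr = 10)
#' ws
work_set <- function(works, direction = c("forward", "reverse"), tau_ns = 1,
                     k_rstr = 0, temperature_K = 298.15, label = "") {
  direction <- match.arg(direction)
  works <- as.numeric(works)
  if (length(works) < 1L) stop("'works' must be non-empty")
  if (!all(is.finite(works))) stop("'works' must be finite")
  if (!is.numeric(tau_ns) || length(tau_ns) != 1L || tau_ns <= 0)
    stop("'tau_ns' must be a single positive number")
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      temperature_K <= 0)
    stop("'temperature_K' must be a single positive number")
  if (!is.numeric(k_rstr) || length(k_rstr) != 1L || k_rstr < 0)
    stop("'k_rstr' must be a single non-negative number")
  structure(
    list(works = works, direction = direction, tau_ns = as.numeric(tau_ns),
         k_rstr = as.numeric(k_rstr),
         temperature_K = as.numeric(temperature_K),
         label = as.character(label)),
    class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> %s, n = %d, tau = %g ns, K = %g, T = %g K\n",
              x$direction, length(x$works), x$tau_ns, x$k_rstr,
              x$temperature_K))
  cat(sprintf("  mean W = %.3f kcal/mol, sd = %.3f\n",
              mean(x$works), stats::sd(x$works)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

is_work_set <- function(x) inherits(x, "work_set")

# coerce numeric vectors for convenience in estimator entry points
.as_work_set <- function(x, direction = "forward", temperature_K = 298.15) {
  if (is_work_set(x)) return(x)
  work_set(x, direction = direction, temperature_K = temperature_K)
}

.check_same_temperature <- function(a, b, tol = 1e-6) {
  if (abs(a$temperature_K - b$temperature_K) > tol)
    stop("forward and reverse work sets have different temperatures (",
         a$temperature_K, " vs ", b$temperature_K, " K)")
  invisible(TRUE)
}

#' Method-tagged free-energy estimate
#'
#' Container returned by all estimators. The `convention` field records the
#' sign convention of `value`: `"dissociation"` (A to B, the internal
#' convention of all estimators) or `"binding"`.
#'
#' @param method estimator name, e.g. `"BAR"`, `"Jarzynski"`, `"Gaussian"`,
#'   `"EM"`, `"JarzynskiMean"`, `"Convolution"`, `"ABFE"`.
#' @param value free-energy change in kcal/mol.
#' @param ci95 95% confidence-interval half-width in kcal/mol, or `NA`.
#' @param n number(s) of work values used.
#' @param applicable logical applicability flag (e.g. the Anderson-Darling
#'   gate of the Gaussian estimator); the value is still reported when
#'   `FALSE`, mirroring "n/a" entries of restrained unidirectional analyses.
#' @param convention `"dissociation"` or `"binding"`.
#' @param temperature_K temperature in kelvin, or `NA`.
#' @param notes free text.
#' @return an object of class `fe_estimate`.
#' @export
fe_estimate <- function(method, value, ci95 = NA_real_, n = NA_integer_,
                        applicable = TRUE,
                        convention = c("dissociation", "binding"),
                        temperature_K = NA_real_, notes = "") {
  convention <- match.arg(convention)
  if (!is.na(ci95) && ci95 < 0) stop("'ci95' must be >= 0")
  if (isTRUE(applicable) && !is.finite(value))
    stop("'value' must be finite when applicable")
  structure(
    list(method = method, value = as.numeric(value), ci95 = as.numeric(ci95),
         n = n, applicable = isTRUE(applicable), convention = convention,
         temperature_K = temperature_K, notes = as.character(notes)),
    class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci95)) "" else sprintf(" +/- %.2f", x$ci95)
  flag <- if (x$applicable) "" else " [not applicable]"
  cat(sprintf("<fe_estimate> %s: %.3f%s kcal/mol (%s)%s\n",
              x$method, x$value, ci, x$convention, flag))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.fe_estimate <- function(x, ...) x$value

#' Convert a free-energy estimate between sign conventions
#'
#' @param x an [fe_estimate].
#' @param convention target convention.
#' @return the estimate with `value` sign-flipped if needed.
#' @export
fe_convention <- function(x, convention = c("binding", "dissociation")) {
  convention <- match.arg(convention)
  stopifnot(inherits(x, "fe_estimate"))
  if (x$convention != convention) {
    x$value <- -x$value
    x$convention <- convention
  }
  x
}
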