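# Standard-state and restraint corrections turning a raw alchemical free
# energy into an absolute binding free energy (ABFE).

#' Boresch restraint geometry
#'
#' The six-coordinate host-guest restraint (one distance, two bending angles,
#' three dihedrals) with all force constants equal: `k_rstr` in kcal/mol/A^2
#' for the stretch, kcal/mol/rad^2 for the bends and kcal/mol for the
#' torsions. The analytic standard-state correction depends only on the
#' equilibrium distance `d1` and the two bending angles; it is independent of
#' the dihedral equilibrium values and singular when a bending angle reaches
#' 0 or pi.
#'
#' @param d1_A equilibrium host-guest restraint distance in angstroms (> 0).
#' @param theta2,theta3 equilibrium bending angles, strictly inside (0, pi)
#'   (radians unless `degrees = TRUE`).
#' @param k_rstr common force constant (> 0).
#' @param temperature_K temperature in kelvin.
#' @param degrees if `TRUE`, `theta2`/`theta3` are given in degrees.
#' @return an object of class `restraint_geometry`.
#' @export
restraint_geometry <- function(d1_A, theta2, theta3, k_rstr,
                               temperature_K = 298.15, degrees = FALSE) {
  if (degrees) {
    theta2 <- theta2 * pi / 180
    theta3 <- theta3 * pi / 180
  }
  if (!is.numeric(d1_A) || d1_A <= 0) stop("'d1_A' must be > 0")
  if (theta2 <= 0 || theta2 >= pi || theta3 <= 0 || theta3 >= pi)
    stop("bending angles must lie strictly inside (0, pi): the analytic ",
         "correction is singular at 0 and pi")
  if (!is.numeric(k_rstr) || k_rstr <= 0) stop("'k_rstr' must be > 0")
  structure(list(d1_A = d1_A, theta2 = theta2, theta3 = theta3,
                 k_rstr = k_rstr, temperature_K = temperature_K),
            class = "restraint_geometry")
}

#' Analytic standard-state correction of a Boresch restraint
#'
#' For six equal force constants the correction is
#' `dA_r = RT [ ln(V0 / (pi (RT)^3)) - ln(d1^2 sin(theta2) sin(theta3))
#'            + 3 ln(k_rstr) ]`
#' with `V0 = 1661` cubic angstroms. It obeys the exact scaling
#' `dA_r(K2) - dA_r(K1) = 3 RT ln(K2/K1)` for any geometry.
#'
#' @param geometry a [restraint_geometry].
#' @return correction in kcal/mol (added to the binding-convention free
#'   energy in the assembly step).
#' @export
#' @examples
#' g <- restraint_geometry(d1_A = 5, theta2 = pi / 2, theta3 = pi / 2,
#'                         k_rstr = 10)
#' boresch_correction(g)
boresch_correction <- function(geometry) {
  stopifnot(inherits(geometry, "restraint_geometry"))
  g <- geometry
  rt <- rt_kcal(g$temperature_K)
  rt * (log(.V0_A3 / (pi * rt^3)) -
          log(g$d1_A^2 * sin(g$theta2) * sin(g$theta3)) +
          3 * log(g$k_rstr))
}

#' Binding-site volume correction
#'
#' `dG_vol = RT ln(V0 / V_site)` with `V0 = 1661` cubic angstroms: the
#' standard-state correction for an unrestrained (or weakly restrained)
#' decoupled ligand, applicable whenever the restraint allowance volume is
#' much larger than the binding-site volume — including the limit where the
#' only "restraint" is the periodic box.
#'
#' @param v_site binding-site translational volume in cubic angstroms (> 0),
#'   e.g. from [site_volume_estimate()].
#' @param temperature_K temperature in kelvin.
#' @return correction in kcal/mol.
#' @export
volume_correction <- function(v_site, temperature_K = 298.15) {
  if (!is.numeric(v_site) || any(v_site <= 0)) stop("'v_site' must be > 0")
  rt_kcal(temperature_K) * log(.V0_A3 / v_site)
}

#' Binding-site volume from COM-COM displacement samples
#'
#' Estimates the translational volume explored by the bound ligand from
#' host-guest center-of-mass displacement samples taken in the fully coupled
#' unrestrained state. The default fits an isotropic 3-D Gaussian to the
#' centered displacements and reports `V_site = (2 pi sigma^2)^{3/2}`; the
#' alternative reports the sphere of the 95th-percentile radius.
#'
#' @param displacements n x 3 numeric matrix of COM-COM displacement vectors
#'   in angstroms (n >= 30).
#' @param method `"gaussian"` (default) or `"spherical"`.
#' @return a list with `v_site` (cubic angstroms), `method`, and the fitted
#'   scale (`sigma2` or `r_eff`).
#' @export
site_volume_estimate <- function(displacements,
                                 method = c("gaussian", "spherical")) {
  method <- match.arg(method)
  m <- as.matrix(displacements)
  if (ncol(m) != 3L) stop("'displacements' must have 3 columns")
  n <- nrow(m)
  if (n < 30L) stop("need >= 30 displacement samples")
  centered <- sweep(m, 2L, colMeans(m))
  if (method == "gaussian") {
    sigma2 <- sum(centered^2) / (3 * (n - 1))
    if (sigma2 < .Machine$double.eps)
      stop("degenerate displacement sample: zero variance")
    list(v_site = (2 * pi * sigma2)^(3 / 2), method = method,
         sigma2 = sigma2)
  } else {
    r <- sqrt(rowSums(centered^2))
    r_eff <- stats::quantile(r, 0.95, names = FALSE)
    if (r_eff < .Machine$double.eps)
      stop("degenerate displacement sample: zero spread")
    list(v_site = 4 / 3 * pi * r_eff^3, method = method, r_eff = r_eff)
  }
}

#' Pose-symmetry entropy correction
#'
#' When a restraint pins the decoupled ligand to one of `n_poses`
#' symmetry-equivalent binding poses that are all accessible in the
#' unrestrained coupled state, the restrained leg misses an entropy
#' `T dS = RT ln(n_poses)` (1.64 kcal/mol for the 16 equivalent
#' glycoluril-moiety poses of a cucurbit[8]uril host at 298.15 K).
#'
#' @param n_poses number of symmetry-equivalent poses (integer >= 1).
#' @param temperature_K temperature in kelvin.
#' @return correction in kcal/mol.
#' @export
symmetry_entropy <- function(n_poses, temperature_K = 298.15) {
  if (!is.numeric(n_poses) || length(n_poses) != 1L || n_poses < 1 ||
      n_poses != round(n_poses))
    stop("'n_poses' must be a single integer >= 1")
  rt_kcal(temperature_K) * log(n_poses)
}

#' Bundle of ABFE corrections
#'
#' Collects the correction terms appropriate to one protocol: a
#' Boresch-restrained bidirectional leg uses `dAr` (plus optionally
#' `TdS_sym`); an unrestrained unidirectional leg uses `dG_vol` (the two are
#' mutually exclusive for the same leg).
#'
#' @param dAr analytic Boresch restraint correction, kcal/mol, or `NULL`.
#' @param dG_vol binding-site volume correction, kcal/mol, or `NULL`.
#' @param TdS_sym pose-symmetry entropy term, kcal/mol, or `NULL`.
#' @param v_site,v_rstr optional bookkeeping volumes in cubic angstroms.
#' @return an object of class `correction_set`.
#' @export
correction_set <- function(dAr = NULL, dG_vol = NULL, TdS_sym = NULL,
                           v_site = NULL, v_rstr = NULL) {
  for (v in list(dAr, dG_vol, TdS_sym))
    if (!is.null(v) && !is.finite(v)) stop("correction terms must be finite")
  structure(list(dAr = dAr, dG_vol = dG_vol, TdS_sym = TdS_sym,
                 v0 = .V0_A3, v_site = v_site, v_rstr = v_rstr),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat("<correction_set> (kcal/mol)\n")
  for (nm in c("dAr", "dG_vol", "TdS_sym"))
    if (!is.null(x[[nm]])) cat(sprintf("  %s = %.3f\n", nm, x[[nm]]))
  invisible(x)
}

#' Assemble an absolute binding free energy
#'
#' Adds the present correction terms to the raw alchemical estimate on the
#' binding convention: `ABFE = dG_raw + dA_r + T dS_sym + dG_vol` (each term
#' only if present). Corrections are treated as exact constants, so the
#' confidence interval of the raw estimate is propagated unchanged.
#' Supplying both `dAr` and `dG_vol` for the same leg is a configuration
#' error.
#'
#' @param raw an [fe_estimate] (any convention; converted internally) or a
#'   single number taken to be in the binding convention.
#' @param corrections a [correction_set].
#' @param convention convention of the returned estimate.
#' @return an [fe_estimate] with `method = "ABFE(<raw method>)"`.
#' @export
#' @examples
#' assemble_abfe(-18.65, correction_set(dAr = 7.52)) # Boresch-restrained BAR
assemble_abfe <- function(raw, corrections,
                          convention = c("binding", "dissociation")) {
  convention <- match.arg(convention)
  stopifnot(inherits(corrections, "correction_set"))
  if (!is.null(corrections$dAr) && !is.null(corrections$dG_vol))
    stop("configuration error: the restraint correction (dAr) and the ",
         "site-volume correction (dG_vol) apply to mutually exclusive ",
         "protocols for the same leg")
  if (is.numeric(raw) && length(raw) == 1L)
    raw <- fe_estimate("raw", raw, convention = "binding")
  stopifnot(inherits(raw, "fe_estimate"))
  rb <- fe_convention(raw, "binding")
  total <- rb$value +
    sum(unlist(corrections[c("dAr", "dG_vol", "TdS_sym")]))
  out <- fe_estimate(paste0("ABFE(", raw$method, ")"), total,
                     ci95 = rb$ci95, n = rb$n, applicable = rb$applicable,
                     convention = "binding",
                     temperature_K = rb$temperature_K,
                     notes = "corrections treated as exact constants")
  fe_convention(out, convention)
}
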