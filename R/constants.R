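# Physical constants. Internal energy unit is kcal/mol throughout.
.R_KCAL <- 1.98720425864083e-3 # gas constant, kcal/mol/K
.KJ_PER_KCAL <- 4.184          # thermochemical calorie, exact
.AVOGADRO <- 6.02214076e23     # mol^-1, exact (SI 2019)
.V0_A3 <- 1661                 # standard-state volume per molecule at 1 M, A^3
                               # (conventional rounded value used in restraint
                               # corrections; see standard_state_volume())

#' Thermal energy RT in kcal/mol
#'
#' @param temperature_K temperature in kelvin.
#' @return RT in kcal/mol (0.5925 at 298.15 K).
#' @export
#' @examples
#' rt_kcal(298.15)
rt_kcal <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  .R_KCAL * temperature_K
}

#' Standard-state volume per molecule
#'
#' Volume available to one solute molecule at the given molar concentration,
#' computed from Avogadro's number: 1660.5 cubic angstroms at 1 M. The
#' restraint and binding-site-volume corrections use the conventional rounded
#' value 1661.
#'
#' @param conc_M reference concentration in mol/L (default 1, the standard
#'   state).
#' @return volume in cubic angstroms.
#' @export
#' @examples
#' standard_state_volume() # 1660.539
standard_state_volume <- function(conc_M = 1) {
  stopifnot(is.numeric(conc_M), conc_M > 0)
  1e27 / (.AVOGADRO * conc_M)
}

# inverse temperature in mol/kcal
.beta <- function(temperature_K) 1 / rt_kcal(temperature_K)

# convert kJ/mol -> kcal/mol
.kj_to_kcal <- function(x) x / .KJ_PER_KCAL

# numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log(sum(exp())) of a matrix, vectorized
.row_logsumexp <- function(lw) {
  m <- lw[cbind(seq_len(nrow(lw)), max.col(lw, ties.method = "first"))]
  m + log(rowSums(exp(lw - m)))
}
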