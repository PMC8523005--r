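---
title: "Estimating binding free energies from nonequilibrium work: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating binding free energies from nonequilibrium work: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqfe)
```

## The problem

Alchemical nonequilibrium switching estimates the absolute binding free
energy (ABFE) of a host–guest complex from repeated fast transformations
between a coupled state A and a decoupled state B. Each trajectory records
the work of driving the coupling parameter $\lambda$,
$W = \pm\int_0^1 (\partial H/\partial\lambda)\, d\lambda$, and the
double-system/single-box variant runs the bound-ligand decoupling and the
bulk-ligand recoupling simultaneously, so one work value per trajectory
summarizes the whole exchange. When the decoupled bound ligand is held by a
six-coordinate (Boresch-style) restraint, the restraint work is part of
$W$ and its standard-state cost must be removed analytically afterwards.

The forward and reverse work distributions are tied together by the Crooks
fluctuation theorem,
$$\frac{P_f(W)}{P_r(-W)} = e^{\beta (W - \Delta G)},$$
which is the organizing identity of this package: estimators are exact to
the extent that they respect it, the synthetic generators enforce it
analytically, and the `ct_residuals()` diagnostic measures how far a data
pair deviates from it.

Throughout, energies are kcal/mol, $R = 1.98720425864083\times10^{-3}$
kcal/mol/K, the default temperature is 298.15 K
(RT $\approx 0.5925$ kcal/mol), and all estimators return the A$\to$B
*dissociation* free energy; the reporting layer flips to the binding
convention. The fixed sign convention avoids the single most common source
of confusion when bidirectional tables mix conventions.

## Estimators

**BAR.** `bar_estimate()` solves the Bennett self-consistent equation
$$\sum_f \frac{1}{1+e^{\,M+\beta(W_f-\Delta G)}} =
  \sum_r \frac{1}{1+e^{\,-M+\beta(W_r+\Delta G)}},\qquad
  M=\ln(n_f/n_r),$$
equivalent to the maximum-likelihood crossing point of $P_f(W)$ and
$P_r(-W)$. The root is bracketed in
$[\min(-W_r)-50\,RT,\ \max(W_f)+50\,RT]$ and solved to $10^{-8}$ kcal/mol
(bisection/interpolation, then Newton polishing on the smooth score). If
the bracket endpoints do not straddle a sign change — possible only for
pathological, non-overlapping inputs — the estimator raises a diagnostic
error rather than returning a number. The test suite cross-checks the
solution against an independent maximization of the Bennett log-likelihood.

**Jarzynski.** $\Delta G = -RT\ln\langle e^{-\beta W}\rangle$, computed by
log-sum-exp. The estimator is consistent but, at small $n$ and dissipation
above a few RT, systematically overestimates the free-energy change in its
own direction because the rare low-work trajectories that dominate the
exponential average go unsampled. The package treats this bias as a
first-class property: it is asserted (positively) in the test suite at
$n = 50$ and $\beta\sigma^2 \approx 11$.

**Gaussian.** $\Delta G = \langle W\rangle - \tfrac{1}{2}\beta\sigma^2$
with the unbiased sample variance: exact and unbiased for normal work only.
Because normality is the entire validity condition, `gaussian_estimate()`
carries an Anderson–Darling gate: the composite-normality statistic with
Stephens' small-sample correction $A^{*2} = A^2(1+0.75/n+2.25/n^2)$,
compared against the both-parameters-estimated critical value (0.752 at
$\alpha = 0.05$). A failed gate flags the estimate `applicable = FALSE`
but still reports the value, mirroring how such cells are published as
"n/a". A passed test is, of course, no proof of normality — the mirror
of the reverse distribution can still be visibly asymmetric — which is why
the skewness diagnostic is reported alongside.

**Mean Jarzynski.** With negligible overlap, BAR degenerates towards the
arithmetic mean of the two directional Jarzynski estimates on a common
convention, $\tfrac12[\Delta G_J^{f} - \Delta G_J^{r}]$;
`jarzynski_mean()` implements exactly this mean. (An alternative reading
of bidirectional summaries defines the combination as a plain difference
of the directional estimates; on published bidirectional tables that
reading produces twice the BAR-scale value, so the mean-on-common-convention
form is the one implemented.)

**Gaussian-mixture EM.** When work is non-normal but well described by
$P(W) = \sum_i^{n_g} c_i\, n(\mu_i,\sigma_i^2)$, the Crooks theorem gives a
closed-form estimate
$$\Delta G = -RT \ln \Big[\sum_i c_i\, e^{-\beta(\mu_i - \frac{1}{2}\beta
\sigma_i^2)}\Big],$$
evaluated in log space to survive $\beta\mu \gg 1$. The mixture is fitted
by a standard one-dimensional EM (`fit_mixture_em()`): maximum-likelihood
$1/n$ variances, quantile-spread initial means with random jitter, best of
20 restarts, tolerance $10^{-10}$ on the log-likelihood, at most 500
iterations, and a variance floor of $10^{-6}$ kcal²/mol² below which a
restart is declared collapsed (all restarts collapsing is an error — a
real possibility for $n_g = 2$ on 50 resampled works, which is why the
model object records such failures per cell instead of aborting). Two
components are the practical default; with one component the estimator
reduces *algebraically* to the Gaussian formula, an identity the tests
assert exactly. The EM log-likelihood is cross-checked against `mclust`.

**Convolution.** When bound-leg and unbound-leg works are measured
separately, the combined forward distribution is their convolution;
`convolve_unbound_bound()` forms the deterministic full cross-sum
$\{w_b + w_u\}$ ($n_b n_u$ values), which is the empirical convolution
without pairing noise, and returns it as an ordinary work set usable by
any unidirectional estimator.

## Corrections

`boresch_correction()` implements the equal-force-constant analytic
standard-state term
$\Delta A_r = RT[\ln V_0/\pi(RT)^3 - \ln(d_1^2\sin\theta_2\sin\theta_3) +
3\ln K]$ with $V_0 = 1661$ Å$^3$; it is independent of the dihedral
equilibrium values, singular at $\theta_{2,3} \in \{0,\pi\}$ (constructor
rejects such geometries), and obeys
$\Delta A_r(K_2)-\Delta A_r(K_1) = 3RT\ln(K_2/K_1)$ exactly, which makes
published $K$-grids reconstructible from a single value. The tests verify
the formula against direct stiff-spring quadrature of the factorized
six-coordinate configuration integral to better than 0.05 kcal/mol for
$K \ge 20$.

For unrestrained (or weakly restrained, $V_{\mathrm{rstr}} \gg
V_{\mathrm{site}}$) protocols the correction is instead
$\Delta G_{\mathrm{vol}} = RT\ln(V_0/V_{\mathrm{site}})$, with the site
volume estimated from COM–COM displacement samples. Two conventions are
offered because the literature does not fix one: the default isotropic
Gaussian fit $V_{\mathrm{site}} = (2\pi\sigma^2)^{3/2}$, and a spherical
95th-percentile-radius alternative; the method used is recorded in the
result. Restraining a ligand to one of $N$ symmetry-equivalent poses that
are all populated in the unrestrained state additionally misses
$T\Delta S = RT\ln N$ (1.64 kcal/mol for $N=16$ at 298.15 K).

`assemble_abfe()` adds whichever terms are present on the binding
convention. Supplying both $\Delta A_r$ and $\Delta G_{\mathrm{vol}}$ for
one leg is rejected as a configuration error — they correct mutually
exclusive protocols. Corrections are treated as exact constants, so only
the statistical interval of the raw estimate propagates; this matches how
such tables are published, and is the reason the assembled interval equals
the raw one.

The standard-state volume itself is a computable quantity
(`standard_state_volume()`, $10^{27}/N_A = 1660.5$ Å$^3$ at 1 M); the
rounded conventional 1661 is used inside the corrections for consistency
with published tables.

## Diagnostics

*Dissipation* ($\langle W\rangle_F - \Delta G$ forward,
$\langle W\rangle_R + \Delta G$ reverse) is the single best predictor of
unidirectional estimator failure. *$\lambda$-profiles* resolve where along
the switch the mean work and the dissipation-related term $\beta\sigma^2/2$
accumulate. *Skewness* $m_3/m_2^{3/2}$ flags non-normality that a blunt
test may miss. *Bootstrap intervals* (percentile, independent
per-direction resampling at the original size, default
$n_{\mathrm{boot}} = 10^4$, seedable) supply every confidence interval;
the percentile form was chosen because resampling over the work collection
is the published procedure while the interval type is not stated. The
half-width scales as $n^{-1/2}$, verified across a 100-fold $n$ range.

*Crooks residuals* histogram $W_f$ and $-W_r$ on shared bins
(Freedman–Diaconis by default; fixed 2 kcal/mol width available for
coarse published-style histograms), keep bins with at least 5 counts per
side, and report $r_j = \ln[P_f/P_r] - \beta(W_j - \Delta G)$ plus the
regression slope of the log-ratio (target $\beta$). The regression is
inverse-variance weighted using the Poisson approximation
$\mathrm{var}(\ln\mathrm{ratio}) \approx 1/n_{f,j} + 1/n_{r,j}$ so that
sparse tail bins — where the two distributions barely overlap — do not
dominate the slope. Fewer than 3 usable shared bins raises an
insufficient-overlap error.

## Synthetic generators: what they emulate and what they do not

All generators enforce the Crooks theorem *analytically* rather than by
rejection: a Gaussian forward component $n(\mu,\sigma^2)$ maps to a
reverse-work component with mean $-(\mu-\beta\sigma^2)$, unchanged
variance, and weight reweighted by $e^{-\beta(\mu-\beta\sigma^2/2)}$
(renormalized; the normalizer *is* $e^{-\beta\Delta G}$, so the implied
free energy comes out in closed form). This makes consistency exact and
sampling fast, at the price of realism: real work distributions need not
be Gaussian mixtures at all.

`sample_gaussian_pair()` is the minimal CT-exact pair — forward
$N(\Delta G + \beta\sigma^2/2, \sigma^2)$, reverse
$N(-\Delta G + \beta\sigma^2/2, \sigma^2)$. `dssb_scenario()` emulates the
qualitative phenomenology of *restrained* switching with a two-component
forward mixture: a relaxed CT-symmetric baseline (dissipation $d_0$,
variance $2d_0/\beta$) plus a restraint tail shifted up by
$a_K\ln(1+K)/\sqrt{\tau}$ at baseline width. Because the tail keeps the
baseline variance, the Crooks map suppresses it exponentially in reverse —
so forward dissipation grows strongly with $K$ while reverse dissipation
stays near $d_0$, reproducing the characteristic forward/reverse asymmetry
of restrained experiments. The dissipation laws are explicit toys
(logarithmic in $K$, $1/\sqrt{\tau}$ tail decay, mild
$1+b_\tau\ln\tau$ baseline growth): the literature reports trends, not a
functional form, and none of these knobs is physical. Defaults
($\Delta G = 18.6$, $K = 10$, $\tau = 1$ ns, $n = 50$ per direction,
298.15 K) sit at the central operating point of published restrained
host-guest experiments: 50 trajectories per direction is exactly the
desk-scale regime in which estimator pathologies matter. The scenario's
reference crossing point is its closed-form implied $\Delta G$ (returned
as `implied_dG`), which sits slightly above the nominal `dG_alch` knob
because the tail component contributes to the mixture normalizer.

Consequently, passing tests on these generators demonstrates estimator
correctness *under exact CT-consistency with mixture-of-Gaussians shapes*;
they say nothing about force-field adequacy, equilibration of the end
states, or pose metastability in real simulations — failure modes that
enter upstream of the work values.

`synth_dhdl_files()` closes the loop on I/O: it writes GROMACS-style
`.xvg` files (comment/directive headers, optional kJ/mol units, linear
$\lambda(t)$ schedule) whose trapezoidal integral reproduces prescribed
work values exactly at zero noise, so the file-parsing path and the
work-table path can be proven equivalent end to end.

## Numerical choices and degenerate inputs

- Unit conversion is fixed at 1 kcal = 4.184 kJ exactly; xvg energies
  default to kJ/mol (GROMACS convention), internal canonical unit kcal/mol.
- Trapezoidal integration over the $\lambda$ grid; explicit $\lambda$
  column preferred, else a linear schedule from the time column. Duplicate
  time stamps keep the first occurrence with a warning; non-monotone
  $\lambda$ is an error.
- Work tables round-trip at 12 significant digits.
- BAR tolerance $10^{-8}$ kcal/mol; Bennett constant $RT\ln(n_f/n_r)$
  handles unbalanced designs (zero for the usual 50/50).
- Degenerate inputs error early and specifically: empty work sets,
  all-equal samples for the AD test or skewness, zero-variance
  displacement clouds, fewer than 3 works for a variance, fewer than
  $5 n_g$ works for an EM fit.
- Bootstrap failure of more than 5% of replicates is an error in
  `bootstrap_ci()`; inside the model object it degrades to an `NA`
  interval with a note, because a fragile mixture bootstrap should not
  destroy the BAR column next to it.

## Problem sizes used in the checks

The statistical validation uses sizes chosen to make each property
resolvable at desk scale: 50 works per side (the published operating
point) for recovery-rate and bias properties; $2\times10^4$ trajectories
for Crooks-residual slope checks of the well-overlapped generators and
$5\times10^4$ for the restrained scenario, whose forward/reverse overlap
is deliberately thin so the shared histogram window only populates at
larger $n$; 100 seeded replicates for the BAR recovery rate; 200 for the
Jarzynski bias; 1000 for the Anderson–Darling type-I rate; and bootstrap
half-width scaling averaged over 10 data realizations because a single
50-work draw has a noisy interval width.

## Known limitations

- Single scalar $\lambda$ only: no coul/vdw split bookkeeping, no MBAR
  over intermediate states, no equilibrium-FEP restraint legs.
- The EM estimator is limited to few components by design; beyond
  $n_g = 2$–3 the fit is ill-defined at 50 works.
- The symmetry term assumes countable, equally populated poses; the
  reorganization (strain) energy of a restrained pose that imperfectly
  matches the unrestrained one is not modeled.
- Corrections carry no statistical uncertainty, so assembled intervals
  understate total uncertainty whenever the site-volume estimate is itself
  noisy.
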