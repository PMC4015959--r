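---
title: "Models and methods behind flavochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flavochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavochar)
```

flavochar implements the quantitative analyses used to characterize an
FMN-binding flavoprotein oxidoreductase: flavin-binding thermodynamics from
fluorescence-quenching titrations, midpoint redox potentials from
dye-coupled reductive equilibrations, steady-state and transient kinetics,
and solution oligomeric state from SEC calibration and SAXS mixture
decomposition. Every analysis has a matching synthetic-data generator with
known ground truth, so the whole pipeline is validated by parameter
recovery. This vignette explains each model, its assumptions, the defaults,
and the numerical choices; it also records the design decisions that were
genuinely open.

## Tight-binding titrations

A fixed total concentration of free flavin, $L_{tot}$ = 100 nM, is titrated
with apoprotein $P$; binding quenches the flavin fluorescence. Because
$L_{tot}$ and the dissociation constant are of comparable magnitude
(tens of nM for the wild-type FMN complex), free titrant cannot be
approximated by total titrant; the bound concentration is the exact root of
the single-site mass balance,

$$C = \tfrac{1}{2}\left[(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}\right],$$

and the observed emission is $F = f_{free}(L_{tot} - C) + f_{bound}C$.
`fit_tight_binding()` profiles $K_d$ on a log grid — the two brightness
coefficients enter linearly and are solved exactly at each grid value —
then polishes all three parameters by Levenberg–Marquardt to obtain
asymptotic standard errors. This two-stage scheme is immune to poor
starting values across the whole affinity range (wild-type FMN at 27 nM to
riboflavin at 6.58 µM was the design span). A constant-emission
(quench-free) curve is detected up front and reported as unidentifiable
rather than fitted.

Gibbs energies use $\Delta G_b = RT\ln K_d$ on the 1 M standard state with
$T$ = 298.15 K (25 °C) unless overridden; mutational effects are
$\Delta\Delta G_b = \Delta G_b(\mathrm{mut}) - \Delta G_b(\mathrm{wt})$,
positive for weakened binding. `additivity_check()` reports
$\sum_i \Delta\Delta G_{b,i}$ minus a jointly measured value; a nonzero
discrepancy quantifies cooperativity between spatially close residues
(single-residue contributions need not add). Dilution during titrant
addition is not corrected unless a `dilution_factor` column is supplied —
with it, the per-point flavin total is rescaled. Inner-filter corrections
and multi-site models are out of scope.

The default titration schedule (`titration_design()`) spans 0–1 µM in 12
points with denser sampling below 0.3 µM, where the tight-binding
transition carries the information; this mirrors manual cuvette titration
practice.

## Dye-coupled redox potentiometry

The enzyme-bound flavin couple (midpoint $E_F$, $n_F$ electrons) is
equilibrated against a reference dye ($E_D$, $n_D$) while a
xanthine/xanthine-oxidase system injects electrons. The generator models
this as a *constant-rate influx with instantaneous inter-couple
equilibrium*: at every time the delivered equivalents
$Q = \min(\text{influx}\cdot t,\; n_F F_{tot} + n_D D_{tot})$ are
partitioned by solving (bisection to $10^{-12}$ mV) for the unique solution
potential $E_h$ with

$$\text{fraction reduced}_i = \frac{1}{1 + 10^{\,n_i(E_h - E_i)/\nu}},
\qquad n_F F_{red} + n_D D_{red} = Q .$$

The mediator that enforces this equilibrium in the cuvette is not modelled
explicitly — its only role is to make the equilibrium assumption true.
Semiquinone intermediates and photoreduction artifacts are deliberately not
simulated. Absorbances at the two analysis wavelengths (450 nm for the
flavin band; 610 nm for indigo carmine or 521 nm for phenosafranin) are
extinction-weighted sums over the four species; reduced flavin
(hydroquinone) and leuco-dyes default to zero extinction at these
wavelengths, but full 4 × 2 matrices are accepted.

`deconvolve()` inverts the per-time linear system using the two closure
constraints, rejecting configurations whose 2 × 2 effective matrix has a
condition number above $10^8$, and clips (with a flag) fractions that noise
pushes outside [0, 1]. `equilibration_fit()` then regresses the enzyme
log-ratio on the dye log-ratio. Two conventions matter here:

* **Nernst slope constant.** $\nu$ = 59 mV/decade exactly (not 59.16),
  matching the operational arithmetic this field uses at 25 °C;
  configurable.
* **Plot orientation.** The axes carry $\log_{10}([red]/[ox])$. With this
  orientation the slope is still $n_F/n_D$, and the standard worked
  arithmetic $E_F = E_D + (\nu/n_F)\cdot\text{intercept}$ — e.g.
  $-125 + (59/2)(-0.45) = -138.3$ mV — is exact, because the intercept is
  $n_F(E_F - E_D)/\nu$. With $\log_{10}([ox]/[red])$ axes the intercept's
  sign flips and the same formula would give the wrong sign; we chose the
  orientation under which the published conversion formula is
  self-consistent.

Regression points are restricted to fractions within 0.1–0.9 (configurable):
the variance of a log-ratio explodes as either couple approaches an
endpoint. A slope deviating more than 25% from $n_F/n_D$ raises an
"equilibrium suspect" warning. Dye midpoints ship in `dye_library()`
(indigo carmine −125 mV, phenosafranin −252 mV,
anthraquinone-2-sulfonate −225 mV, all treated as two-electron couples;
the anthraquinone electron count is an assumption, user-overridable).

Default equilibration conditions are 65 µM enzyme flavin with 40 µM dye and
an influx of 6 µM equivalents min⁻¹ sampled every 2.5 min to 40 min, which
reduces the full system in ~35 min — the time scale of the reference
experiment design.

## Steady-state kinetics

Initial velocities come from NADH absorbance slopes at 340 nm via
$\varepsilon_{340}$ = 6.22 mM⁻¹cm⁻¹. `fit_mm()` fits
$v = k_{cat}E_0 S/(K_m + S)$ by unweighted nonlinear least squares — the
source analyses state only "nonlinear regression", so no error model is
presumed; a 1/v² weighting flag exists for rate data with proportional
errors. The specificity constant is reported in mM⁻¹ s⁻¹ (so
$k_{cat}/K_m$ = 11727 for 22 µM and 258 s⁻¹) with a delta-method standard
error.

`fit_pingpong()` globally fits the substituted-enzyme (bi-bi ping-pong)
law $v = k_{cat}E_0AB/(K_aB + K_bA + AB)$ across all (A, B) pairs.
Double-reciprocal plots are *diagnostics only*, never the fitting route:
under ping-pong kinetics the slope of $1/v$ against $1/A$ equals
$K_a/V_{max}$ at every B, so the coefficient of variation of the per-B
slopes (`parallelism_stat`) is ≈ 0; a ternary-complex (sequential) rate
law — available as a negative control in `gen_rates_ternary()` — makes the
lines intersect and the statistic large. The default bisubstrate design is
8 NADH levels (5–400 µM) crossed with flavin at 10, 20, 50 and 100 µM and
18 nM enzyme, the design used for the engineered flavin-reductase variant;
the single-substrate NADH grid (2–500 µM, 10 levels) is a package default
since no source grid is stated.

`kcat_from_specific_activity()` converts µmol min⁻¹ mg⁻¹ into s⁻¹ via the
subunit mass ($k_{cat} = V_{max} M/60000$, one site per subunit). Isotope
and activity ratios propagate standard errors to first order.

A note on reproducing printed tables: published parameter tables round each
entry for display, so a ratio recomputed from *rounded* inputs can differ
from the printed ratio in its last digit or two.
`check_specificity_table()` therefore tests whether the printed
$k_{cat}/K_m$ lies in the interval attainable from inputs within half a
unit of their last printed digits (± one unit in the ratio's own last
digit) — the faithful reading of "internally consistent". Similarly,
`display_round()` rounds half away from zero, the convention used in
hand-reported figures, where `round()`'s round-half-even would disagree
(e.g. 396.5 → 397).

## Transient kinetics

Stopped-flow traces are fitted to
$A(t) = \text{offset} + \text{amplitude}\,e^{-k_{obs}t}$, with starting
values from the tail mean (offset) and a log-linear transform of the
baseline-subtracted signal. Traces are assumed trimmed past the instrument
dead time; an optional `dead_time` shift is applied before fitting. A flat
trace is reported unidentifiable; $k_{obs} t_{max} < 1$ flags
under-sampling; lag-one residual autocorrelation above 0.5 warns that a
second phase may be present (only single exponentials are modelled — the
oxidative half-reaction, complete within the dead time, is out of scope).
The default synthetic trace samples 200 points over eight lifetimes.

The concentration dependence $k_{obs} = k_{max}S/(k_{half} + S)$ is fitted
by direct Levenberg–Marquardt on the residual vector rather than through an
`nls`-style front end: when every concentration sits far above $k_{half}$
the start-point gradient columns are nearly collinear and `nls` machinery
rejects the problem outright, whereas the damped iteration still converges
(and the result is then flagged `k_half_flag`, since half-saturation is
barely identified by such a design). The characteristic values here are a
147.0 s⁻¹ limiting electron-transfer constant with 6.4 µM half-saturation
at 10 °C, probed over 1–5000 µM NADH.

## Oligomeric state

`sec_calibrate()` is ordinary least squares of $\log_{10}$(mass) on elution
volume over marker proteins (albumin 67, ovalbumin 43, chymotrypsinogen A
25, ribonuclease A 13.7 kDa for the analytical column emulated here);
apparent masses queried outside the marker range are flagged as
extrapolated. `subunit_count()` divides by the monomer mass and reports two
decimals — 9.5 mL on the emulated column gives ≈ 40 kDa, i.e. 1.88 subunits
of 21 288 Da, a homodimer.

`fit_mixture()` performs the OLIGOMER-style decomposition of a scattering
curve over supplied component form factors: minimize

$$\chi^2 = \frac{1}{N-K}\sum_j
\left(\frac{I_{exp}(q_j) - c\sum_i w_i I_i(q_j)}{\sigma_j}\right)^2,
\qquad w_i \ge 0,\ \textstyle\sum_i w_i = 1 .$$

The reduced form (divide by $N-K$) follows CRYSOL/OLIGOMER practice. The
problem is linear in $v_i = c\,w_i \ge 0$, and with the small component
counts of oligomer analysis it is solved *exactly* by enumerating active
subsets of a non-negative weighted least-squares problem (no iterative NNLS
approximation); weight standard errors follow from the linear-fit
covariance by the delta method, and near-colinear component sets are
flagged by condition number. Form factors are inputs: computing scattering
from atomic coordinates is out of scope, and the synthetic generator uses
analytic homogeneous-sphere intensities
$I(q) = R^6[3(\sin qR - qR\cos qR)/(qR)^3]^2$ (with a small-$x$ series
below $qR = 0.05$ to avoid cancellation), radii 23 and 29 Å approximating
a ~43 kDa dimer and ~85 kDa tetramer, on the 0.008–0.2 Å⁻¹ grid used after
truncation in the reference measurements. Guinier/P(r) analysis and shape
reconstruction are not goals.

## The synthetic-data module, noise, and what recovery tests show

Every generator is seeded (`sim_config`), bit-reproducible, and attaches
its ground truth to the output. Noise is multiplicative Gaussian on the
signal — the dominant error structure of the photometric instruments these
analyses consume — with an optional absolute floor; no source noise model
is stated, so this is a package choice. SAXS curves additionally report a
per-point σ column (the relative noise level, with a 10⁻⁴ floor so
noiseless curves remain usable in weighted fits).

The generators emulate the statistical *structure* the analyses assume:
exact rate laws, exact Nernstian partitioning, single exponentials,
weighted sums of form factors. They deliberately do not emulate instrument
drift, inner-filter effects, semiquinone formation, enzyme inactivation, or
inter-particle interference. Passing recovery tests therefore demonstrates
that the estimators are correct and well-conditioned under the stated
models at realistic noise — not that real data are free of systematic
deviations from those models.

Problem sizes used throughout the test suite were chosen to keep each
recovery study statistically meaningful at desk scale: 12–15 point
titrations, 17-point equilibrations, 8 × 4 bisubstrate grids, 200-point
traces, 120-point scattering curves, and replicate counts of 12–100 per
study.

## Numerical choices and degenerate inputs

* All nonlinear fits use Levenberg–Marquardt (minpack) with analytic model
  expressions, non-negativity bounds on rate/affinity constants, and
  data-driven starting values; the titration fit adds the log-grid profile
  stage described above.
* The equilibration solver brackets the solution potential 600 mV beyond
  both midpoints and handles the $Q = 0$ and full-capacity endpoints
  (±∞ potential) explicitly.
* Degenerate inputs fail loudly and informatively: quench-free titrations,
  singular extinction matrices (with condition number), < 3 usable Nernst
  points, flat stopped-flow traces, saturated hyperbola designs, duplicate
  form factors.
* Ties in the mixture enumeration cannot occur for generic data; the
  all-zero solution is kept as an explicit fallback for curves with no
  positive projection.

## Known limitations

Single-site binding only; two-couple (no semiquinone) potentiometry only;
single-exponential transients only; the SEC calibration is linear in
log-mass over the marker range; mixture components must be supplied on (or
interpolable onto) the curve's q grid. The dye library treats
anthraquinone-2-sulfonate as a two-electron couple by default. The
`paper_checks()` worked-example mode recomputes only arithmetic whose
inputs are printed values; quantities that require the original raw
instrument data (real-data regression slopes, measured isotope ratios,
experimental SAXS fractions) are validated instead by the synthetic
recovery suites.
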