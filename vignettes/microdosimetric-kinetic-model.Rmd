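---
title: "Methods: the microdosimetric-kinetic survival model in microkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the microdosimetric-kinetic survival model in microkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microkin)
```

## The model and its assumptions

`microkin` predicts clonogenic survival for irradiations whose dose rate
and radiation quality change during delivery. The biological picture is
the microdosimetric-kinetic (MK) one: the nucleus is partitioned into
micrometre-scale domains (1 µm diameter spheres); radiation induces
potentially lethal lesions in proportion to the specific energy each
domain receives; lesions convert to lethal lesions first-order, pairwise
second-order within a domain, or are repaired first-order. With lesion
counts Poisson-distributed across cells, survival is the probability of
zero lethal lesions, so $-\ln S$ equals the mean number of lethal
lesions per nucleus.

Solving the lesion kinetics over a delivery split into $N$ equal
sub-intervals $\Delta T$ with per-interval doses $D_n$ and qualities
$\gamma^*_n$ gives

$$-\ln S=\sum_{n=1}^{N}\left[(\alpha_0+\gamma^*_n\beta_0)D_n+\beta_0
D_n^2\right]+2\beta_0\sum_{n<m}e^{-(m-n)(a+c)\Delta T}D_nD_m .$$

Only three composite cell-line parameters survive in this reduced form:
$\alpha_0$ (Gy⁻¹), $\beta_0$ (Gy⁻²) and the sub-lethal damage repair
rate $(a+c)$ (h⁻¹). The microscopic rates that generate them (lesion
conversion, pairwise interaction, repair, domain count, DNA content) are
not separately identifiable from survival data and are deliberately not
represented as free parameters. Two further assumptions are inherited
from the reduced form: cell-cycle-dependent quantities are constant over
the delivery (appropriate for slowly cycling melanoma lines), and
radiation quality enters only the linear term — $\beta_0$ is
LET-independent, which is the standard MK convention; LET-dependent
$\beta_0$ variants are out of scope.

For constant rate and quality the sum has the closed form
$-\ln S=(\alpha_0+\gamma^*\beta_0)D+\beta_0\,q(T)\,D^2$ with the
Lea–Catcheside-type protraction factor
$q(T)=2[(a+c)T+e^{-(a+c)T}-1]/((a+c)T)^2$, $T=D/\dot D$.

### Radiation quality

Quality is summarised by the saturation-corrected dose-mean lineal
energy $y^*$ of the field,

$$y^*=\frac{y_0^2\int[1-\exp(-y^2/y_0^2)]f(y)\,dy}{\int y f(y)\,dy},$$

the standard Kase-type saturation correction with $y_0=150$ keV/µm;
for low-LET photon spectra $y^*\approx y_D$, while far above $y_0$ the
overkill correction saturates effectiveness per unit dose. The
conversion to the dose-mean specific energy per event is
$\gamma^*=0.1602\,y^*/(\rho\pi r_d^2)$ Gy with $y^*$ in keV/µm, $r_d$
in µm and $\rho$ in g/cm³; the constant 0.1602 is 1.602×10⁻¹⁶ J/keV
expressed per µm³ of unit-density tissue, and is exported as
`KEV_UM_TO_GY`.

### Boron mixing

A boron-loaded neutron field is modelled as two components: a
background (neutrons plus secondary photons) and the ¹⁰B capture
products, whose dose rate is linear in the ¹⁰B concentration because
the capture rate is proportional to the ¹⁰B number density at fixed
fluence. Because $y^*$ is a linear functional of the dose density
$d(y)$, the mixed-field $y^*$ is exactly the dose-weighted mean of the
component values; `calibrate_components()` inverts this identity from
two measured operating points (the neutron-only field and the full
field at a reference concentration), and `mix_quality()` evaluates it
at any concentration.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `alpha0` | Gy⁻¹ | fitted | linear sensitivity before quality correction |
| `beta0` | Gy⁻² | fitted | quadratic (intra-domain pairwise) sensitivity |
| `repair_rate` $(a+c)$ | h⁻¹ | fitted | sub-lethal damage repair; sets the dose-rate transition at $\dot D \sim (a+c)/\beta_0$-scale |
| `rd` | µm | 0.5 | domain radius (1 µm diameter sphere) |
| `rho` | g/cm³ | 1.0 | domain density |
| `y0` | keV/µm | 150 | overkill saturation parameter |
| reference quality | keV/µm | 2.26 | photon reference ($y_D\approx y^*$ for ⁶⁰Co) |
| reference rate | Gy/min | 10 | effectively acute photon delivery |

Dose rates are quoted in Gy/min at every interface (the field's habit);
internally all kinetics run in hours and Gy/h. The bundled
`melanoma_params()` table carries published MCMC estimates for the
HX34, M8 and Mel-J human melanoma lines with their marginal SDs.

## Numerical choices

- **Quadrature on spectra** is trapezoidal on the supplied grid; grids
  need not be uniform because spectra arrive pre-binned. Length-1 and
  length-2 inputs are treated as discrete point masses so that
  single-event ("Dirac") closed forms are exact.
- **$q(T)$ near zero** is evaluated by the series
  $1-x/3+x^2/12$ for $x=(a+c)T<10^{-4}$ to avoid the catastrophic
  cancellation in $x+e^{-x}-1$; $q(0)=1$ is the analytic limit, not a
  numerical one. Note that $q$ genuinely deviates from 1 by $x/3$, i.e.
  about $3\times10^{-4}$ at $x=10^{-3}$; claims of $10^{-6}$ closeness
  hold only for $x<3\times10^{-6}$.
- **The schedule sum** is evaluated in O(N) by the running-sum
  recursion $S_m=e^{-(a+c)\Delta T}(S_{m-1}+D_{m-1})$ (a linear
  recursive filter), which matches the literal double sum to near
  machine precision and converges to the closed form at second order in
  $\Delta T$.
- **$\Delta T$ selection** for continuous schedules uses
  $(a+c)\Delta T\le 0.05$ and per-interval dose $\le 0.1$ Gy; at that
  resolution the discretisation error in $-\ln S$ is far below the
  model's parameter uncertainty.
- **Mean inactivation dose** integrates $S(D)$ by adaptive quadrature
  (relative tolerance $10^{-8}$) up to the dose where $-\ln S=46$
  ($S\sim10^{-20}$), located by root bracketing with doubling; a
  parameter set with $\alpha_0+\gamma^*\beta_0=0$ and $\beta_0=0$ is
  rejected as non-integrable.
- **Timeline interpolation** is monotone-preserving cubic
  (`monoH.FC`), clamped at zero and held at the boundary values outside
  the knots: pharmacokinetic concentration curves must not overshoot
  below zero, and plain cubic splines do.
- **Dose bookkeeping**: a delivery plan's stated total dose is
  authoritative; modelled rates are rescaled by one global factor so the
  delivered dose matches the prescription, which keeps the comparison
  between delivery durations at exactly equal physical dose.

## Bayesian fitting

The measurement model takes the observed $-\ln S$ of each record to be
the model value plus independent $N(0,\sigma^2)$ noise — noise on the
log-survival scale, not on the surviving fraction, matching how
clonogenic data scatter multiplicatively. The sampled vector is
$(\alpha_0,\beta_0,a+c,1/\sigma)$; $1/\sigma$ is given a uniform prior
on $(0,100]$ as the least-informative bounded choice, and the default
boxes $\alpha_0\in[0,3]$, $\beta_0\in[0,1]$, $(a+c)\in[0,50]$ are
generous relative to published mammalian values. Negative candidates
are rejected through the prior support, which is equivalent to
truncation at zero.

The sampler is component-wise Gaussian random-walk Metropolis. No
proposal mechanism is canonical for this likelihood, so widths adapt
toward a 20–50% acceptance window in 50-sweep batches during burn-in
and are then frozen — the retained chain is a valid Metropolis sample.
Chains start at the posterior mode (Nelder–Mead). Defaults are $10^4$
retained draws after $10^3$ burn-in sweeps; every fit requires an
explicit seed and reproduces bit-identically under it.

Sequential updating across datasets is supported by
`update_prior_from()`: the marginal posterior mean and SD of a
parameter become a zero-truncated normal prior for the next fit. This
is how a repair rate estimated from one cell line's dose-rate data is
carried to lines measured only acutely; the exact prior family for such
updates is a modelling choice, and the truncated normal is the one used
here.

## Uncertainty propagation to RBE, and a known fragility

When only published marginal summaries (mean ± SD per parameter) are
available, `draw_cell_params()` reconstructs parameter draws from
independent normals truncated at zero. This is the only reconstructible
surrogate for an unpublished joint posterior, and it has a documented
cost: correlations are lost. The consequence is mild when every
marginal sits well away from zero (M8, HX34), but severe when one does
not. Mel-J's $\alpha_0=0.002\pm0.047$ Gy⁻¹ is essentially a point mass
at zero with unknown skew; truncating an independent normal there
inflates the mean $\alpha_0$ to $\approx0.038$ and makes the low-dose-
rate mean RBE land well below values computed from the true joint
posterior. The package reports what the surrogate gives; the
qualitative structure — a much larger low-dose-rate RBE drop for Mel-J
than for M8, monotone decline with dose rate for photons, and a
markedly smaller decline for neutron/BNCT qualities — is robust to the
surrogate choice. The 68% bands everywhere are 16th–84th percentiles of
the per-draw RBE.

## What the synthetic generators emulate

- `sim_survival_data()` reproduces exactly the statistical structure
  the fitter assumes: Gaussian noise on $-\ln S$, clipped so the
  surviving fraction stays in (0, 1]. The default design (doses 1–8 Gy
  × rates 10–0.01 Gy/min) spans the protraction transition for repair
  rates near 9 h⁻¹. Real clonogenic data differ in ways the generator
  does not model: per-point SDs that vary with colony counts, plating-
  efficiency normalisation errors, and inter-experiment batch effects.
  Passing recovery/coverage tests therefore demonstrates correctness of
  the fitting machinery under its own assumptions, not robustness to
  real-data misspecification.
- `sim_lineal_spectrum()` builds multi-peak dose densities from
  log-normal bumps near 0.3, 20 and 200 keV/µm (photon electrons,
  recoil protons, capture ions). These are phenomenological stand-ins
  with the right moments and saturation behaviour, not track-structure
  output.
- `sim_boron_timeline()` produces a saturating rise to a peak followed
  by first-order washout, sampled at 1-minute knots — the generic shape
  of carrier pharmacokinetics after injection. Its defaults (25 ppm
  peak near 10 min, 0.005 min⁻¹ washout over 160 min) are module
  defaults chosen to exercise the schedule machinery, not measured
  kinetics.

## Problem sizes used by the test-suite

The suite validates the sampler's coverage with 50 synthetic replicates
of 24 records each ($\sigma=0.15$), fitting 2000 retained draws after
500 burn-in sweeps per replicate, and checks 68% interval coverage
against a 55–80% band; the RBE acceptance computations use 5000
parameter draws. These sizes were chosen to make Monte-Carlo error
comfortably smaller than the acceptance bands while keeping the full
suite around a minute of compute.

## Known limitations

- Inverse dose-rate effects (enhanced killing below ~0.1 Gy/min seen in
  some BNCT data) are deliberately unmodelled; predictions below that
  regime for high-LET fields should be read as SLDR-only baselines.
- $\beta_0$ is LET-independent by construction.
- ¹⁰B is assumed uniformly distributed in cells; intratumoral
  heterogeneity, spectrum differences between facilities and photon
  contamination enter only through whatever calibration values the user
  supplies.
- No pharmacokinetic compartment model, normal-tissue dosimetry or
  fractionation optimisation: the schedule module consumes a measured
  or assumed concentration timeline as-is.
- Radiation transport is out of scope: lineal-energy spectra and
  dose-rate calibration constants are inputs.
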