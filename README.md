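# microkin

Microdosimetric-kinetic modelling of clonogenic cell survival when both
the dose rate and the radiation quality change during dose delivery —
the situation in boron neutron capture therapy (BNCT), where the
cellular ¹⁰B concentration (and with it the mix of low-LET background
and high-LET capture products) varies over a delivery that can last
40–160 minutes. The package is aimed at radiobiologists and treatment
modellers who want to quantify how much sub-lethal damage repair during
a protracted delivery erodes cell killing, and at anyone fitting
linear-quadratic-type dose-response data with dose-rate structure.

## The model

Survival follows a microdosimetric-kinetic (MK) model. The delivery is
split into N sub-intervals of length ΔT with per-interval dose
D_n = Ḋ_n ΔT and radiation quality γ\*_n, and the mean number of lethal
lesions per nucleus is

    −ln S = Σ_n [(α₀ + γ*_n β₀) D_n + β₀ D_n²]
          + 2 β₀ Σ_{n<m} e^{−(m−n)(a+c)ΔT} D_n D_m

with cell-line parameters α₀ (Gy⁻¹), β₀ (Gy⁻²) and the sub-lethal
damage repair rate (a+c) (h⁻¹). Radiation quality enters only the
linear term, through the dose-mean specific energy per event
γ\* = 0.1602 y\*/(ρ π r_d²) of a 1 μm spherical domain, where y\* is the
saturation-corrected dose-mean lineal energy

    y* = y₀² ∫ [1 − exp(−y²/y₀²)] f(y) dy / ∫ y f(y) dy,   y₀ = 150 keV/μm.

For constant dose rate and quality the sum collapses to the closed form

    −ln S = (α₀ + γ*β₀) D + β₀ q(T) D²,
    q(T) = 2[(a+c)T + e^{−(a+c)T} − 1] / ((a+c)T)²,

the familiar LQ model with a Lea–Catcheside protraction factor on the
quadratic term. Radiosensitivity parameters are estimated by
random-walk Metropolis MCMC under a Gaussian likelihood on −ln S, with
sequential prior updating across datasets. Treatment endpoints are the
mean inactivation dose D̄ = ∫ S(D) dD and the RBE defined as the ratio
of the photon-reference D̄ (2.26 keV/μm at 10 Gy/min) to the test
radiation's D̄.

## Worked example

```r
library(microkin)

m8 <- melanoma_params("M8")      # bundled published parameters
#> <cell_params M8>
#>   alpha0 = 0.612 ± 0.13 Gy^-1
#>   beta0  = 0.066 ± 0.02 Gy^-2
#>   (a+c)  = 8.769 ± 2.128 h^-1

# survival under the BNCT field (10 ppm: 3.75 Gy/min, y* = 68.50 keV/um)
survival_fraction(m8, dose = c(2, 5, 8), dose_rate = 3.75, y_star = 68.50)

# RBE versus dose rate for 60Co quality, 68% band from 2000 draws
sw <- rbe_dose_rate_sweep(m8, c(10, 1, 0.1, 0.01, 1e-3),
                          n_draws = 2000, seed = 42)
sw
#>   dose_rate rbe_mean rbe_lo rbe_hi
#> 1     1e+01    1.000  1.000  1.000
#> 2     1e+00    0.982  0.975  0.989
#> 3     1e-01    0.890  0.851  0.928
#> 4     1e-02    0.820  0.764  0.877
#> 5     1e-03    0.810  0.752  0.869
autoplot(sw)
```

The RBE of 1 at the 10 Gy/min reference is the identity check; the fall
to ~0.81 at 10⁻³ Gy/min quantifies how much low-dose-rate delivery
spares M8 cells under low-LET photons (the same sweep with
`y_star = 68.50` shows a much smaller drop — the reduced dose-rate
dependence that makes high-LET BNCT attractive).

Delivery-plan comparison at a fixed 13.86 Gy prescription, using a
synthetic boron timeline that rises to ~25 ppm and washes out slowly:

```r
comp <- calibrate_components(1.0, 41.36, 3.75, 68.50, 10)
tl   <- sim_boron_timeline(duration_min = 160)
for (dur in c(40, 158)) {
  r <- plan_dose_response(m8, delivery_plan(13.86, dur, comp), tl,
                          dose_grid = 13.86)
  print(r$survival[r$curve == "schedule"])
}
#> [1] 5.849e-12    # 40-minute delivery
#> [1] 1.010e-10    # 158-minute delivery
```

Stretching the same dose from 40 to 158 minutes raises survival by a
factor ~17: repair during delivery is not negligible even for a
high-LET field.

Fitting synthetic data recovers known truths (α₀ = 0.263, β₀ = 0.047,
(a+c) = 8.857, σ = 0.15):

```r
dat <- sim_survival_data(melanoma_params("HX34"), sigma = 0.15, seed = 11)
fit <- fit_imk_mcmc(dat, n_samples = 4000, burn_in = 1000, seed = 12)
tidy(fit)
#>   term        estimate std.error conf.low conf.high
#> 1 alpha0        0.257    0.0120    0.245     0.268
#> 2 beta0         0.0463   0.00237   0.0440    0.0484
#> 3 repair_rate   9.23     2.29      7.04     11.2
#> 4 sigma         0.137    0.0253    0.114     0.159
```

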