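# steamdiff

Two-pool water-exchange modelling of long-diffusion-time STEAM diffusion MRI.

## What this is for

Treatments that induce apoptosis change cell microstructure long before a
tumour changes size: cells shrink, the intracellular water fraction drops,
and the membrane becomes leakier. Diffusion MRI at a *single* diffusion time
compresses all of this into one apparent diffusion coefficient. Stimulated
echo (STEAM) acquisitions store magnetization longitudinally during the
mixing time, reaching diffusion times of hundreds of milliseconds, where the
signal's dependence on diffusion time separates cell size, compartment
fractions and transmembrane water exchange.

`steamdiff` is for researchers analysing that kind of experiment (cell
pellets or other effectively two-compartment systems): it fits a two-pool
exchange model jointly over b-values and diffusion times, runs the
complementary diffusion-kurtosis analyses, and ships a synthetic-data
generator so the whole chain is testable end to end.

## The model

Water occupies an intracellular pool (fraction *m*<sub>I0</sub>, impermeable
sphere of radius *r*, intrinsic diffusivity *D*<sub>I</sub>) and an
extracellular pool with apparent diffusivity *D*<sub>E</sub><sup>app</sup>.
Over the diffusion time *t*<sub>D</sub> = Δ − δ/3 the pool magnetizations
evolve under diffusion attenuation, longitudinal relaxation and first-order
exchange:

    dM_I/dt = −q² D_I^app(t_D) M_I − R_1I M_I − k_IE M_I + k_EI M_E
    dM_E/dt = −q² D_E^app      M_E − R_1E M_E − k_EI M_E + k_IE M_I

with q² = b/t<sub>D</sub>, k<sub>EI</sub> = k<sub>IE</sub>·m<sub>I0</sub>/(1 − m<sub>I0</sub>)
(detailed balance), and D<sub>I</sub><sup>app</sup>(t) the narrow-pulse
restricted-sphere diffusivity from the eigen-expansion over roots of
j₁′(α) = 0. The signal is the summed matrix-exponential solution, fitted by
bounded multi-start Levenberg–Marquardt with the b = 0 images excluded
(STEAM crusher artifacts) and D<sub>I</sub> fixed at 1.7 μm²/ms.

The kurtosis route fits ln S = ln S₀ − b·D + b²D²K/6 per gradient
separation and then the exchange-time model
K(t) = K₀ (2τ/t)[1 − (τ/t)(1 − e^(−t/τ))] + K<sub>∞</sub> to the longest
separations, with 1/τ<sub>ex</sub> = k<sub>IE</sub> + k<sub>EI</sub>, plus
the kurtosis-peak relations f = K₀/(3 + K₀), t<sub>c</sub> = r²/D<sub>I</sub>,
t<sub>peak</sub> = (6/5)√(t<sub>r</sub> t<sub>c</sub>) that disentangle
radius from exchange.

## Worked example

Simulate a control-group pellet at SNR 50 with Rician noise and fit it:

```r
library(steamdiff)

d <- generate_dataset(group_preset("control"),
                      noise = noise_spec("rician", snr = 50, seed = 42))
fit <- fit_two_pool(d, fixed = list(d_i = 1.7), n_starts = 20, seed = 1)
fit
#> Two-pool fit ('control-1', control): 54 points, 7 free parameters, reduced chi^2 = 1.321
#>   fixed: d_i = 1.7
#> Two-pool exchange parameters:
#>   r = 4.061 um, m_i0 = 0.5168, k_ie = 2.155 s^-1 (k_ei = 2.304)
#>   d_i = 1.7, d_e_app = 0.7619 um^2/ms; r1_i = 0.7175, r1_e = 1.66 s^-1; s0 = 0.9785
```

The generating parameters were m_i0 = 0.55, r = 4.2 μm, k_ie = 4 s⁻¹: at
this noise level the fraction and radius come back tightly while the
exchange rate is the noisiest estimate — its 95% contour interval makes
that visible:

```r
ci <- contour_interval(fit, d, c("m_i0", "k_ie"), confidence = 0.95)
round(ci$interval, 3)
#>      lower  upper
#> m_i0 0.402  0.707
#> k_ie 0.000 12.284
```

Reduced chi^2 = 1.32 says the residuals are consistent with the per-point
noise. A full two-group study — generate 10 control and 10 apoptotic
samples, fit every pellet, compare groups — is one call:

```r
report <- run_pipeline(list(
  study = list(n_per_group = 10, snr = 50, noise = "rician", jitter = 1, seed = 7),
  fit = list(n_starts = 8, seed = 1)
))
report
#> Study report: 20 fits (0 failed samples)
#> ...
#>   m_i0               p = 2.97e-10  mean 0.554 -> 0.322 (-41.9%)
#>   r                  p = 5.6e-07   mean 4.34 -> 3.78 (-13.0%)
#>   k_ie               p = 0.0154    mean 3.45 -> 5.89 (+70.7%)
```

Apoptosis shows up as a large drop in intracellular fraction, a smaller drop
in radius, and an increase in exchange rate. Percent changes are reported
both from group means and as means of per-pair changes, because the two
conventions genuinely differ.

A thin command-line wrapper over the same functions lives at
`inst/scripts/steamdiff-pipeline.R` (subcommands `simulate`, `fit`,
`kurtosis`, `report`, `all`; YAML/JSON configs).

## Documentation

The methods vignette (`vignettes/two-pool-exchange.Rmd`) describes the
model and its assumptions, the numerical choices (sphere-series truncation,
contour criterion, optimizer settings), what the synthetic generator does
and does not emulate, and known limitations.
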