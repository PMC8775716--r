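# fibrilmorph

Quantitative analysis of protein amyloid fibrillization experiments —
the kind of study that asks how a co-solvent (here, imidazolium ionic
liquids acting on hen egg-white lysozyme) changes *how fast* fibrils
form, *how stable* the native protein is, and *what kind of fibrils*
grow. The package is for biophysicists who have:

1. **aggregation kinetics** — ThT fluorescence or CD ellipticity versus
   time,
2. **DSC thermograms** — excess heat capacity versus temperature, and
3. **AFM topographies** — height maps of deposited fibrils,

and want the standard derived quantities with tested, reproducible
code. A synthetic-data module generates ground-truth-labelled inputs
for all three pipelines, so everything installs and tests with zero
downloads.

## The models

**Kinetics.** Sigmoidal aggregation curves are fitted with the
Boltzmann parameterization

y(t) = y₁ + (y₂ − y₁) / (1 + exp(−2 (t − t_half)/(t_half − t_lag))),

giving the lag time t_lag (nucleation), half-time t_half, and the
apparent aggregation rate constant **k_agg = 2/(t_half − t_lag)**
(min⁻¹), with the Pearson correlation r as fit quality.

**DSC.** Thermograms are analyzed with the two-state excess heat
capacity with independent enthalpies,

Cp(T) = ΔH_cal·ΔH_vH/(R T²) · K/(1+K)², K(T) = exp(−ΔH_vH/R · (1/T − 1/T_m)),

yielding T_d, the calorimetric enthalpy ΔH_cal (by integration), the
van't Hoff enthalpy ΔH_vH (by fit), the cooperativity ratio
ΔH_vH/ΔH_cal (≈1 for a two-state monomeric unit) and scan-to-scan
reversibility.

**AFM morphometry.** Height maps are flattened scanline-by-scanline
(2nd-order polynomial, robust background masking), fibril ridges are
traced (automatic skeleton mode or seeded live-wire), perpendicular
cross-sections are sampled by bilinear interpolation and fitted with a
4-parameter Gaussian (accepted when r ≥ 0.95); ridge heights build a
histogram that is decomposed into normal components, and each peak is
labelled under a hierarchical assembly model in which n intertwined
protofilaments of height h₁ give a fibril of height h₁·√n
(compositions written "1 + 1", "2 + 2", ...).

## Worked example

```r
library(fibrilmorph)

# --- kinetics: noisy synthetic ThT trace, known truth ----------------
tr  <- gen_kinetic_trace(kinetic_sim_spec(
  y1 = 0, y2 = 100, t_lag = 64.8, t_half = 80.3, noise_sd = 2, seed = 1))
fit_boltzmann(tr)
#> <boltzmann_fit>
#>   y1 = 0.3031 +/- 0.26   y2 = 99.9 +/- 0.19
#>   t_lag  = 64.93 +/- 0.3 min
#>   t_half = 80.28 +/- 0.15 min
#>   k_agg  = 0.1303 1/min   r = 0.99915

# --- DSC: thermogram with instrumental baseline and a 98% rescan -----
tg1 <- gen_thermogram(thermogram_sim_spec(
  T_d = 66.57, dH_cal = 432.2, dH_vH = 448.5,
  baseline_coeffs = c(2, 0.01), noise_sd = 0.2, seed = 1))
tg2 <- gen_thermogram(thermogram_sim_spec(
  T_d = 66.57, dH_cal = 432.2 * 0.98, dH_vH = 448.5,
  baseline_coeffs = c(2, 0.01), noise_sd = 0.2, seed = 2))
fit <- fit_two_state(subtract_baseline(tg1))
fit$reversibility <- reversibility(subtract_baseline(tg1),
                                   subtract_baseline(tg2))
fit
#> <two_state_fit>
#>   T_d    = 66.57 +/- 0.0018 degC
#>   dH_cal = 431.8 +/- 0.21 kJ/mol
#>   dH_vH  = 448.9 +/- 0.27 kJ/mol
#>   dH_vH/dH_cal = 1.04   reversibility = 98%
```

The lag/half-times are recovered within their uncertainties, k_agg
matches the generating 2/15.5 = 0.129, and the DSC analysis returns the
generating enthalpies to ~0.1% with the expected cooperativity ratio
1.04 and reversibility 98%.

For the imaging pipeline:

```r
sim <- gen_afm_image(afm_sim_spec(seed = 1))   # 512x512, 180 fibrils
ana <- analyze_heightmap(sim$map, n_peaks = 3)
ana$mixture$peaks$mean     # c(2.63, 3.41, 5.89) -- truth 2.6/3.7/6.1 nm
median(ana$accepted_r)     # 0.997, all profile fits r >= 0.95
ana$assignments            # peak labels: "1", "1 + 1", "2 + 1"/"2 + 2" ...
```

## Command line

```sh
fibrilmorph kinetics trace.csv --normalize percent-of-max --out fit.json
fibrilmorph dsc scan1.csv --rescan scan2.csv --baseline progress
fibrilmorph afm map.tif --pixel-size 4.0 --bin-width 0.25 --peaks 3
fibrilmorph run --config config.json --seed 7 --out results/
```

(the launcher installs to `<library>/fibrilmorph/exec/fibrilmorph`).

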