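---
title: "Models and methods behind fibrilmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrilmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmorph)
```

fibrilmorph analyzes three complementary measurements of protein amyloid
fibrillization — aggregation kinetics, differential scanning calorimetry
(DSC), and AFM fibril morphometry — and ships a synthetic-data generator
that produces ground-truth-labelled inputs for all three. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what a green test does and does not establish.

## 1. Aggregation kinetics: the Boltzmann sigmoid

Nucleation-growth aggregation curves (ThT fluorescence or CD
ellipticity at 218 nm) are parameterized with the Boltzmann sigmoid

$$y(t) = y_1 + \frac{y_2 - y_1}
  {1 + \exp\!\big(-2\,(t - t_{half})/(t_{half} - t_{lag})\big)},$$

where $y_1, y_2$ are baseline and plateau signals, $t_{half}$ the time
at half-maximal signal and $t_{lag}$ the lag time given by the tangent
construction at the midpoint. The apparent aggregation rate constant is
$k_{agg} = 2/(t_{half} - t_{lag})$ (1/min); `fit_boltzmann()` always
derives it from the fitted times, so the identity with `compute_kagg()`
is exact by construction.

Numerical choices:

* Starting values are data driven: $y_1 = \min y$, $y_2 = \max y$,
  $t_{half}$ at the sample closest to mid-signal,
  $t_{lag} = t_{half} - \mathrm{range}(t)/10$.
* The geometry $t_{half} > t_{lag} \ge 0$ is enforced by fitting
  $\log(t_{half}-t_{lag})$, so invalid parameter sets are unreachable
  rather than penalized.
* `nlminb` bounded least squares (cost tolerance $10^{-10}$, at most
  10,000 evaluations) is followed by a few Gauss–Newton polish steps.
  The polish matters only for noiseless round-trip tests: quadratic
  local convergence takes zero-residual fits to ~machine precision,
  which derivative-free stopping rules do not guarantee.
* Parameter uncertainties come from the numeric Jacobian at the optimum
  ($\sigma^2 (J^TJ)^{-1}$, pseudo-inverse if the fit is exact and the
  Jacobian is numerically rank-deficient).

CD kinetics reuse the same code path on min–max-normalized ellipticity
($\theta_{norm}$); ThT curves conventionally use percent-of-maximum
normalization. Both are in `normalize_trace()` and neither affects
$t_{lag}$, $t_{half}$ (the fit is affine-invariant in $y$, a tested
property).

One tabulated inconsistency is deliberately not reproduced: for the
5% EMIM-ac condition the printed times (19.80, 21.90) give
$2/2.10 = 0.952$, not the printed 0.925. The package follows the
formula; the test suite asserts 0.952 and documents the mismatch.

## 2. DSC: two-state unfolding with independent enthalpies

Thermal unfolding is modelled with the MicroCal-style "non-two-state"
excess heat capacity in which the calorimetric enthalpy (peak area)
$\Delta H_{cal}$ and van't Hoff enthalpy (peak sharpness)
$\Delta H_{vH}$ are independent:

$$C_p^{exc}(T) = \frac{\Delta H_{cal}\,\Delta H_{vH}}{R\,T^2}
  \frac{K}{(1+K)^2}, \qquad
  K(T) = \exp\!\Big(-\frac{\Delta H_{vH}}{R}
  \Big(\frac 1T - \frac 1{T_m}\Big)\Big),$$

with $T$ in Kelvin internally (I/O in °C), $R$ in kJ/(mol·K), and the
unfolding heat-capacity increment fixed to zero (documented
limitation). Substituting $u = 1/(1+K)$ shows
$\int C_p^{exc}\,dT = \Delta H_{cal}$ exactly, which is both a
generator invariant and the basis of `integrate_enthalpy()`. At
$T = T_d$, $K = 1$ and
$C_p^{exc} = \Delta H_{cal}\Delta H_{vH}/(4RT_d^2)$, which seeds the
fit. The cooperativity ratio is reported as
$\Delta H_{vH}/\Delta H_{cal}$: every tabulated value in the source
data matches this orientation even though the column header prints the
reciprocal, so the package implements the orientation the numbers
support.

**Baseline handling.** The default `progress` baseline interpolates
between separate pre- and post-transition lines with the transition
progress (cumulative normalized peak area) as the weight, iterated
three times; `linear` fits one line through both flanking windows.
Flanking windows are auto-detected as everything farther than 3 FWHM
from the smoothed peak (relaxed stepwise to 2 FWHM if a side would
keep fewer than 3 points). A slope-threshold detection rule was tried
first and rejected: on a noiseless two-state curve the region where the
pointwise $|dC_p/dT|$ stays below a few percent of the peak slope
extends well into the transition tails, which biased
$\Delta H_{cal}$ by about 1.5% and the ratio by +0.03; and on noisy
scans the pointwise derivative essentially never stays below such a
threshold. At 3 FWHM the two-state tail is below $10^{-4}$ of the peak
height, so the windows are flat to within noise for any realistic scan.
Because the model tails are strictly positive on any finite bracket, a
"pure model curve is unchanged" identity can only hold to roughly the
tail amplitude (~$10^{-4}$ of the peak on the default grid), not to
machine precision; tests assert 1% of peak height.

## 3. AFM morphometry

The measurement chain is: per-scanline flattening → ridge tracing →
robust tangents → perpendicular cross-sections → 4-parameter Gaussian
fits → ridge-height histogram → multi-peak decomposition → hierarchical
assembly assignment.

* **Flattening** (`flatten_scanlines()`): each scanline has a
  polynomial of order 2 (configurable 0–3) fitted to background pixels
  and subtracted. Foreground (fibril) pixels are excluded by iterative
  one-sided masking: fit, mask residuals above 2 robust SDs, refit
  (3 iterations). This removes plane tilt and per-line bow exactly and
  preserves apex heights to ~2% on synthetic maps.
* **Tracing** (`trace_ridges()`): automatic mode thresholds the map
  (default $5\times\mathrm{MAD}$, a background-noise scale — an early
  max-relative threshold was rejected because a single tall fibril
  could push the threshold above the 2.6 nm population), thins the mask
  with a vectorized Zhang–Suen skeletonizer, removes junction pixels
  and links the remaining chains into ordered paths. Seeded mode runs a
  live-wire minimal-cost path (igraph Dijkstra) with per-pixel cost
  $w_1(\max H - H) + w_2|\nabla H|$, $w_1 = 1$, $w_2 = 0.5$. Points
  within the crossing-exclusion radius (3 × expected fibril half-width,
  default 18 nm) of a junction or another path are flagged and skipped
  by the profiler, mirroring the exclusion of overlapping and crossing
  segments.
* **Tangents** (`estimate_normals()`): median-filtered central
  differences (window 5) make single bad path points harmless; normals
  are rotated tangents.
* **Profiles** (`extract_profiles()`, `fit_profile()`): bilinear
  sampling along each normal at half-pixel steps over ±20 nm; the
  4-parameter Gaussian (position, width, amplitude, baseline) is
  accepted when $r \ge 0.95$ (the lower end of the published range)
  and the peak sits in the central third of the window. Ridge height is
  the fitted amplitude above the local baseline, not the raw apex.
  Because bilinear interpolation smooths the surface by a kernel with
  standard deviation close to $\mathrm{pixel}/\sqrt 6$, the fitted peak
  is slightly wider and flatter than the true cross-section; the
  amplitude is therefore deconvolution-corrected
  ($A \to A\,\sigma_{fit}/\sqrt{\sigma_{fit}^2 - \mathrm{px}^2/6}$,
  area-preserving). Without the correction recovered heights are biased
  about −4% at 4 nm pixels (−0.25 nm on a 6.1 nm fibril).
* **Histogram and mixture** (`build_histogram()`, `fit_multipeak()`):
  0.25 nm bins; a sum of $n$ Gaussians is fitted to bin counts by
  weighted least squares with Poisson-motivated $\sqrt{\text{count}}$
  weights, initialized from the visible histogram maxima plus
  quantile- and equally-spaced fallback starts (best of all starts
  kept). If $n$ is not given, $n = 1..6$ are fitted and AICc selects;
  components whose means fall within half the larger SD are merged
  with a warning.
* **Assembly model** (`predict_heights()`, `assign_fibril_types()`):
  protofilaments (height $h_1$) intertwine into protofibrils and
  fibrils; a composition "a + b" totalling $n$ strands has predicted
  height $h_1\sqrt n$ under the default `sqrt_n` rule. The
  `pythagorean` rule ($h(a{+}b) = \sqrt{h(a)^2 + h(b)^2}$ with
  balanced-tree leaf heights) coincides with `sqrt_n` for integer
  compositions and is kept as an explicit alternative; `additive`
  models loose stacking. With $h_1 = 2.6$ nm, (1+1) predicts 3.68 nm,
  matching the observed 3.7 nm protofibril peak; no simple rule
  quantitatively reaches the 6.1 nm peak labelled (2+1, 2+2) in the
  source analysis (predictions 4.5–5.2 nm), so the packing rule is
  exposed as a parameter and assignments report their deviation rather
  than forcing agreement.

## 4. The synthetic world

`gen_afm_image()` renders curved, non-crossing fibrils (cubic splines
through 4–8 bounded-turn waypoints) with Gaussian transverse profiles
(σ = 5 ± 0.5 nm) on a background of plane tilt (12/8 nm), per-scanline
quadratic bow (SD 2 nm) and white roughness (SD 0.15 nm) — exactly the
artifact classes scanline flattening must remove. Non-crossing is
enforced by a dilated occupancy grid, which guarantees the
`min_separation` (default 16 nm) up to pixel quantization margins.

The default field is 512 × 512 pixels at 4 nm/pixel with 60 fibrils in
each of three height populations, 2.6 ± 0.4, 3.7 ± 0.8 and
6.1 ± 1.1 nm, of lengths 100–300 nm. Two modelling decisions deserve
explanation:

* **Variance partition.** The population SDs above are treated as
  *observed histogram component widths*, not as between-fibril spread.
  By default 25% of each component's variance is between-fibril
  (`between_fraction = 0.25`); the remainder is a smooth mean-zero
  height modulation along each ridge (natural spline, correlation
  length ≈ 30 nm). This mirrors the physical account of peak
  broadening — fibril types have near-quantized heights ($h_1\sqrt n$),
  and the width of a histogram component comes mostly from structural
  fluctuation along the fibril and instrument precision. It is also a
  statistical necessity: with constant-height fibrils a single field
  contains only ~180 independent height draws, and Monte Carlo with a
  truth-initialized oracle fit shows the three-component decomposition
  of this strongly overlapping mixture is then not estimable to
  ±0.3 nm regardless of the fitter.
* **Fibril count.** 60 per population keeps the field at ~30% area
  occupancy (placement succeeds reliably) while providing enough
  independent draws; each analysis yields ~3000 accepted cross-section
  profiles, comparable to the ~1600 used per condition in the source
  analysis.

What the generator does **not** emulate: AFM tip dilation (all apparent
widths are intrinsic), feedback/scan-direction artifacts, helical pitch
modulation with a measurable period, fibril branching, and surface
adsorption deformation. A green end-to-end test therefore establishes
that the analysis chain is unbiased for smooth-ridge, well-separated
fibrils on polynomial-plus-noise backgrounds — not that it would
survive strongly tip-convolved or densely entangled real images.

## 5. Acceptance-scale expectations

The kinetics and DSC pipelines are deterministic given their inputs and
reproduce the published aggregation constants (0.129 vs printed
0.130 ± 0.010; 0.049; 0.036) and enthalpy ratios (1.04, 1.28, 1.34
± 0.02) from noiseless synthetic inputs. The end-to-end AFM experiment
is stochastic: across seeds the recovered population means scatter
around 2.6/3.7/6.1 nm with SDs of roughly 0.05/0.2/0.2 nm, so the
±0.3 nm target is met for most but not every seed — the middle
component, overlapped by both neighbours, is the least identifiable.
The acceptance run fixes the component count at the operator-chosen
three, as the source analysis did ("optimization with various peaks");
automatic AICc selection is the default elsewhere and is exercised on
iid draws in the unit tests, where it recovers the correct count and
means within 0.1 nm.

## 6. Known limitations

* DSC model fixes $\Delta C_p = 0$ and handles a single transition; no
  scan-rate-dependent (kinetic) irreversibility model.
* Ridge tracing assumes bright ridges on a flat background; it has no
  sub-pixel centerline refinement (the Gaussian profile fit recovers
  the apex regardless).
* The bilinear deconvolution correction assumes the only smoothing is
  resampling; real tip dilation would require a different (and much
  larger) correction.
* The TIFF codec covers baseline grayscale TIFFs (uncompressed,
  8/16/32-bit integer or 32-bit float, either byte order) — enough for
  exported height maps, not arbitrary instrument files.
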