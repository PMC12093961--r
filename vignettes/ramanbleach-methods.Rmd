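---
title: "Methods: photobleaching-based Raman/autofluorescence unmixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photobleaching-based Raman/autofluorescence unmixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ramanbleach)
```

## The measurement model

A pigmented bacterial cell illuminated at 632.8 nm produces, on a grating
spectrometer with 1,600 detector pixels spanning 660–3,022 cm⁻¹
(≈ 660–782 nm), an intensity spectrum that this package models per 30 s frame
$t \in \{0, 1, 2\}$ as

$$ I_t = R_0\,e^{-k_R t} + F_0\,e^{-k_F t} + B + \varepsilon, $$

where $R_0$ is the resonance Raman spectrum of the cell's carotenoids
(Lorentzian ν₁ ≈ 1,500, ν₂ ≈ 1,150, ν₃ ≈ 1,000 cm⁻¹ bands, defined in Raman
shift), $F_0$ the autofluorescence emission (broad bands defined in
wavelength, as emission physically is), $B$ a stable background (offset plus
the non-resonant C–H stretching band near 2,930 cm⁻¹, which does not bleach),
and $\varepsilon$ detector noise. Both electronically resonant components
photobleach; the assumption $k_F \ge k_R \ge 0$ encodes that fluorescence
bleaches at least as fast as the resonance-enhanced Raman signal.

Two consequences drive the decomposition (`decompose_cell()`):

1. the difference spectrum $I_0 - I_2 = R_0(1 - e^{-2k_R}) +
   F_0(1 - e^{-2k_F})$ contains only the bleaching components, so the
   *baseline* of the difference spectrum — its slowly varying part — is taken
   as the autofluorescence spectral component (recovered up to the
   $(1 - e^{-2k_F})$ scale factor, which cancels in all shape analyses and is
   absorbed by normalization in intensity scores);
2. the resonance Raman component is frame 0 minus frame 0's own baseline, so
   `raman + baseline_first == frame 0` holds exactly, pixelwise, by
   construction — an invariant the tests verify to machine precision.

The pixel grid is uniform in *wavelength* (grating + CCD), and Raman shifts
are derived per pixel via $\lambda = (10^7/\lambda_{exc} - \tilde\nu)^{-1}
\cdot 10^7$. This choice makes the 2,204–2,274 cm⁻¹ silent region span 50
pixels on the default axis, consistent with the instrument geometry the
package emulates. Whether the physical grid is *exactly*
wavelength-uniform is unknowable from the published description; uniformity
is the natural assumption for a single-grating spectrograph and is adopted
throughout.

## Baseline estimation

Two estimators are provided; both return the fitted curve and never the
peaks.

**Iterative polynomial** (`fit_baseline_iterpoly()`, the default): the input
is presmoothed once with a 20-point moving average, then iterated: fit an
order-12 polynomial by least squares over the whole axis, replace fitted
values that exceed the current working spectrum by the working spectrum's
values (truncating the peaks), and use the result as the next iteration's
input. Iteration stops when the fitted curve changes by less than a tolerance
(default $10^{-4}$ of the input dynamic range; cap 100 iterations, flagged if
reached). The "presmoothing factor 20" is read as a 20-point moving-average
window — the standard reading of a single scalar presmoothing parameter.
The polynomial is fitted on a centered/scaled pixel coordinate and the
projection is precomputed once per call, so order-12 fits are both stable and
fast. The working spectrum is pointwise non-increasing across iterations, and
the whole procedure is equivariant to adding a constant.

**Arc hull** (`fit_baseline_archull()`): for cells whose fluorescence curves
sharply near the carotenoid peaks, a rubber-band (lower convex hull) baseline
fails — under a concave-down dome the hull is just the chord. The arc hull
flattens the smooth curvature first: a rolling minimum (window ≈ 1/20 of the
axis) estimates the peak-free baseline; a circular arc is fitted through the
two chord anchor points and the interior point where that estimate deviates
most from the chord (for a profile dipping below the chord this is its global
minimum); the arc is subtracted, the lower convex hull of the residual taken,
and the arc added back. The circle is fitted in chord-subtracted coordinates
rescaled to a fixed sagitta of 0.25, which guarantees a single-valued arc for
any input scale. Near-collinear anchors fall back to the plain lower hull,
which is exact for linear baselines. The result never exceeds the input at
any pixel. This construction is a from-scratch design with the published
behavior (follow high-curvature fluorescence that a polynomial underfits) as
its target; the original routine of the same name is proprietary and
unpublished.

## Peak descriptors and filtering

ν₁ and ν₂ are fitted on the Raman component by nonlinear least squares of a
single Lorentzian with constant offset,
$A(\Gamma/2)^2 / ((\tilde\nu - \tilde\nu_0)^2 + (\Gamma/2)^2) + c$,
over windows of 1,480–1,560 and 1,110–1,180 cm⁻¹ (the published band
positions are approximate, so the windows are configurable). Initialization:
center at the window argmax, $\Gamma = 15$ cm⁻¹. Fits are rejected — never
silently accepted — when the optimizer fails, the amplitude is negative, or
the center pins within half a pixel of a window edge. The offset term is kept
because baselined spectra retain small residual offsets.

The SNR divides the mean (default, environmental mode: maximum) of 5 signal
pixels around the fitted center by the RMS of the silent region
2,204–2,274 cm⁻¹. The published procedure permits 3–7 signal points without
stating a rule; 5 is the default and the number actually used (after edge
truncation) is recorded. Cells with SNR **strictly below** threshold are
excluded: 2.0 for model organisms, 2.5 for environmental samples.

Intensity scores are normalized to the Euclidean norm of the
Savitzky–Golay-smoothed (15-point, order 2) C–H stretching region of the
*last* frame. The C–H band does not bleach and tracks biomass in the focal
volume, so the ratio cancels detector gain and focus differences. The C–H
region bounds are not published; the default 2,800–3,022 cm⁻¹ (up to the axis
limit) is configurable. The ν₁ intensity used for spectrum normalization in
`species_average_spectrum()` is the fitted amplitude plus offset at the
fitted center (option: raw window maximum). Autofluorescence intensity is the
maximum of the AF component over 737–776 nm divided by the same norm, with no
additional smoothing. The AF-positivity threshold is the *maximum* intensity
of a nonphototrophic control population, with strict exceedance — so the
defining control cell is itself negative.

## Shape classification

Autofluorescence components are truncated to 665–775 nm (cutting the
divergence of the baseline fit at the spectrum ends), min–max rescaled to
[0, 1] per cell (shape, not brightness), mean-centered (no variable scaling —
rows are already normalized) and reduced to 7 principal components, then
clustered by X-means with $k_{init} = 2$, $k_{max} = 20$ and centroid-change
tolerance $10^{-4}$. The published analysis states the 7 components, the BIC
splitting criterion and the tolerance but not $k_{init}$/$k_{max}$; the
defaults are recorded in every output.

X-means refines clusters with Lloyd iterations (the tolerance is the
centroid-movement stop condition, which is why `stats::kmeans` is not used
underneath), then tentatively splits each cluster in two (deterministic
seeding at centroid ± the principal direction) and keeps a split when the
two-cluster BIC exceeds the one-cluster BIC on that cluster's points. The BIC
uses the spherical-Gaussian likelihood with pooled variance
$\hat\sigma^2 = W/(n-k)$ and charges the parameter penalty
$\frac{p}{2}\log n$, $p = (k-1) + kd + 1$, **per cluster**. This is the
scoring of the clustering library whose behavior the pipeline reproduces, and
the per-cluster penalty is deliberately conservative: single-cell spectral
shapes vary smoothly within a species (amplitude ratios, bleed-through of
Raman tails at ≈ 681/697 nm into the AF window), producing thin, low-rank
within-cluster structure that a textbook single-penalty BIC will split
indefinitely even when the between-family separation is unambiguous. With
the per-cluster penalty, planted spherical Gaussians are still recovered
exactly and a single Gaussian cloud is never split beyond $k_{init}$.
Clusters below twice the minimum cluster size (default 2) are never split,
and $k$ never exceeds $k_{max}$.

Hierarchical clustering (`hcluster()`) defaults to Ward linkage on Euclidean
distances; neither is stated in the published analysis.

## Group statistics

`kruskal_wallis()` wraps the standard rank test (tie-corrected, χ²
approximation; the all-tied degenerate case is reported as $H = 0$, $p = 1$).
The post hoc procedure is implemented as Dunn's joint-rank $z$ comparisons in
the Hollander–Wolfe formulation:
$Z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}$
with mid-ranks and tie term $T = \sum(t^3 - t)/(12(N-1))$, declaring $i \ne j$
when $|Z_{ij}| \ge z_{1-\alpha/(k(k-1))}$. The name "Dunn–Holland–Wolfe"
does not pin down a stepwise variant; the single-step $\alpha/(k(k-1))$
adjustment is used, which controls the familywise error at $\alpha$ (the
acceptance suite measures the realized null rate at 2,000 replicates). The
compact letter display uses the insert-and-absorb algorithm, and the tests
verify both display conditions against the decision matrix directly.

## The synthetic-data generator

`simulate_cell()`/`simulate_population()` generate exactly the measurement
model above on the 1,600-pixel default axis: Raman peaks in shift space,
emission bands in wavelength space resampled onto the axis, per-frame
exponential bleaching (the frame index is the time unit; a frame-midpoint
convention only rescales $F_0$ and is therefore absorbed), additive Gaussian
noise (σ = 1 detector unit by default; Poisson shot noise optional), and a
non-bleaching background. Default bleaching constants
($k_F = 1.2$, $k_R = 0.15$ per frame) reproduce the qualitative published
behavior — fluorescence largely gone by frame 3, Raman peaks only mildly
reduced; single-exponential kinetics are assumed since only qualitative decay
is published. Default ν₁ amplitudes (30 detector units) put cells at
silent-region SNR ≈ 15–30, the regime in which model organisms pass the 2.0
filter.

Populations draw each cell's species by mixture weights and jitter its Raman
and AF amplitudes by a lognormal factor with CV 0.2 (cell-to-cell pigment
content). The default population size, 25 cells per strain, matches the
reference design. Emission *shape* is fixed within a species by default
(`af_center_jitter_nm = 0`, `af_shape_cv = 0`): a species' pigment complement
determines its emission shape, while its pigment amount varies strongly from
cell to cell. Nonzero shape jitter is available for robustness experiments,
with the caveat that smooth low-rank shape variation is genuine structure to
any BIC-based splitter.

Preset profiles span ν₁ 1,503–1,531 cm⁻¹ and the three observed emission
shape families: a ~690 nm band with a ~760 nm shoulder and a rise toward
780 nm (BChl *a*-like), a ~690 nm band with no long-wavelength rise
(BChl *b*-like), and a ~730 nm band (an environmental shape unlike the model
organisms); plus carotenoid-only and fully blank (nonphototroph) profiles.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: cosmic-ray spikes, detector etaloning and
wavelength-calibration drift, multi-exponential or intensity-dependent
bleaching, optical-trap heating, multiple carotenoid species per cell
(asymmetric/broadened bands), and Mie/substrate scattering backgrounds.

## Problem sizes and numerical choices

The shipped validation uses: 1,000 random cells for the additivity invariant,
200 cells for peak-recovery bias, 75-cell populations (3 × 25, the reference
per-strain size) for cluster recovery with 5 replicate populations in the
acceptance script, 2,000 null replicates for the familywise error rate, and
25 controls + 50 positive cells for threshold sensitivity. These sizes give
Monte-Carlo standard errors comfortably inside every asserted margin.
Other numerical choices: baseline convergence $10^{-4}$ of dynamic range
(cap 100 iterations); Lorentzian fits capped at 200 optimizer iterations
with box constraints ($A \ge 0$, center inside the window); k-means++
population seeding under a caller-supplied seed with PCA-deterministic split
seeding; silent-region RMS of exactly the pixels inside 2,204–2,274 cm⁻¹;
signal windows truncated (and recorded) at axis edges.

## Known limitations

- The AF component inherits the $(1 - e^{-2k_F})$ bleaching factor;
  absolute AF intensities are therefore comparable only across cells with
  similar bleaching kinetics, which is why all downstream analyses use
  normalized intensities or shapes.
- Resonance Raman intensity does not simply reflect pigment concentration
  (resonance enhancement varies by species and environment); the package
  accordingly never reports concentrations.
- The arc-hull reconstruction targets the published *behavior* of a
  proprietary routine; on profiles with both strong convex and concave
  curvature its single-arc correction is only first-order.
- X-means results depend on the BIC formulation; the package pins one
  (documented above) rather than exposing a family of criteria.
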