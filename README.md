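# ramanbleach

Photobleaching-based unmixing of simultaneous single-cell resonance Raman and
autofluorescence spectra of pigmented bacteria.

## The problem

Under 632.8 nm (He–Ne) excitation, a single pigmented bacterial cell yields a
spectrum that superimposes two electronically resonant signals on a stable
background: sharp resonance Raman bands of carotenoids — the C=C stretching
mode ν₁ near 1,500 cm⁻¹, the C–C stretching mode ν₂ near 1,150 cm⁻¹, and a
C–CH₃ band near 1,000 cm⁻¹ — and a broad autofluorescence continuum from
bacteriochlorophyll-type pigments. Both resonant components photobleach over
tens of seconds of illumination, while the non-resonant Raman signal (notably
the C–H stretching region near 2,800–3,022 cm⁻¹) does not. Measuring each cell
as three consecutive 30 s frames therefore encodes the separation in time:

- the **difference spectrum** (frame 1 − frame 3) contains only the bleaching,
  electronically resonant components;
- its **baseline** (the slowly varying part) is the autofluorescence spectral
  component;
- the **resonance Raman component** is frame 1 minus frame 1's own baseline.

From the two components the pipeline derives, per cell: Lorentzian ν₁/ν₂ peak
positions (ν₁ anticorrelates with the carotenoid conjugation length *N*), a
signal-to-noise ratio against the cellular silent region (2,204–2,274 cm⁻¹),
peak intensities normalized to the C–H-region vector norm of the last frame,
and an autofluorescence intensity (maximum over 737–776 nm, same
normalization). Populations are then classified by autofluorescence *shape*
(min–max normalized 665–775 nm window → PCA → X-means clustering with BIC
splitting) and compared across groups with the Kruskal–Wallis test followed by
Dunn–Holland–Wolfe multiple comparisons and a compact letter display.

The package is aimed at microbial spectroscopists and microbiome researchers
who want a tested, scriptable implementation of this workflow — including a
synthetic-spectra generator with full ground truth, since raw single-cell
spectra of this kind are rarely published.

## Worked example

Simulate a 45-cell population mixing two phototrophic profiles
(spirilloxanthin-like, ν₁ = 1,505 cm⁻¹, and spheroidene-like, ν₁ = 1,519 cm⁻¹)
with a nonphototrophic control, then run the full pipeline:

```r
library(ramanbleach)

profiles <- preset_profiles()[c("spirilloxanthin_bchla", "spheroidene_bchla",
                                "nonphototroph")]
pop    <- simulate_population(profiles, n_cells = 45, seed = 42)
groups <- setNames(pop$truth$species, pop$truth$cell_id)
res    <- run_pipeline(pop$cells, groups = groups,
                       config = run_config(control_group = "nonphototroph",
                                           seed = 1))

head(res$kept[, c("cell_id", "group", "nu1_center", "nu2_center",
                  "snr", "nu1_intensity", "af_intensity", "af_positive")], 5)
#>    cell_id                 group nu1_center nu2_center      snr nu1_intensity
#> 1 cell_001 spirilloxanthin_bchla   1505.037   1150.419 27.72068     0.1745158
#> 2 cell_002 spirilloxanthin_bchla   1504.844   1150.299 22.93792     0.1590352
#> 3 cell_003     spheroidene_bchla   1518.903   1152.835 19.94179     0.1413493
#> 5 cell_005 spirilloxanthin_bchla   1504.661   1150.281 18.26795     0.1117295
#> 7 cell_007 spirilloxanthin_bchla   1504.820   1150.065 15.77761     0.1000822
#>   af_intensity af_positive
#> 1    0.2428763        TRUE
#> 2    0.2406167        TRUE
#> 3    0.1768867        TRUE
#> 5    0.1721939        TRUE
#> 7    0.2575795        TRUE
```

The fitted ν₁ centers recover the two true positions (1,505 / 1,519 cm⁻¹) to a
fraction of a wavenumber, at silent-region SNRs far above the 2.0 exclusion
threshold. The 16 nonphototrophic cells carry no carotenoid peaks, so their
Lorentzian fits are rejected and the SNR filter excludes them
(`nrow(res$rejected)` is 16) — exactly the role a pigment-free control plays.
The autofluorescence threshold is the control maximum, and every pigmented
cell scores strictly above it:

```r
res$af_threshold        # highest AF intensity among the controls
#> [1] -0.001748048
table(res$kept$group, res$kept$af_positive)
#>                         TRUE
#>   spheroidene_bchla       13
#>   spirilloxanthin_bchla   16
res$stats$af_intensity
#> Kruskal-Wallis H = 1.617, df = 1, p = 0.2035
#> Letters: spheroidene_bchla:a  spirilloxanthin_bchla:a
```

The two BChl *a* profiles share one emission shape family, so their AF
intensities do not separate (shared letter `a`). Lower-level entry points
(`decompose_cell()`, `fit_lorentzian_peak()`, `compute_snr()`, `ch_norm()`,
`prepare_af_matrix()`, `af_pca()`, `xmeans()`, `compare_groups()`, …) expose
each stage individually; `vignettes/ramanbleach-methods.Rmd` explains the
model, parameters and design choices.

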