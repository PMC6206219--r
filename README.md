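# thickpen

Multi-scale comparison of curves with the **thick pen transform (TPT)**
and the **thick pen measure of association (TPMA)**, applied to spectral
irradiance in forest understoreys.

## The problem

Light beneath a forest canopy — shade, semi-shade, sunflecks — differs
not only in intensity but in spectral shape, and plants use that shape
(e.g. the red to far-red balance) as a developmental cue. Comparing
irradiance spectra as *shapes* is awkward: they are multi-scale (sharp
absorption lines on a smooth continuum), often come in groups of more
than two, and sit on non-equispaced wavelength grids. The TPT handles all
three at once, without interpolation, and is for anyone — plant
ecologists, atmospheric scientists, anyone with curves on an irregular
grid — who wants scale-resolved similarity rather than a single
correlation number.

## The method

Draw a curve X with a square pen of thickness τ: at every wavelength λ
the pen sweeps the window {l : λ ≤ l ≤ λ + τ} and leaves boundaries

    L(λ, τ) = min over the window of X,   U(λ, τ) = max over the window of X.

The collection of (L, U) pairs over a thickness set T = {τ₁, …, τₙ} is
the TPT: thin pens trace fine-scale roughness, thick pens the trend. To
compare K ≥ 2 curves, each is first normalized onto [0, 1] over the
analysis window (shape, not amplitude), and the pen intervals are
compared pointwise:

    ρ(λ, τ) = (minₖ Uₖ − maxₖ Lₖ) / (maxₖ Uₖ − minₖ Lₖ)  ∈ (−1, 1]

— intersection over union when the K intervals overlap, minus gap over
spanning interval when they do not. Averaging over λ gives the mean TPMA
ρ̄(τ), a one-number cross-dependence summary *per scale*.

The package implements the transform (O(N) monotonic-deque windowed
extrema in C++, windows by wavelength width), the K-variate TPMA, the
study pipeline (screening of saturated/UV-deficient replicates, two-stage
averaging, factor comparisons), summary statistics (maximum irradiance,
PAR, R:FR), a synthetic solar-spectrum generator with the full factorial
design (5 stands × 3 dates × 3 positions + full-sun, including the
missing-cell structure), CSV input/output, plotting, and a small CLI.

## Worked example

Three canopy positions in one stand on one date, compared at the study's
nine thicknesses:

```r
library(thickpen)

grid <- make_grid(spectrum_scenario(seed = 22))
curves <- lapply(c("shade", "semi-shade", "sunfleck"), function(p)
  simulate_spectrum(spectrum_scenario(position = p, stand = "BetulaOld",
                                      date = "2015-05-22", seed = 22),
                    grid = grid))
curves[[1]]
#> <spectral_curve> 1091 points on [300, 800] nm
#>   max irradiance: 0.1585 | date=2015-05-22 stand=BetulaOld position=shade

tpma_curves(curves, thickness_set())
#> <tpma_set> K = 3 curves, 9 thicknesses
#>  tau_nm    mean_rho K
#>      15 -0.48257063 3
#>      20 -0.40090791 3
#>      25 -0.33829006 3
#>      30 -0.28427608 3
#>      40 -0.14137092 3
#>      50 -0.07455510 3
#>      60 -0.01492716 3
#>      70  0.03545691 3
#>      80  0.08379976 3
```

The trivariate mean TPMA is negative at small thicknesses (the three
positions' shapes disagree scale-by-scale: shade and semi-shade are
depleted in blue-green relative to the sunfleck) and rises with τ —
coarse pens see the shared solar envelope, so cross-dependence grows with
scale. Summary statistics behave as the light environments suggest:

```r
round(spectral_summaries(curves[[1]]), 3)  # shade
#>   max_irradiance    par  r_fr
#> 1          0.158 37.766 1.009
round(spectral_summaries(curves[[3]]), 3)  # sunfleck
#>   max_irradiance    par  r_fr
#> 1          0.821 221.89 1.113
```

A whole synthetic study and a factor comparison:

```r
study <- simulate_study(seed = 1)            # 42 cell-level spectra
cmp <- run_comparison(study$curves, "position")
plot_mean_tpma(cmp)                          # one line per stand x date
```

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/thickpen.R simulate --seed 1 --position shade --n 5 --out shade.csv
Rscript inst/cli/thickpen.R associate --in shade.csv --out shade_assoc
Rscript inst/cli/thickpen.R compare --in study.csv --vary position --out pos
```

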