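# mobflim

Label-free metabolic profiling of single cells from NAD(P)H/FAD fluorescence
lifetime imaging (FLIM), for imaging labs studying stem-cell metabolism —
e.g. hematopoietic stem cells (HSCs), whose quiescent, glycolysis-leaning
state shows up in autofluorescence lifetimes long before surface markers
change. The package turns per-pixel photon decay histograms into a scalar
per-cell **MOB score** ("metabolic optical biomarker" score) of metabolic
stemness, and classifies cell divisions as metabolically symmetric or
asymmetric from the scores of paired daughter cells.

## What it computes

- **Fit-free phasor analysis.** Each pixel's decay is Fourier-transformed to
  phasor coordinates `g = Σ I(t)cos(ωt)/Σ I(t)`, `s = Σ I(t)sin(ωt)/Σ I(t)`.
  Mono-exponential decays lie on the universal semicircle
  `(g − 1/2)² + s² = 1/4`; a free/bound NAD(P)H mixture lies on the chord
  between the two species. With the free lifetime fixed at τ_free = 0.45 ns,
  extending the anchor–pixel line to the semicircle yields the bound lifetime
  τ_bound = s/(ωg) at the intersection, and the chord ratio gives the bound
  intensity fraction α_bound. A 3×3 median filter on g and s precedes the
  decomposition.
- **Optical redox ratio (ORR).** FAD/NAD(P)H intensity ratio in mitochondria,
  corrected by subtracting the cytoplasmic/nuclear ratio (an additive
  baseline).
- **Segmentation.** NAD(P)H photon threshold (1–2 counts/pixel) → hole
  filling → erosion-seeded watershed → size exclusion; per-cell Otsu split of
  background-subtracted FAD into mitochondria vs cytoplasm/nucleus.
- **A 205-entry feature registry** per cell: signal strength, distribution,
  and GLCM/GLRLM texture statistics of NAD(P)H intensity, α_bound, τ_bound
  (both compartments) and ORR (mitochondria), mito↔cyto compartmentalization
  `(m − c)/(m + c)`, and morphology.
- **Feature selection**: per-feature logistic F1 (> 0.6, held-out 40%) and
  trending index `TI = Σ Δmean / Σ |Δmean|` (|TI| > 0.5) in two independent
  differentiation datasets, then knowledge-graph reduction to representative
  features; SVM ROC/AUC evaluation.
- **MOB score**: robust scaling (median → 0, quartiles → ±1), DBSCAN outlier
  removal, then a 3-dimensional maximum-likelihood factor model; the first
  latent variable is the score, with per-feature weights = correlations.
- **Division patterns**: |ΔMOB| between paired daughters, two-component
  Gaussian mixture threshold (equal-posterior point), parent–daughter Pearson
  inheritance, post-division dynamics, and condition screening (ANOVA).
- **Synthetic FLIM scenes** with known ground truth (two-exponential decays,
  Poisson photon statistics at ~20–30 photons/pixel, punctate mitochondria)
  so the whole chain is testable without instrument data.

## Worked example

```r
library(mobflim)

# a 2x2 grid of synthetic cells at ~25 photons/pixel
cells <- grid_cells(2, 2, spacing_px = 48, radius_px = c(15, 17), seed = 3)
spec  <- scene_spec(image_size = c(96, 96), cells = cells,
                    n_time_bins = 256L, seed = 5)
scene <- simulate_decay_image(spec)

proc <- mob_process(scene$nadph, scene$fad,
                    mob_config(min_size_px = 200, max_size_px = 5000))
recovery_summary(proc, scene)[, c("true_alpha", "est_alpha",
                                  "true_tau", "est_tau")]
#>   true_alpha est_alpha true_tau  est_tau
#> 1  0.4310937 0.4377591 3.282731 3.368851
#> 2  0.5814753 0.5937511 3.666735 3.677857
#> 3  0.3947540 0.3960191 3.528492 3.567738
#> 4  0.5048064 0.5000226 3.156531 3.278415
```

Each row is one segmented cell: the pooled-phasor estimate of its bound
NAD(P)H fraction and bound lifetime (ns) against the generator's ground
truth — at this photon budget the estimates land within a few percent.
`proc$features` holds the 205-column feature table for downstream selection
and scoring:

```r
ds  <- simulate_division_dataset(division_spec(n_pairs = 500, seed = 19))
mix <- fit_delta_mixture(ds$pairs$delta_mob)
mix$threshold
#> [1] 1.098275
mean(as.character(mix$pattern) == ds$pairs$true_pattern)
#> [1] 1
```

The mixture threshold separates the two ΔMOB modes (0.3 vs 2.0 score units)
near their density intersection, and every division is classified correctly.

A command-line front end mirrors the R API
(`exec/mob simulate|phasor|segment|features|select|score|divisions|run-all`).

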