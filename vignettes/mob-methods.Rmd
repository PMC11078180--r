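---
title: "Metabolic optical biomarkers from phasor FLIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic optical biomarkers from phasor FLIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobflim)
```

mobflim quantifies single-cell metabolism label-free, from the
autofluorescence of two metabolic coenzymes: NAD(P)H (whose fluorescence
lifetime differs between its free and enzyme-bound states) and FAD. This
vignette is the package's own account of the models it implements, the
tunable parameters and their defaults, the numerical choices, what the
synthetic generator does and does not emulate, and the known limitations.

## The phasor model of NAD(P)H decays

Time-correlated single photon counting records, per pixel, a histogram
$I(t)$ of photon arrival times over one laser period $T$ (default
$T = 12.5$ ns, i.e. an 80 MHz repetition rate). The first-harmonic phasor
transform maps the decay to

$$g = \frac{\sum_t I(t)\cos\omega t}{\sum_t I(t)}, \qquad
  s = \frac{\sum_t I(t)\sin\omega t}{\sum_t I(t)}, \qquad
  \omega = 2\pi/T,$$

with $t$ at bin centers. Mono-exponential decays of lifetime $\tau$ lie on
the *universal semicircle* $(g-\tfrac12)^2 + s^2 = \tfrac14$ at
$g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau g$; mixtures lie inside, on the
chord between their components, at the position given by their fractional
*intensity* contributions. This linearity is what makes the analysis
fit-free: no curve fitting is ever performed, which matters at the
20–30 photons/pixel budget of live-cell imaging where biexponential fits are
hopeless.

Free NAD(P)H has a nearly constant lifetime across hematopoietic cell types,
fixed here at $\tau_{free} = 0.45$ ns; enzyme-bound NAD(P)H is slower and
enzyme-dependent. For each pixel phasor $P$, the line from the free anchor
$F$ (the semicircle point of $\tau_{free}$) through $P$ is extended to its
second semicircle intersection $B$; then

$$\tau_{bound} = \frac{s_B}{\omega g_B}, \qquad
  \alpha_{bound} = \frac{|P-F|}{|B-F|},$$

the bound lifetime and the bound fraction of the emission. A 3×3 median
filter is applied to the $g$ and $s$ matrices first (invalid zero-photon
pixels excluded from neighborhoods; borders use reduced windows).

Numerical choices:

* **Bin-center time convention.** The discrete transform with bin-center
  times is a midpoint-rule approximation of the continuous transform; at 256
  bins the discretization error on recovered lifetimes is of order $10^{-3}$
  relative, at 512 bins a few $10^{-4}$. Tests that assert $<10^{-3}$
  recovery therefore use 512-bin scenes; the calibration check uses 4096.
* **Out-of-range pixels.** Shot noise pushes phasors outside the semicircle
  or beyond the chord. These are clamped into $[0,1]$ and flagged
  (`qc = clamped`) rather than discarded, preserving per-cell statistics;
  pixels on the short-lifetime side of the anchor, where no bound
  intersection exists, are flagged invalid. QC fractions are reported.
* **Per-cell estimates.** The per-pixel $\tau_{bound}$ map is noisy and its
  cell mean is convexity-biased at low photon counts; for ground-truth
  recovery the package pools the cell's phasor (photon-weighted mean of $g,
  s$ — exactly the phasor of the summed decay, linear and hence unbiased)
  and decomposes once. The feature library keeps per-pixel statistics, which
  is what the subcellular texture features require.
* **Repetition rate.** Not a measured quantity here: 80 MHz / first harmonic
  is the documented default, and all geometry is parameterized by $\omega$.

The optical redox ratio uses the identity that diffuse cytoplasmic signal
adds a constant to the mitochondrial FAD/NAD(P)H ratio: the observed ratio is
the true one plus a baseline $\alpha$, so
`orr_corrected = (ΣFAD/ΣNADPH)_mito − (ΣFAD/ΣNADPH)_cyto` removes it exactly
for additive contamination. No FAD lifetime decomposition is performed; FAD
contributes intensity only.

## Segmentation

Cells are masked by an NAD(P)H photon threshold (default 2 counts/pixel;
1–2 is appropriate because live-cell imaging at low excitation leaves the
background nearly photon-free), holes filled, then split by an
erosion-seeded watershed: one 3×3-cross erosion produces seed markers, and
mask pixels are assigned to markers by propagation on the distance
transform. Components outside a size window (default: disk-equivalent areas
of 6–20 µm diameters at the 0.18 µm pixel size) are discarded as debris or
clumps. Within each cell, Otsu's threshold on background-subtracted FAD
(background = mean FAD outside the global cell mask; the formula is not
specified upstream, so this is a documented package choice) separates the
punctate, FAD-bright mitochondria from the pooled cytoplasm/nucleus
compartment — no nuclear segmentation is attempted. Cells where the split
degenerates (constant FAD, or an empty compartment) are flagged and excluded
from compartment features only.

## The feature registry

`mob_registry()` enumerates 205 per-cell features as a declarative table:

* 7 channel–region combinations (NAD(P)H intensity, α_bound, τ_bound in
  mitochondria and cytoplasm/nucleus; per-pixel ORR in mitochondria only) ×
  23 statistics — 4 signal strength (average, median, 10th/90th percentile),
  7 distribution (SD, variance, skewness, excess kurtosis, entropy, IQR,
  uniformity), 12 texture (6 GLCM, 6 GLRLM);
* compartmentalization $(m-c)/(m+c)$ of the 11 non-texture statistics for
  the three per-pixel channels (33);
* 10 morphology features (areas, axis lengths, eccentricity, perimeter,
  circularity, mitochondrial count and dispersity);
* the corrected per-cell ORR.

Conventions: percentiles use linear interpolation between closest ranks;
entropy/uniformity use a fixed 16-bin histogram per region; texture
quantizes each region to 16 gray levels by min–max scaling and aggregates 4
symmetrized distance-1 directions (standard radiomics defaults — the
upstream parameter file is not public, so the registry is data-driven and
reconcilable). "Mitochondrial dispersity" is not defined upstream; it is
implemented as connected mitochondrial components per mitochondrial pixel,
and is swappable. Constant regions take their defined texture limits (zero
contrast and difference variance, unit energy); only the GLCM correlation is
undefined there and flagged NA. Every feature is finite or explicitly NA
with a row flag — nothing silently missing.

## Feature selection

A feature is *informative* when, in **both** of two independent
differentiation datasets, (i) a single-covariate logistic model trained on a
stratified 60% split achieves held-out F1 > 0.6 for the stem class, and
(ii) the trending index of its population stage means,
$TI = \sum_n \Delta_n / \sum_n |\Delta_n|$, exceeds 0.5 in magnitude
($TI = \pm 1$ exactly iff the means are strictly monotone; $|TI| < 0.5$ is
"fluctuating"). By default the TI sign must also agree across the two
datasets — a consistent up- or down-trend is what "informative" means
biologically; `require_sign_agreement = FALSE` restores the literal
two-threshold rule. Ties at exactly 0.6/0.5 fail the strict inequalities.
Logistic fits use no regularization and a fixed split seed.

Selected features are then reduced by a knowledge graph whose leaf nodes
group registry entries by (compartment, channel, statistic family); a node
is kept when at least half its members pass selection (the fraction cutoff
is a package choice — only the node fractions, not a rule, are shown
upstream), and emits one canonical representative (priority average >
median > variance). A radial-kernel SVM ROC (70/30 stratified split,
trapezoid AUC on held-out decision values) evaluates feature subsets.

## The MOB score

Representative features are conditioned in three steps: DBSCAN outlier
removal (hand-rolled distance-matrix DBSCAN; `min_samples = 5`, `eps` from a
k-distance heuristic of 3× the median 5-NN distance — no parameters are
printed upstream), per-condition shuffling and trimming to equal n, and
robust scaling fit on a training reference (stem cells, or all cells for
paired-daughter studies): $x \mapsto (x - \mathrm{med}) / \frac{q_3-q_1}{2}$,
so the training median maps to 0 and the quartiles to exactly −1 and +1.
The common full-IQR convention maps quartiles to ±0.5 and contradicts the
±1 anchor statement, so half-IQR is the default and the convention is
switchable. Quartiles use linear interpolation (the convention changes the
anchors, so it is stated).

The score is the first latent variable of a 3-dimensional maximum-likelihood
linear factor model on the scaled representative features, fitted by EM on
the correlation matrix with near-zero initial noise variances (an exact zero
is degenerate in the likelihood; $10^{-3}$ is used). EM's monotone
likelihood makes it robust on the near-collinear panels real feature sets
produce, where gradient-based optimizers can fail outright; on
well-conditioned data it agrees with `stats::factanal` to numerical
precision (a test asserts this). Factors are ordered by explained variance;
LV1 is the MOB score; per-feature weights are the Pearson correlations
between LV1 and each feature. Because a factor's sign is arbitrary, LV1 is
oriented so a designated anchor feature has positive weight — by default the
mitochondrial τ_bound average, which is elevated in stem cells — anchoring
to a feature rather than a labeled population so unlabeled datasets can be
oriented. New cells are scored deterministically by the Thomson/regression
formula from the stored loadings; rows missing any representative feature
are flagged, not scored. A stem/differentiated threshold on scores is the
equal-posterior point of a two-component Gaussian mixture (below).

## Division-pattern analysis

Daughter-cell pairs are recovered by micropattern identity: cells at both
timepoints are assigned to their nearest site within a radius; sites with
one cell before and exactly two after division yield records, and sites with
more than two cells (second divisions) are flagged out. ΔMOB is the
*absolute* score difference between the unordered siblings (a sign has no
meaning between them; this also makes classification invariant to daughter
order).

The ΔMOB histogram of a division experiment is bimodal — a symmetric mode
near zero and an asymmetric mode well above it. A two-component univariate
Gaussian mixture is fitted by EM, initialized deterministically at the 25th
and 75th percentiles with a common SD; the classification threshold is the
equal-posterior (density-intersection) root between the two means, falling
back to the midpoint for numerically equal variances. When the fitted means
are separated by fewer than 2 pooled SDs the sample is treated as unimodal
(no threshold, pairs unclassified): EM "splits" of genuinely unimodal
samples measure 1.5–2.0 pooled SDs, the benchmark mixtures 6+, so 2 is a
clean separating value in the spirit of the usual bimodality criteria.
Thresholds are never silently reused across experiments.

Inheritance is the Pearson correlation (with zero-slope p-value) between
parent and daughter scores — the daughter-pair mean by default, each
daughter optionally — overall and per pattern. Post-division dynamics report
per-pattern mean trajectories and the fraction of daughters above the
stemness threshold per timepoint, compared by Mann-Whitney; condition
screens compare ΔMOB distributions and asymmetric fractions across
treatments by one-way ANOVA.

## The synthetic generator: what it emulates, and what it does not

`simulate_decay_image()` renders disk-shaped cells on a dark background.
Each cell's NAD(P)H decay is the intensity mixture
$(1-\alpha)\,p_{free}(t) + \alpha\,p_{bound}(t)$ of normalized periodized
exponentials — α is defined as the fractional intensity contribution, the
quantity the phasor chord ratio measures. Photon counts are Poisson per time
bin; the default rates put 20–30 photons/pixel inside cells, the documented
live-cell regime. Mitochondria are punctate disks covering a configured area
fraction with a FAD-intensity contrast (default 5×), mirroring the
Otsu-on-FAD segmentation handle. Background counts are time-uniform dark
counts. The instrument response is ideal (a delta): the upstream system
corrects for its IRF internally, and the clean limit is what synthetic tests
need. `noise = FALSE` returns the expected histograms exactly.

Not emulated: optics (PSF blur, spectral bleed-through beyond the additive
baseline the ORR correction removes), photobleaching, cell-to-cell decay
heterogeneity within a cell, autofluorescence from other species, or
realistic mitochondrial morphology. Passing tests therefore demonstrate the
*analysis* is correct and calibrated under the stated photon statistics —
not that instrument data will be this clean.

`simulate_population_features()` draws Gaussian features around configured
stage means (monotone for the ground-truth informative set — the selection
benchmark spaces stage means 2 SDs apart over 4 stages);
`simulate_latent_features()` plants one latent factor (11 features, loadings
0.6–1, noise SD 0.3 — a strongly factor-driven panel, as a representative
feature set is by construction); `simulate_division_dataset()` draws parent
scores, daughter-pair means inheriting them at a configured correlation
(defined against the pair mean; the per-daughter correlation is attenuated
by the sibling split), and |Gaussian| sibling differences at 0.3 vs 2.0
score units (SD 0.2) for symmetric vs asymmetric divisions. Benchmark sizes
used by the tests — 4-cell scenes at 96², a 64-cell scene at 368² for the
binning-robustness check, 200 cells/stage, 500 division pairs — run the full
suite in about a minute on one CPU.

## Known limitations

* The exact upstream feature list (205 entries) is not public; the registry
  reproduces the documented categories and counts but individual texture
  parameters may differ. It is a data-driven table precisely so it can be
  reconciled.
* Robust-scaled factor models do not transfer across instruments without
  re-anchoring; the model serializes its anchors and loadings to JSON for
  exactly that reason.
* Vendor FLIM formats (.ptu, .lif) are out of scope; the conversion contract
  is a multi-plane TIFF of per-bin counts plus a JSON sidecar with the laser
  period (the TIFF codec stores scaled integers, so integer photon counts
  round-trip exactly at 16 bits).
* DBSCAN's `eps` heuristic assumes one dominant population per condition;
  strongly multi-modal feature tables should set `eps` explicitly.
* At 25 photons/pixel the per-pixel τ_bound maps carry upward bias (noise
  convexity); per-cell pooled-phasor estimates do not, and the 2×2-binning
  consistency of the final score is tested directly.
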