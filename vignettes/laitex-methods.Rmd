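---
title: "Methods: spectral-textural estimation of maize LAI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-textural estimation of maize LAI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leaf area index (LAI, m²/m²) is the standard descriptor of canopy
development and a key input to growth monitoring and yield forecasting.
At the plot scale it is estimated non-destructively from multiband
reflectance imagery: band reflectances and vegetation indices (VIs) carry
the spectral signal of canopy closure, while image texture carries
complementary spatial-structure information that keeps discriminating
after the spectral signal saturates or is disturbed by soil background
and illumination. `laitex` implements the full analysis: per-plot feature
extraction, texture-index construction and screening, and a four-family
regression comparison under ten-fold cross-validation — together with a
synthetic scene generator so the entire pipeline is testable end to end
without field data.

## The synthetic canopy model

The generator emulates a single-field trial of `n_plots` varieties
observed on `n_dates` dates (defaults 140 × 5, i.e. 700 plot-date
samples, the design of a typical breeding-nursery campaign).

**Spectral mixing.** A plot with leaf area index $L$ is a two-endmember
mixture. The gap fraction seen from above decays by Beer–Lambert,
$f_b(L) = e^{-k_b L}$ with per-band extinction $k_b$ (default 0.5, a
typical canopy value), so expected reflectance in band $b$ is

$$R_b(L) = s_b\,e^{-k_b L} + \ell_b\,(1 - e^{-k_b L}),$$

with soil and leaf endmember spectra $s_b, \ell_b$ given as documented
piecewise-linear curves (`default_soil_spectrum()`,
`default_leaf_spectrum()`). The curves satisfy $\ell < s$ through the
visible and red edge up to ~717 nm and $\ell > s$ at 740–842 nm, which
fixes the sign structure of band/LAI correlations and makes every ratio
index increase with LAI.

**Spatial texture.** Within a plot, a Gaussian random field smoothed at
correlation length `gap_scale` (default 4 px) is thresholded *by rank* so
that exactly a fraction $f_b(L)$ of pixels expose soil; the remainder
take the leaf spectrum. Rank thresholding makes the realized gap
fraction exact, so the image mean reproduces $R_b(L)$ up to sensor noise
and a one-pixel rounding term — a property the tests assert. Because the
pattern is driven by the gap fraction, co-occurrence statistics change
monotonically with canopy closure and within-plot variance peaks at
intermediate cover.

**Nuisance terms.** Three field realities are simulated at the plot-date
level and are individually switchable:

* multiplicative brightness factors on the soil and leaf spectra
  (`soil_jitter_sd = 0.15`, `leaf_jitter_sd = 0.08`), emulating soil
  moisture/variety brightness differences;
* an additive reflectance offset common to all bands
  (`illum_sd = 0.012`, about twice the sensor noise), emulating the
  residual illumination/BRDF and shadow differences that panel
  calibration of a mosaicked scene does not remove. This term matters:
  ratio-type vegetation indices largely cancel multiplicative effects
  but *not* additive ones, whereas min–max-quantized co-occurrence
  structure is insensitive to both — which is exactly why texture
  indices add information to spectral indices in this analysis;
* ground-truth measurement error on LAI (`lai_obs_sd = 0.15` m²/m², a
  ceptometer-scale error), applied to the values written to `plots.csv`.

Additive Gaussian sensor noise (`noise_sd = 0.005` reflectance) is added
per pixel and clipped to [0, 1]. True LAI trajectories follow a
rise-and-fall phenology (sine bump over the dates, from tasseling to
milk ripening) with a persistent per-plot variety offset, clamped
strictly inside `lai_range` (default 0.5–6.5 m²/m², a plausible span for
140 maize varieties across five growth stages; no published
per-stage distribution was available to calibrate against).

**What the generator does not emulate:** radiative transfer (no
PROSAIL-level fidelity), BRDF geometry, variety-specific spectra, row
structure, weeds, or mosaicking artifacts beyond the additive offset.
Passing tests therefore demonstrate the *internal correctness and
statistical behavior* of the pipeline, not field-level accuracy claims.

## Feature extraction

**Rasters and ROIs.** Scenes are multi-page 32-bit TIFFs (one page per
band) with a JSON band-registry sidecar; bands are addressed by center
wavelength, never by position, so any subset containing 650/705/842 nm
works. ROIs live in 0-based pixel coordinates; rectangles are half-open
and polygons use the pixel-center rule. Radiometric calibration is the
standard single-panel zero-intercept gain
$\rho = \mathrm{DN} \cdot \rho_\text{panel}/\mathrm{DN}_\text{panel}$.

**Vegetation indices.** Eight indices over blue 475, red 650, red edge
705 and NIR 842 nm: NDVI, NDRE, MTCI, DVI, RVI, CI~red edge~, EVI,
OSAVI. The MTCI variant used here has the red band in its denominator,
and OSAVI is the $(1+0.16)$ form; both are implemented exactly as used
in this analysis dialect rather than reconciled with other literature
forms. A denominator of exactly zero raises a domain error — screening
treats such rows as missing rather than propagating infinities into
correlations.

**GLCM texture.** Per band raster the pipeline computes windowed
gray-level co-occurrence maps: linear min–max quantization to `levels`
gray levels over the *full raster* (per-window scaling would destroy
cross-plot comparability of the `mean`/`var` statistics), then per pixel
a GLCM from its centered window at each offset, each normalized and
symmetrized, averaged over offsets with equal weight, and summarized by
the eight statistics mean, var, hom, con, dis, ent, sm, cor (entropy in
natural log; correlation defined as 0 when a marginal variance is 0, so
flat plots do not propagate NaN). Statistics are computed on the
offset-averaged GLCM, not averaged per-offset statistics — one
convention, tested as such. Defaults — 64 levels, 3×3 window, the four
unit directions, symmetric — correspond to a common ENVI-style
occurrence-texture configuration; the original tool settings behind such
analyses are typically unstated, so these are declared, overridable
defaults rather than inferences. Border pixels are missing; ROI means
over the valid pixels give the 24 texture features (8 stats × 3 bands).

## Texture indices and screening

Three pairwise forms over texture feature values $T_1, T_2$:

$$\mathrm{NDTI} = \frac{T_1 - T_2}{T_1 + T_2},\qquad
  \mathrm{RTI} = \frac{T_1}{T_2},\qquad
  \mathrm{DTI} = T_1 - T_2.$$

All **ordered** pairs of the 24 features are traversed (576 per kind,
diagonal included but degenerate): |r| is order-invariant for NDTI/DTI
but not for RTI, and published selections name specific ordered pairs,
so the ordered superset is the safe convention. Cross-band pairs are
included. Each index column is correlated with LAI
(pairwise-complete Pearson, so isolated domain errors do not delete a
whole feature), and the best pair per kind is selected with a
deterministic lexicographic tie-break — note NDTI always ties with its
pair-transpose at $\pm r$, so the tie-break decides the reported
ordering.

Screening reports Pearson r, the two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, and raw significance stars
(\* p<0.05, \*\* p<0.01) with **no multiple-testing correction** — the
conventional raw-star reporting for correlation panels; the output notes
the caveat. Vegetation indices with $|r| \ge 0.700$ (configurable) form
the `VIs` input set; the three selected texture indices form `TIs`;
their union `VIs+TIs`. Correlations pool all dates into one sample, the
same pooling the cross-validation uses.

## Models and evaluation

All families run on identical ten-fold splits (for n = 700: exactly
630 calibration / 70 validation per fold). Calibration metrics come from
in-fold training predictions, validation metrics from the held-out fold;
the reported Cal/Val numbers are across-fold means. Anything fitted —
scaler, SVM, PLSR latent-variable count, RF mtry — uses the training
fold only, a property the permutation (leakage) tests verify.

* **SVM** — RBF kernel, cost 1.00, kernel parameter g = 3.03, on
  z-scored features. Two readings of a "kernel function parameter g"
  exist: the libsvm coefficient γ, or the MATLAB-style kernel *scale*
  with γ = 1/g². The scale reading is used here (γ ≈ 0.109): taken as
  the raw libsvm γ, 3.03 makes the kernel radius so small that
  validation skill collapses as soon as features are added, the
  opposite of how this family behaves in spectral-textural fusion
  studies; γ ≈ 0.109 is also the magnitude (≈ 1/p) every standard
  heuristic recommends at these feature counts. An explicit `gamma`
  override restores the literal reading if wanted.
* **RF** — 200 trees (`ranger` backend, single-threaded, seeded). mtry
  is tuned per training fold by out-of-bag error over the grid
  {1, ⌈p/2⌉, p}. OOB is the forest's built-in internal validation and
  costs one fit per grid point; an inner CV over all p values would be
  ~25× more expensive for no practical gain at these problem sizes.
* **BPNN** — single hidden layer of 10 units, linear output
  (`nnet`), weight decay 0.5 on standardized inputs, up to 500
  iterations. A "10 hidden layers, 1 output layer" description is read
  as 10 hidden *units* — a 10-layer perceptron on ≤11 features with 630
  samples would be pathological; a config override allows any topology
  `nnet` accepts. The decay value is chosen so the network is properly
  regularized for this sample size: with weak decay a 10-unit network
  memorizes pure noise (strongly negative validation R² under permuted
  responses), while from 0.01 up to about 1 the genuine validation
  skill is flat (±0.005), so the noise behavior, not the signal, pins
  the choice. `nnet` optimizes by BFGS, which has no learning-rate
  parameter; the conventional lr = 0.01 is carried in the model spec
  for provenance.
* **PLSR** — `mixOmics` PLS in regression mode; the latent-variable
  count is chosen per training fold by inner 5-fold CV over
  1..min(p, 8), minimizing RMSE.

Metrics: $R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ (negative
values possible on validation data), RMSE, and RPD = sd(y)/RMSE with the
**population** (divisor n) standard deviation — that convention makes
the constant-mean-predictor identity RPD = 1 exact, which the tests
assert. A perfect fit reports RPD = Inf. The summary layer averages each
metric across families per input set and split and reports percent
changes of the fused set against each single set, both signed and as
positive magnitudes with an increase/decrease label (the form used in
prose).

## Numerical choices and degenerate inputs

* TIFF samples are stored as 32-bit integers by the codec; written
  values are snapped to the representable grid so a read file re-writes
  losslessly (first-write quantization ≤ 2⁻³³).
* Quantization maps a constant raster to level 0; windows constant after
  quantization have contrast exactly 0 and correlation defined as 0.
* Zero denominators (VIs, NDTI, RTI) raise domain errors at the scalar
  API and become missing values in vectorized traversal.
* Fold assignment, gap fields, forests and network initializations are
  all seeded through one deterministic seed-derivation chain; identical
  seeds reproduce results byte for byte.
* Ties in mtry tuning go to the smallest mtry; ties in index selection
  are lexicographic.

## Problem sizes used by the test suite

The acceptance-level checks run the full design (140 × 5 plots at 64×64
px, 700 samples; model comparisons across five experiment seeds).
Module-level property checks use a reduced trial (60 plots × 3 dates at
48×48 px) and a noise-free 70 × 5 variant for the recovery test, sizes
at which every property asserted is already stable.

## Known limitations

* The synthetic scene is a statistical stand-in: conclusions about
  *field* accuracy require real imagery and ground truth.
* The fixed SVM hyperparameters are taken as given, not re-tuned; they
  are demonstrably sub-optimal for larger feature sets.
* No feature-importance analysis, no stage-stratified screening, no
  hybrid spectral×texture index search — deliberately out of scope.
* Georeferencing is pixel-space; real orthomosaics must be supplied with
  ROIs in pixel coordinates of the same grid.
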