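---
title: "Methods: peri-lymphatic gradient, localization and rhythm quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-lymphatic gradient, localization and rhythm quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilymph)
```

`perilymph` quantifies dendritic-cell trafficking into skin lymphatic
capillaries from whole-mount fluorescence imaging: chemokine gradients as
a function of distance from the vessel, inside/outside-vessel cell counts,
migration-track statistics, and 24-h rhythmicity of any of these readouts.
This vignette is the package's own account of the underlying models, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices a user should know about.

## Coordinate and distance conventions

All arrays are stored `(y, x)` or `(y, x, z)` with a per-axis voxel size
in micrometres; the voxel with 0-based index *i* has its centre at
`i * spacing`. Every physical quantity downstream (distances, volumes,
track coordinates) is in µm, never in pixels — the I/O layer refuses
stacks without spacing.

**Distance transform.** For a binary vessel mask, `distance_transform()`
returns, for every voxel, the exact Euclidean distance from its centre to
the centre of the nearest mask voxel, using per-axis spacing (confocal
stacks are anisotropic: 0.5 µm in xy, 1 µm steps in z). We deliberately
define distance to the nearest *foreground voxel centre* rather than to a
sub-voxel mask boundary: manual outlines give no sub-voxel geometry, and
the voxel-centre definition is exactly testable against brute-force
search (the test suite asserts equality, not approximation). It differs
from a polygon-boundary distance by at most half a voxel diagonal. The
implementation is the separable lower-envelope (Felzenszwalb–Huttenlocher)
algorithm on squared distances, which remains exact under anisotropic
spacing because squared Euclidean distance is additive over axes; it is
compiled (Rcpp) and handles 256×256×30 stacks in milliseconds.

**Zones.** `make_zone_map()` bins distances into half-open bands
`[a, b)`: label 0 is the vessel itself, the last label is a sentinel for
"beyond the last edge", so the labels always partition the grid. Default
edges `c(0, 10, 20, 40, 80)` µm; the band widths of the original zone
analysis are not published, so the default is a configuration choice, not
a claim.

## Gradient profiling

Interstitial chemokine signal is quantified on maximum-intensity
projections. Each non-vessel pixel contributes to the 1-µm bin at
`round(distance)` (half away from zero, matching the "rounded" metric
distances of the original analysis); `distance_profile()` reports the
per-bin mean intensity and pixel count, omitting empty bins and
discarding bins beyond `max_distance` (default 100 µm — unpublished in
the source analysis, chosen to cover the interstitial field of typical
ear-skin stacks).

Fields of view are averaged with *equal weight* (not pixel-weighted):
five images from one ear form one biological replicate, as intensities,
not pixels, are the replicated quantity. Bins absent from some fields are
averaged over the fields that contain them, with the contributing count
reported.

**Normalization.** `normalize_group()` implements the day-anchored
convention: every profile in a day/night pair is divided by the maximum
over bins of the day-set mean profile, so the day mean profile peaks at
exactly 1 and the night peak directly reads out the day:night contrast.
The operation is idempotent. **Isotype subtraction** clamps negative
differences to 0 by default — fluorescence below the nonspecific
background carries no signal, and clamping keeps subsequent normalization
stable; `clamp = FALSE` restores signed differences.

**Decay refit.** `fit_decay_length()` refits
$I(d) = I_0 e^{-d/\lambda} + b$ by nonlinear least squares with a
log-linear initialisation. With a free baseline, $\lambda$ and $b$
become jointly weakly identified when the field of view ends within
~2–3 decay lengths (the λ = 40 µm case on a 96-µm field); tests that
target recovery of λ therefore supply the known simulation baseline, and
the free-baseline fit is exercised where the geometry identifies it.

## Cell localization

A cell is **inside** a vessel iff the voxel containing its centroid is
mask foreground (voxel `floor(c/s + 1/2)` per axis). The original assays
decided this by visual 3D inspection; the centroid rule is the
deterministic, testable surrogate, and boundary cells resolve by centroid
only. Inside counts are normalized to the mask volume of the same image
field (cells/µm³); the in/out ratio is reported as undefined — not
infinite — when no cell lies outside. Per-cell distances are the distance
map value at the centroid's voxel; an optional "surface distance"
subtracts a configured mean vessel radius (the original analysis used a
40-vessel average diameter as a proxy) and floors at 0.

**GOLPH4 ratio.** Within the LYVE-1 mask, pixels above the configurable
GOLPH4 quantile (default upper quartile — "GOLPH4-high" is not defined
quantitatively in the source) form the Golgi-high region; the
isotype-subtracted mean chemokine intensity of high and low regions and
their ratio quantify Golgi-localized versus vesicular chemokine pools.

## Rhythm analysis

**Cosinor.** `cosinor_fit()` fits
$y = M + \beta_c \cos\omega t + \beta_s \sin\omega t$, $\omega = 2\pi/P$,
by ordinary least squares; amplitude $A = \sqrt{\beta_c^2+\beta_s^2}$,
acrophase $\phi = \mathrm{atan2}(\beta_s, \beta_c)/\omega \bmod P$, and
rhythmicity is the F-test of $(\beta_c, \beta_s) = 0$ (zero-amplitude
test). The period is fixed at 24 h: four samples per cycle cannot
identify a free period. All replicates are fitted (not replicate means);
the fit is phase- and scale-equivariant, and its type-I error is
calibrated by simulation in the acceptance suite. Degenerate designs
(< 3 distinct times, collinear regressors) are rejected; a perfect or
saturated fit reports p = 0 or 1 explicitly rather than an F ratio of
two zeros.

**Screen normalization.** Per molecule and tissue: subtract the mean
isotype MFI (clamp at 0), divide by the *second-highest* corrected value
across ZTs (the second order statistic, so tied maxima normalize to 1.0),
and flag "no/low expression" when the maximum raw MFI is below 1.5% of
the screen-wide maximum. Fold-change matrices are pairwise ratios with
NA (never Inf) for zero denominators, satisfying
$M_{ij} M_{ji} = 1$ for positive inputs.

**Integration.** Collapsing many rhythmic profiles into one graph
requires a per-profile rescaling the source does not specify; the default
is min–max to [0, 1], with z-score and peak-normalization behind
`method =` — the choice affects the amplitude, not the phase, of the
integrated profile. Flat profiles cannot be min–max rescaled and are
excluded with a warning.

**Detrending.** Relative bioluminescence is the photon-count series minus
its centered 24-h moving average (subtraction, because it is exact for
additive trends — a linear ramp detrends to numerically zero; division is
available via `method = "divide"` for multiplicative trends). The first
and last half-windows are dropped, so the output is `window − 1` samples
shorter than the input.

## Track metrics

From ordered (t, x, y) samples: accumulated distance (summed step
lengths), Euclidean distance (net displacement), **directionality** =
Euclidean/accumulated ∈ [0, 1] (the "directness" measure of standard
chemotaxis tools; the original figures report it in arbitrary units, and
we make the definition explicit rather than claiming numeric equality
with that tool), and velocity = accumulated distance over elapsed time
(mean path speed; mean instantaneous speed is also reported). Frame
windows are 1-based and inclusive ("frames 31 to 300" keeps 270 frames);
tracks left with fewer than two samples, or containing detection gaps
larger than `max_gap` (default 2 frames), are dropped and counted.

## The synthetic world

The generator exists so that every stage has inputs with known ground
truth. Its defaults are fixed once and stated here:

- **Scene**: 256×256×30 voxels at (0.5, 0.5, 1.0) µm — the size and
  anisotropy of a 30-µm confocal whole-mount stack — holding one gently
  curved capsule (polyline within radius 15 µm, the calibre of a
  lymphatic capillary). Tests use smaller grids for speed; the geometry
  model is identical.
- **Gradient**: $I(d, t) = I_0(t)\, e^{-d/\lambda} + b$ with λ = 20 µm,
  b = 10. The exponential form is a simulator choice: the source
  demonstrates a decaying peri-lymphatic gradient but asserts no
  functional form.
- **Circadian modulation**: $I_0(t) = 150 + 50\cos(2\pi(t-7)/24)$, i.e.
  mesor 150, amplitude 50, acrophase ZT7 — by day (ZT7) the peak
  intensity is exactly twice the night (ZT19) value, the 2:1 day/night
  contrast the assays revolve around, peaking in the rest phase as
  observed for the chemokine.
- **Noise**: additive Gaussian, σ = 15 (10% of mesor I₀), clamped at 0
  for photon-like positivity. Gaussian rather than Poisson keeps
  closed-form test tolerances; a Poisson option was considered and left
  out of scope of the stated world.
- **Cells**: placed on vessel/interstitial voxels (weighted by a distance
  density or per-zone weights) at voxel centres plus ≤ 0.3-voxel jitter,
  so each cell's true compartment and zone are known exactly.
- **Tracks**: correlated random walk at the live-imaging cadence (one
  frame per 100 s, ~30 steps ≈ 50 min); new heading = normalized mixture
  of previous heading (persistence 0.5) and a fresh random direction,
  then of the bias direction (bias weight); log-normal steps with median
  5 µm — a few µm/min, the speed scale of activated dendritic cells.
  Bias 1 gives perfectly straight tracks (directionality exactly 1).
- **Bioluminescence**: baseline 100 + slope·t + damped 24-h cosine
  (amplitude 50, damping 0.01 h⁻¹) + noise, per minute over 96 h.

Every generator is a pure function of (spec, seed); ground truth is
emitted alongside the data and no analysis stage reads it.

**What a green test does not establish.** The simulator produces smooth
tubes, a stationary exponential gradient, isotropic Gaussian noise and
point-like cells. It does not emulate vessel branching, staining
heterogeneity, depth attenuation, cell shape, optical blur, or detection
noise in tracking. Green acceptance tests establish that the
*quantification* is correct on a known world — not that the biological
effect sizes of any particular experiment are reproduced.

## Numerical and design choices

- Half-open bins everywhere (`[a, b)`); a distance exactly at an edge
  belongs to the upper band.
- Profile bins are 1 µm at integer centres via round-half-away-from-zero.
- Ratios with empty denominators are NA with an explicit `*_defined`
  flag, never ±Inf.
- The cosinor acrophase is reported in [0, 24) h; comparisons in tests
  use circular distance.
- CLI exit codes: 0 success, 2 validation error (bad arguments, rejected
  before I/O), 1 runtime failure. Identical config + seed gives
  byte-identical tabular outputs.
- TIFF support is a minimal built-in baseline codec (uncompressed
  grayscale, 8/16-bit unsigned and 32-bit float, multi-page, both byte
  orders) because no TIFF package is available in the target R stack;
  it is round-trip tested and was cross-validated against an independent
  TIFF implementation during development. Compressed or multi-sample
  TIFFs are rejected with a clear error.

## Known limitations

- Distances are voxel-centre based; sub-voxel boundary distances differ
  by up to half a voxel diagonal.
- Vessel masks are inputs (manual outlines or simulation); there is no
  automatic segmentation.
- The cosinor is single-component with fixed period; no free-period or
  nonparametric rhythm detection (JTK/RAIN-style) is provided.
- The decay-length refit needs either a field of view several λ deep or a
  known baseline to pin λ tightly (see above).
- 2D gradient profiling on projections compresses z-structure; cell
  localization operates in 3D, profiling in 2D by design.
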