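# perilymph

Quantification of peri-lymphatic chemokine gradients, dendritic-cell (DC)
localization and circadian rhythmicity in skin whole mounts.

## The problem

Dendritic cells leave the skin through lymphatic capillaries, guided by a
CCL21 chemokine gradient that is displayed on the interstitial matrix
around LYVE-1⁺ vessels and sensed through CCR7. Whether (and when) this
trafficking is under circadian control is measured with ex vivo "crawl-in"
assays: cells are counted inside versus outside vessel masks, their
accumulation is profiled as a function of distance from the vessel, their
migration tracks are scored for speed and directness, and per-time-point
readouts collected at ZT1/7/13/19 are screened for 24-h rhythmicity.

`perilymph` re-implements that quantification stack as a tested, reusable
R package, together with a synthetic-scene simulator that generates every
input with known ground truth, so the whole pipeline can be validated
without microscope data.

## What it computes

- **Geometry** — binary vessel masks from polygon outlines; the *exact*
  anisotropic Euclidean distance transform D(v) = min over foreground f of
  ‖(v − f) ⊙ s‖₂ (voxel centres, spacing s in µm; Rcpp); half-open distance
  zones [a, b); mask volume/area.
- **Gradient profiling** — maximum-intensity projections; distance-binned
  mean fluorescence I̅(d) with 1-µm bins at round(d); unweighted replicate
  averaging; day-anchored normalization (all profiles scaled by the
  day-set peak); isotype subtraction; exponential refit
  I(d) = I₀·e^(−d/λ) + b.
- **Cell localization** — inside/outside classification by the centroid's
  voxel, counts normalized to vessel volume (cells/µm³), in/out ratio,
  per-cell vessel distances, zone-wise relative distributions,
  GOLPH4-high/low chemokine MFI ratios.
- **Rhythm analysis** — fixed-period cosinor
  y(t) = M + A·cos(2π(t − φ)/24) by least squares with the zero-amplitude
  F-test; immunofluorescence-screen normalization (isotype subtraction,
  second-highest-ZT scaling, 1.5 %-of-max expression flag, ZT fold-change
  matrices); min–max profile integration; 24-h centered moving-average
  bioluminescence detrending; one-way ANOVA with Tukey post test.
- **Track metrics** — accumulated and Euclidean distance, directionality
  (directness = Euclidean/accumulated ∈ [0, 1]), mean path velocity,
  1-based inclusive frame-window trimming, origin normalization.
- **Simulation** — capsule-vessel scenes with exponential gradients whose
  peak intensity follows a 24-h cosine; seeded cell placements with known
  compartments; biased persistent random-walk tracks; damped rhythmic
  bioluminescence.

## Worked example

```r
library(perilymph)

## a day (ZT7) and a night (ZT19) synthetic scene; the default world has
## peak intensity I0(t) = 150 + 50 cos(2*pi*(t - 7)/24): 200 by day,
## 100 by night (2:1)
spec  <- scene_spec(shape = c(128L, 128L), spacing = c(0.5, 0.5),
                    radius_um = 6)
day   <- gen_scene(spec, time_label = 7,  seed = 1)
night <- gen_scene(spec, time_label = 19, seed = 2)

prof_day   <- distance_profile(day$scene$intensity$ccl21,
                               day$truth$dmap,   max_distance = 60)
prof_night <- distance_profile(night$scene$intensity$ccl21,
                               night$truth$dmap, max_distance = 60)
nz <- normalize_group(list(prof_day), list(prof_night))
round(nz$constant, 1)                            # 201.8
round(max(nz$night[[1]]$mean_intensity), 3)      # 0.524

## refit the decay length from the profile (truth: lambda = 20 um)
round(fit_decay_length(prof_day, baseline = 10)$lambda, 2)   # 20.04

## inside/outside counting on the same scene
cells <- gen_cells(day$scene, n_cells = 60, inside_fraction = 0.4, seed = 3)
classify_in_out(cells$cells, day$scene)
#> <in_out_result> in: 24  out: 36  vessel volume: 826.5 um^2
#>   density: 0.02904 cells/um^2

## cosinor screening of a rhythmic readout
s <- gen_rhythm_series(mesor = 10, amplitude = 4, acrophase_h = 7,
                       sigma = 1, n_per_time = 5, seed = 4)
cosinor_fit(s$time_h, s$value)
#> <cosinor_fit> mesor 10.38, amplitude 4.2, acrophase 6.83 h (period 24 h)
#>   zero-amplitude test: F = 131, p = 4.78e-11, n = 20
```

The normalization constant is the day profile's peak mean intensity
(≈ I₀ + b = 210 expected); the night peak of ≈ 0.52 recovers the simulated
2:1 day/night contrast; the cosinor recovers the 7-h acrophase with a
decisively rejected zero-amplitude null.

## Command line

```sh
inst/cli/perilymph simulate scene --seed 1 --time 7 --out run/
inst/cli/perilymph gradient --image run/scene.tif --mask run/mask.tif \
    --out run/profile.csv
inst/cli/perilymph rhythm  --series series.csv --out fit.json
inst/cli/perilymph tracks  --in tracks.csv --trim 31:300 --out metrics.csv
inst/cli/perilymph run     --seed 1 --out run/   # simulate->gradient->cosinor
```

Exit codes: 0 success, 2 validation error, 1 runtime failure. Identical
arguments and `--seed` give byte-identical tabular outputs.

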