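# blurkit

Quantify — and then minimise — the spatial smoothing that fMRI
preprocessing sneaks into high-resolution data.

## Who this is for

High-resolution (≥7T, ~1 mm and below) fMRI studies of cortical columns and
layers operate at the limit of what the acquisition can resolve. Every
preprocessing step that interpolates the data — motion correction,
anatomical registration, volume-to-surface projection, distortion
correction — acts as a small convolution and erodes the *effective*
resolution, nonuniformly across the brain, even while the nominal voxel
size is unchanged. blurkit is for analysts who want to measure that loss
per preprocessing pathway, report it as a "spatial error bar", and adopt
the pipeline choices that keep it small.

## The core idea

Push a 4D series of i.i.d. unit-variance white noise through the exact
preprocessing pathway under study. Spatial mixing averages independent
samples, so each location's temporal standard deviation (TSTD) drops below
1; for a convex interpolation with weights *w* the output TSTD is
√Σw². Calibrating TSTD against explicit 3D Gaussian smoothing of known
width (FWHM 0.1–3.9 mm, σ = FWHM / (2√(2 ln 2))) gives a monotone lookup
table, so the measured TSTD of any pathway converts into the width of the
equivalent Gaussian kernel in mm — a number you can put next to an
activation map. The flat sub-voxel part of the table (its *plateau*) sets
the minimal blur detectable on a given grid; blur-free pathways report the
plateau edge.

Around this calibration the package implements the anti-blur toolbox:
volume upsampling before resampling, rigid-transform composition and
single-interpolation surface projection, midpoint mesh refinement with
unique-voxel accounting, radial-only intracortical smoothing, a
motion-estimation accuracy simulation across voxel sizes, Jacobian
voxel-size maps for geometric distortion, and a Dice-overlap benchmark on
interdigitated columnar stripe phantoms that are non-overlapping by
construction. Synthetic generators (folded cortical sheets, stripe truths,
block-design BOLD runs with a gamma HRF, motion traces, smooth phantoms)
make every stage runnable with no external data.

## Worked example

```r
library(blurkit)

# Calibrate a TSTD -> FWHM lookup for a 1-mm grid
lut <- build_lookup(1.0, nframes = 300, seed = 1, dim = 48)
plateau_edge(lut)
#> [1] 0.5

# Audit two projection pathways onto a synthetic folded cortical sheet:
# a composed rigid transform + single nearest-neighbour interpolation,
# versus trilinear interpolation
sheet <- make_cortical_sheet(extent = 40, spacing = 1, seed = 1)
reg   <- rigid_from_params(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))  # deg / mm
grid  <- voxel_grid(c(64, 64, 64), 1)

nn  <- blur_audit(function(noise) vol2surf(noise, sheet$white, reg, "nearest"),
                  grid, lut, nframes = 1000, seed = 11)
tri <- blur_audit(function(noise) vol2surf(noise, sheet$white, reg, "linear"),
                  grid, lut, nframes = 1000, seed = 11)
glance(nn)$mean_fwhm  - plateau_edge(lut)
#> [1] 0.06451587
glance(tri)$mean_fwhm - plateau_edge(lut)
#> [1] 0.6789267
```

Read: projecting through a single nearest-neighbour step adds only ~0.06 mm
of equivalent Gaussian blur beyond the 0.5-mm detection floor of a 1-mm
grid, while trilinear projection of the same data costs ~0.7 mm of
effective resolution. `autoplot(nn)` shows the per-vertex FWHM histogram;
`tidy(lut)` / `autoplot(lut)` expose the calibration curve.

The same `blur_audit()` wraps any pathway — e.g.
`function(v) motion_correct(v, trace, "linear")` — and
`strategy_comparison()` scores full pipelines by the Dice overlap of two
independently analysed, ground-truth-disjoint stripe systems (less blur ⇒
less overlap).

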