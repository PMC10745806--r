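---
title: "Quantifying axon collateral branching with axoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon collateral branching with axoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoquant)
```

## The problem

A growing motor axon — for instance a zebrafish caudal primary (CaP)
motor axon between 24 and 48 hours post-fertilization — extends lateral
collaterals along its shaft. Manual collateral tracing is slow and
observer-dependent; `axoquant` instead asks the user only for the easy,
robust piece of manual input (the path of the axonal shaft on a maximum
intensity projection) and automates everything downstream: straightening,
segmentation, skeletonization, density profiling, scalar branching
metrics, and group statistics.

The package assumes the input stack has been cropped to a single axon
without cell bodies, that the trace is ordered proximal (dorsal) end
first, and that in-plane pixel sizes are known (from TIFF metadata, a
JSON sidecar, or an explicit override — a missing pixel size is an error,
never a silent default).

## Straightening

The trace polyline is resampled at uniform arc-length steps equal to the
source pixel size along y. Unit tangents come from central differences of
the resampled path; the transverse direction is the tangent rotated so
that, for a trace running down the image, positive offsets point towards
+x. Each output pixel is a bilinear sample of the source at
`p(s) + t · n(s)`; samples outside the source are zero-filled and flagged
in a validity mask that travels with the image, so no later average ever
sees out-of-bounds values.

Numerical choices worth knowing:

* The column count is `width_um / pixel_size_x` rounded to the nearest
  odd integer, so an exact centre column exists and the shaft sits on it.
* Central-difference normals are a deliberate, stated choice; common
  interactive straightening tools fit and smooth the line slightly
  differently, and no published macro pins the exact variant down. For an
  axis-aligned straight trace the result equals the axis-aligned crop
  exactly, and a 90° rotation of image + trace changes the band only at
  interpolation level (both properties are tested).
* A zero-length trace is rejected; consecutive duplicate vertices are
  rejected at trace construction.

`trace_length()` is the plain Euclidean polyline length and works for 2D
and 3D traces; `project_to_2d()` drops z (merging vertices that become
coincident), and projection can only shorten a path — the package's way
of mirroring the comparison between full-3D path lengths and their 2D
projections.

## Collateral mask

Three steps, each exposed separately and composed by `make_mask()`:

1. **Threshold.** Default is Otsu's criterion on the histogram of valid
   pixels (256 levels). "Automatic thresholding" in fluorescence
   workflows almost always means Otsu or a close variant; since the exact
   flavour is not recoverable, Otsu is the default and a fixed threshold
   is the escape hatch. A constant image yields an empty foreground, not
   an error. Invalid pixels are always background.
2. **Skeletonize.** Zhang–Suen thinning to a one-pixel-wide,
   8-connected skeleton. 8-connectivity is used everywhere for
   consistency.
3. **Length filter.** A component's length is the maximum geodesic path
   length over its pixel graph, with physical edge weights
   (`pixel_size_x`, `pixel_size_y`, or their Euclidean diagonal). This is
   a physical length, not a pixel count — pixel counts overestimate
   diagonal runs. The minimum is strict: a component of exactly 0.5 µm is
   removed, only strictly longer components survive. Components are found
   and measured on a weighted igraph adjacency graph; tests compare every
   length against an independent all-pairs shortest-path oracle.

The filter runs before shaft-band excision (the shaft itself survives as
one long component and is removed geometrically by the band, not by
length). Re-running `make_mask()` on a clean mask returns it unchanged.

## Shaft excision, densities and profiles

A 5 µm longitudinal band centred on the shaft column is *flagged*
excluded rather than deleted, so transverse positions keep their physical
meaning and plots show a visible gap. Densities are computed over
transverse bins of 4 consecutive columns (0.9932 µm at the reference
pixel size 0.2483 µm/px, chosen so the two numbers reproduce each other
exactly); bins are laid out outward from the band edges, so the bins
adjacent to the shaft — where most collaterals emerge — are always
complete, and partial bins at the image edges are dropped. A bin cell's
value is its foreground-pixel count divided by the cell area
(collaterals/µm²); on straightened intensity images the same machinery
yields intensity/µm². Counting foreground pixels (rather than distinct
components) per cell is a stated interpretation: at the 1-row × 4-column
cell scale, components are not resolvable.

Two exact identities are built in and tested: summed density × cell area
equals the covered foreground pixel count (integer identity), and the
transverse and longitudinal profiles, weighted by their per-position
valid-cell counts, both reproduce the grand mean density. Group profile
values are pooled means over all valid cells (per-image means are kept
separately as the observations for statistics — pooling is what makes the
weighted-mean identity exact).

Group stacks are top-aligned (proximal ends registered) and padded with
excluded pixels, because longitudinal positions are measured from the
top; average and maximum projections ignore padding.

## Branching metrics

"Total branching" is defined as collateral skeleton length (µm) divided
by axon length (µm) — a dimensionless, scale-aware ratio. The skeleton
length metric is the same diagonal-aware edge metric as the component
filter: every adjacency between two valid foreground pixels contributes
its Euclidean step length, shared half-and-half between its two pixels.
The per-pixel sharing makes the regional split exact: dorsal (first
70 µm, normalized by 70 µm) and ventral (the remainder, normalized by its
own length) satisfy
`dorsal·70 + ventral·(L − 70) = total·L` identically. Each region is
normalized by its own extent so dorsal values are comparable between
young axons (whose whole length is ≈ 70 µm) and older, longer ones. An
axon not longer than the dorsal extent reports ventral branching as
missing, not zero. Component counts are exposed alongside as a secondary
robustness check; the pipeline deliberately does not classify branch
order.

## Group statistics

Scalar comparisons are gated on normality: both groups must pass
Shapiro–Wilk at α = 0.05 for a pooled-variance two-sided Student *t*
test, otherwise a two-sided Mann–Whitney test is used. All tests are
two-sided. Mann–Whitney p-values are exact (full rank-assignment
distribution) for tie-free data when the smaller group has ≤ 8
observations, and otherwise use mid-ranks with tie-corrected variance and
continuity correction. The continuity-corrected normal approximation
tracks the exact distribution to within 0.02 wherever the exact p ≤ 0.25
and to within 0.04 everywhere at these sizes — an inherent property of
the approximation, checked exhaustively in the test suite; the exact path
is what actually runs at small n.

Profile comparisons run one Mann–Whitney test per shared position (the
per-image profile values being the observations; positions with fewer
than 3 valid observations in either group are excluded and reported) and
control the FDR across all tested positions jointly at q = 0.05. The
default procedure is the two-stage linear step-up of Benjamini, Krieger
and Yekutieli — the documented default of the widely used commercial
statistics package at "q = 5%" — with plain Benjamini–Hochberg
selectable; both are tested against brute-force cutoff scans, and the
null false-discovery proportion is verified by simulation (200 replicates
of 19 vs 20 images over 80 positions).

## The phantom generator

`phantom_spec()` / `generate_phantom()` render a curved shaft plus
collaterals as analytic Gaussian ridges: the intensity at a pixel is the
background plus the maximum over structures of
`peak · exp(−d² / 2σ²)`, with `d` the exact distance from the pixel
centre to the structure's segment. Rendering from analytic distances
(rather than rasterized lines) keeps the ground truth sub-pixel accurate.
Gaussian noise and optional Poisson resampling are applied under the
spec's seed, with the caller's RNG state saved and restored, so a seed
fixes the image bit-exactly.

The presets encode the three regimes the pipeline is meant to
discriminate, with values chosen once as biologically plausible for the
system: `sparse_24hpf` (shaft 66–74 µm, 2–4 collaterals), `dense_48hpf`
(shaft 134–146 µm, 10–20 collaterals biased ventral of 70 µm, terminal
arbor), and `aberrant` (70–80 µm shaft, 8–14 dense dorsal collaterals).
Collateral lengths start at 4 µm in presets and tests: a collateral whose
tip lies within 2.5 µm of the shaft centre falls entirely inside the 5 µm
excision band and is geometrically unrecoverable, and 4 µm leaves a
comfortable margin above the 0.5 µm filter after excision. Shaft peak
intensity is 200 over a background of 10, collateral intensities 120–180
(≥ 3× contrast); the default preset noise (σ = 20) corresponds to SNR 10.

What the phantom does *not* emulate: a realistic point-spread function,
depth attenuation, fasciculation with neighbouring axons, autofluorescent
background structure, or tracing error in the manual path (phantom
analyses reuse the exact ground-truth trace). Passing phantom tests
therefore demonstrates the correctness of the measurement chain, not
robustness to every property of real specimens.

## Problem sizes and runtime choices

The test-suite and acceptance-script simulation sizes are the package's
own verification choices: 1000 random polylines for length checks, 100
random masks for conservation, 10 random 32×32 skeletons for the
geodesic oracle, phantoms with 0–15 collaterals (50 seeds at SNR 5 for
the noisy aggregate), 200 null replicates / 40 shifted replicates for FDR
calibration, and cohorts of 19 vs 20 phantoms for the group-direction
checks — sizes at which every Monte-Carlo margin used in the assertions
is comfortably resolved.

## Known limitations

* The pipeline is 2D; out-of-plane collaterals are foreshortened in the
  projection, and straightening treats the mapping as area-preserving
  (no curvature correction of area elements along bent paths).
* Collaterals shorter than ≈ 2.5 µm of lateral reach vanish inside the
  excised shaft band by construction.
* Branch order (primary vs higher-order collaterals) is not classified,
  and crossing collaterals merge into single mask components.
* Otsu thresholding assumes a reasonably bimodal intensity histogram;
  very sparse or very dim collaterals may require the fixed-threshold
  escape hatch.
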