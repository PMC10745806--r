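# axoquant

Quantification of axon collateral branching from 2D fluorescence microscopy.

Developing motor axons — the canonical example being the caudal primary
(CaP) motor axons of zebrafish embryos between 24 and 48 hours
post-fertilization — elaborate lateral collaterals along their shaft as
they grow. `axoquant` turns a confocal stack of a single axon plus a
manually traced axon path into unbiased, reproducible branching numbers:
where collaterals sit along and across the shaft, how much collateral
length an axon carries per micrometre of shaft, and whether two groups of
axons differ, position by position, under false-discovery-rate control.

## The method

Starting from a maximum intensity projection `I(x, y)` and a manual axon
trace (an ordered polyline, proximal end first), the pipeline computes:

1. **Straightening (STR).** The trace is resampled at uniform arc-length
   steps; at each step *s* the image is sampled bilinearly at
   `p(s) + t · n(s)` for transverse offsets `t ∈ [−w/2, +w/2]`
   (default width `w = 25 µm`), with `n(s)` the unit normal from
   central-difference tangents. Rows of the STR run along the axon
   (row 0 = proximal/dorsal), the shaft sits on the exact centre column.
2. **Collateral mask (MASK).** The STR is thresholded (Otsu by default),
   skeletonized (Zhang–Suen thinning), and every 8-connected component
   whose maximum geodesic path length — with diagonal-aware physical edge
   weights — is not strictly greater than 0.5 µm is removed.
3. **Shaft excision and densities.** A 5 µm longitudinal band centred on
   the shaft is flagged excluded; the remaining mask is binned into
   4-pixel transverse bins (0.9932 µm at the reference pixel size of
   0.2483 µm/px) and converted to collaterals/µm². Transverse profiles
   (mean vs signed distance from the shaft) and longitudinal profiles
   (mean vs distance from the proximal end) follow, per image and pooled.
4. **Branching metrics.** Total collateral skeleton length divided by
   axon length, plus a regional split: dorsal = the proximal 70 µm
   (normalized by 70 µm), ventral = the remainder (normalized by its own
   length).
5. **Group statistics.** Scalars are compared with a Shapiro–Wilk-gated
   Student *t* / Mann–Whitney test; profiles are compared per position
   with two-sided Mann–Whitney tests and a step-up FDR procedure at
   q = 5% (two-stage Benjamini–Krieger–Yekutieli by default, plain
   Benjamini–Hochberg selectable).

A seeded phantom generator renders synthetic axons — a curved Gaussian
ridge shaft with collaterals of known position, side, length and angle,
plus noise — with machine-readable ground truth, so every stage above is
verifiable without real data.

## Worked example

```r
library(axoquant)

sp  <- phantom_preset("dense_48hpf", seed = 7)   # a dense, 48 hpf-like axon
ph  <- generate_phantom(sp)
ph$truth$collateral_count
#> [1] 12

res <- analyze_axon(ph$image, ph$trace)          # full pipeline, defaults
res$str
#> <axo_straightened> 590 rows x 101 cols, width 25.0 um, axon length 146.31 um
res$branching
#> <axo_branching> axon 146.3 um, total 0.617, dorsal 0.087, ventral 1.103, 15 components
```

The axon is 146.3 µm long and carries 0.617 µm of collateral skeleton per
µm of shaft; branching is strongly ventral (1.103 vs 0.087), as built into
the dense preset. 15 mask components are found: the 12 seeded collaterals
plus segments of the terminal arbor that the band excision separates.

A transverse profile and a two-group comparison:

```r
tp <- transverse_profile(list(res$grid))
tp$positions[which.max(tp$values)]   # density peaks just off the shaft
#> [1] 3.10375

# 19 sparse vs 20 dense phantoms, per-position Mann-Whitney + FDR (q = 5%)
cmp <- compare_profiles(tp_sparse, tp_dense, q = 0.05, method = "bky")
sum(cmp$discovery)
```

A command-line front end wrapping the same functions lives at
`inst/cli/axoquant.R` (`straighten`, `mask`, `profiles`, `metrics`,
`compare`, `simulate`, `run-all`).

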