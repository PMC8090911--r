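---
title: "perilyso: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perilyso: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilyso)
```

## The problem and the measurement model

Invasive ErbB2-driven cancer cells position lysosomes near the plasma
membrane, where lysosomal exocytosis supports matrix degradation; effective
repositioning drugs pull them back around the nucleus. A screen for such
drugs needs a scalar per-well readout of "how perinuclear are the
lysosomes", robust enough for plate-based statistics. `perilyso` implements
that readout and everything around it.

The perinuclear ring of a cell is constructed from its segmented nucleus:
erode the label by `shrink_px` (default 2 px = 0.325 µm at the package's
default 0.1625 µm/px), expand it by `grow_px` (default 25 px = 4.0625 µm)
with collision-free nearest-label growth, discard objects touching the
image border, and subtract the eroded nucleus. The growth step is a
Euclidean Voronoi expansion: a background pixel within `grow_px` of any
label joins the nearest label, equidistant ties going to the smallest id.
The tie rule is arbitrary but deterministic and oracle-checkable; the
behaviour of the commercial implementations this mirrors is not published,
so exact agreement with them is out of reach and not attempted.

The **PNLA score** of a field is the mean pixel area of detected lysosome
puncta whose centroids lie in any ring. Its sensitivity comes from a
physical effect: when lysosomes pack into a tight perinuclear shell they
cease to be resolvable spots and are segmented as larger merged objects,
raising the mean member area. Two companion readouts — the fraction of
puncta inside rings and the mean ring intensity — are computed alongside.

Ring membership is *centroid-in-ring* by default (an `overlap` rule is
selectable). Centroid membership is unambiguous for puncta straddling the
ring edge. Fields with no member puncta score 0 and carry a
`no_ring_puncta` flag rather than being dropped: dropping them would bias
cytotoxic wells upward. Scores are pooled across the field and averaged
over fields per well (per-well granularity matches the screen's unit of
intervention); per-cell pooling can be built from
`assign_puncta_to_cells()` if needed.

## Segmentation primitives

All operators share fixed conventions, stated once here and in
`segment_config()`:

* 8-connectivity for foreground components and for holes;
* disk structuring elements rasterized as `{p : ||p|| <= r}`;
* exact Euclidean distances (not chamfer approximations) for shrink and
  grow, so the micrometre calibration of the ring is honest;
* structuring elements clipped at image borders;
* "roundness" is `4*pi*A/P^2` with `P` the Crofton-corrected perimeter
  (`pi/4` times the count of 4-neighbour foreground/background pixel
  edges, the border counting as background). Under this estimator a
  rasterized disk scores ≈ 1 and a thin line ≈ 0.4, so the default
  `roundness_min = 0.6` cleanly separates the two. Perimeter estimators
  that count boundary *pixels* rather than edges score thin lines above
  disks and cannot be used for this filter.

Round-object detection is threshold → connected components → equivalent
circular diameter band → roundness filter, with labels renumbered in
raster-scan order of each component's first pixel. The "appropriate
threshold" of high-content practice is represented two ways: nuclei
default to a per-image Otsu threshold (nuclei are always present, so the
histogram is reliably bimodal), while puncta default to a fixed absolute
threshold (600 on the generator's 16-bit scale, far above background
100 + noise sd 20 and far below spot peaks ~2000). A per-field Otsu
threshold is *wrong* for puncta: at early timepoints a marker channel may
contain almost no spots, and Otsu, which always splits the histogram,
would then threshold inside the noise.

The same pathology motivates the minimum-contrast guard in
`segment_organoids()`: the Otsu threshold of the bottom-hat response must
exceed its median by `min_contrast = 5` raw-scaled MADs, otherwise the
image is declared organoid-free and the mask is empty.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
the optics of a microscope. Defaults (chosen once as the package's study
conditions):

| parameter | default | meaning |
|---|---|---|
| `image_shape` | 192×192 px | one field at 0.1625 µm/px |
| `n_cells` | 10 | non-overlapping nuclei, rejection-sampled |
| `nucleus_radius_range` | 9–14 px | live nuclear radius |
| `puncta_per_cell_range` | 10–20 | lysosome-like spots per cell |
| `perinuclear_bias` | 0.5 | fraction of spots in the perinuclear band |
| `band_px` | 25 px | perinuclear band, mirroring the ring |
| `peri_offset_mean_px` | 4 px | truncated-exponential offset in the band |
| `periph_max_px` | 55 px | outer edge of the peripheral annulus |
| `punctum_sigma_px` / amplitude | 1.5 px / 2000 | Gaussian spot model |
| `background` / `noise_sd` | 100 / 20 | flat background, additive Gaussian noise |
| control biases | 0.1 / 0.9 | vehicle-like vs repositioning-drug-like |

Perinuclear puncta sit at truncated-exponential offsets from the nucleus
boundary rather than uniformly in the band: perinuclear accumulation in
cells is a tight shell around the microtubule-organizing centre, and this
clustering — which makes neighbouring spots merge — is precisely the
signal the mean-area readout needs. Peripheral puncta are uniform in an
annulus strictly outside the band, so the ground-truth radial class is
consistent with the geometry by construction. Dead cells render with half
the nuclear radius and twice the peak intensity. All randomness flows from
one top-level seed through an affine substream split
(`child = (seed * 48271 + 104729 * k) mod (2^31 − 1)`), so identical
spec + seed gives bit-identical output.

What the generator does **not** emulate — and what green tests therefore do
not certify on real data: optics (no PSF beyond the Gaussian spot, no
z-structure), illumination gradients, photobleaching, autofluorescent
drugs (the fixed-and-restain workflow is supported as a separate input set
instead), cell shape (territories are Voronoi regions, not real
membranes), and cell-to-cell heterogeneity beyond Poisson counts.

Organoid pairs are dark disks (default 3500 px² at day 1, level 1200 on a
3000 background) with day-3 area `growth_factor` times day 1 and optional
thin radial protrusions. The day-1 size keeps even a doubled organoid
(diameter ~94 px) within reach of the default 50 px bottom-hat structuring
element; organoids wider than the element would only be rim-enhanced, as
in any closing-based pipeline. The 3 px dilation stage adds
≈ perimeter × 3 px² to each mask; because the bias applies at both days,
the growth metric is only mildly compressed (a true doubling measures
≈ 91 %), which the growth-recovery suite covers with its ±10-point band —
the bias is documented rather than corrected, mirroring the stage order of
the assay it reproduces.

## Plate statistics

`z_factor()` uses sample (n−1) standard deviations — standard screening
practice. `robust_z_scores()` implements the formula exactly as printed
for screening data: raw MAD, no 1.4826 consistency factor (opt-in via
`scale`). The normalization population is the compound wells of the plate,
controls excluded; pooling across plates is a caller decision. No
multiple-testing correction is applied at hit calling — the screen uses a
fixed 2-MAD cutoff, inclusive ("2 or higher").

A consequence worth stating: for approximately Gaussian inert-well
readouts the raw 2-MAD cutoff sits at ≈ 1.35 σ, whose upper tail is
≈ 9 %. Hit lists called this way are *enrichment* lists, not
false-positive-controlled lists — on a 64-compound plate several inert
compounds will typically cross the line, which is why such screens confirm
hits in a secondary screen. The hit-recovery validation suite measures
exactly this behaviour on simulated plates (planted actives are recovered
essentially always; inert crossings occur at the tail rate).

`compare_two_conditions()` defaults to the Welch t-test, with pooled
variance as an option; a bare report of "Student's t-test" leaves the
variant open, and Welch is the safer default.

## Time courses and flux

Per-cell puncta counts are Poisson draws from monotone class profiles:
`early_LMP` is a logistic rise centred at 6 h (width 1.5 h), `late_LMP`
at 18 h (width 2.5 h), `none` stays at the 0.3 puncta/cell baseline;
plateaus default to 6 puncta/cell. Death ramps linearly to
`death_end_frac` (default 0.2) at the last timepoint. Timepoints are
independent — the analysis scores each timepoint separately, so no cell
tracking is simulated or needed.

"Evident" puncta formation is operationalized as the positive-cell
percentage (among live cells) reaching
`max(lmp_rise_factor × baseline, lmp_min_pct)` with defaults 2× and 15 %.
The 15 % floor requires at least two positive cells in a typical 8–12-cell
field; with one cell it would take a single Poisson outlier to declare a
drug an LMP inducer. Classes: *early* if evident strictly before the 12 h
split, *late* at or after it, *none* if never; series that do not span
12 h are refused rather than guessed.

Flux classification thresholds the GFP/RFP mean-intensity ratio within
each punctum at 0.5; the generator renders "red" puncta with GFP quenched
to 0.1× amplitude, so the two classes are well separated even without
background subtraction.

## Numerical choices and degenerate inputs

* Otsu: 256 bins spanning the image range, first maximum on ties,
  threshold reported at the upper edge of the winning bin; constant images
  are an error (no threshold exists).
* `z_factor` with equal control means, robust Z with zero MAD, percent
  change with zero day-1 area, ring intensity on an empty ring set,
  two-sample comparison of two constant samples: all errors with named
  reasons, never silent NaNs.
* Labels annihilated by erosion are dropped and reported; empty nucleus
  masks yield an empty ring set with a warning.
* Grayscale disk filters run by chord decomposition with a sparse-table
  running extreme, padded so window anchors stay in range; they agree
  exactly with the brute-force offset definition, which the test suite
  asserts on random instances.

## Validation scale

The validation suites run at desk scale, chosen to exercise every code
path with tight statistics: 100 random 64×64 instances per morphological
operator against brute-force oracles; 20 fields per bias level across the
9-level bias grid; a 72-well secondary-screen plate (64 compounds, 7
planted actives, 2 fields/well) over 10 seeds; 4 organoid growth factors
noise-free; 10 seeds per LMP class over a 0–24 h course sampled every 4 h.

## Known limitations

* Equivalence with the commercial modules the primitives mirror cannot be
  verified — their algorithms are unpublished; what is reproduced is the
  documented pipeline structure.
* The mean-area PNLA readout depends on segmentation merging behaviour; on
  real images its contrast will vary with staining quality and spot
  density in ways the generator does not model.
* The organoid pipeline assumes dark objects on a bright background;
  inverted-contrast input triggers a warning, not an automatic flip.
* Low false-positive rates at a raw 2-MAD cutoff are statistically
  unattainable for Gaussian-tailed readouts (see Plate statistics); the
  package reproduces the published cutoff rather than "fixing" it.
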