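---
title: "Density-based quantification of spheroid invasion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based quantification of spheroid invasion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherodens)
```

## The measurement problem

A multicellular tumor spheroid (MCTS) embedded in a collagen matrix is
imaged daily in bright-field as cells proliferate and invade outward. The
conventional readouts — counting invading cells, or outlining an "invasive
front" — fail in exactly the interesting cases: a 2-D micrograph is a
cross-section of a 3-D object, so cells overlap and cannot be counted; and
once cells disperse or leave the camera aperture there is no front to
outline. Two spheroids whose outermost cells reach the same distance can
differ enormously in how densely the intervening space is populated.

`spherodens` instead quantifies *binarization density*: it segments the
image, asks what fraction of each small neighborhood is covered by
segmented structure, and integrates that density surface over the frame.
The integral responds both to the size of the spheroid and to how densely
its surroundings are invaded, without ever identifying individual cells or
a front.

## Three-region segmentation

No single segmentation handles both the nearly black core and faint
isolated cells. The pipeline therefore extracts three regions with three
techniques, each tuned to its intensity regime, and unions them:

**Core.** The image is first corrected for uneven illumination: a strong
Gaussian blur (sigma = 1/8 of the smaller image dimension by default)
estimates the illumination field, and each pixel is shifted by the field's
deviation from the image mean, `clip(img - (blur - mean), 0, 255)`. A
constant image is untouched; a linear brightness ramp flattens to
near-constant; structures much smaller than the blur sigma survive. Otsu's
threshold (256-bin histogram, maximizing between-class variance; ties
resolved by averaging the tied candidates) then splits the corrected image,
and the below-threshold (dark) class is labelled into 8-connected
components. Components are screened for plausibility — minimum area
fraction 0.001, centroid within half the half-diagonal of the image
center, solidity at least 0.7 (spheroid cores are near-convex blobs) — and
the largest survivor, holes filled, is the core. All three screening
parameters are exposed in the configuration; the solidity of a component is
its pixel count over its convex-hull area with the discrete `A + P/2 + 1`
correction, so a filled digital disk scores ~1. An empty core is a legal
outcome: a blank field finds no spheroid.

**Halo.** Otsu thresholding under-covers a smoothly spread-out spheroid:
the dense ring of escaping cells around the core is brighter than the core
but darker than the background, and a global threshold cuts through it. The
halo stage recovers it by watershed flooding: starting from the core as
seed, the image's intensity range is quantized into `levels` steps (default
256) and the flooded region grows step by step to every pixel 8-connected
to the seed through intensities at or below the current level. Flooding
runs on the *original* image — background subtraction also compresses
contrast, which would blur the boundary between spheroid and field edge.
The flood eventually escapes across the background and reaches the image
border; that is the stop criterion, and the flooded region of the step
*before* the border-touching one is the halo. For a compact spheroid with a
sharp rim this nearly reproduces the core; for a diffuse one it extends
deep into the dense region. With a pixels-per-micron calibration the halo
area is also reported in µm².

Two numerical choices matter here. First, the flooding grid is anchored to
the image's own intensity range, not to the absolute 0–255 scale. A global
illumination change that acts affinely on intensities (an exposure offset,
a contrast gain) then maps the flooding levels along with the pixels, and
the flooded sets — hence the halo — are exactly unchanged. This is the
mechanism behind the pipeline's illumination robustness, and the package's
four-illumination stress test (shadow, under-exposure, average,
bright/low-contrast) verifies the residual variation stays within the 2 %
bound that motivated the design. Second, flooding deliberately spills into
any darker structure touching the spheroid's rim (nearby cells, debris);
that is accepted, because the segmentation is subsequently averaged into a
density map where a thin spill contributes negligibly.

**Periphery.** Scattered invading cells outside the halo are represented by
edge granularity: the more cells in a neighborhood, the more edges a Canny
detector finds there. The implementation smooths with a 1 px Gaussian,
takes Sobel gradients, suppresses non-maxima perpendicular to the edge, and
applies hysteresis thresholding (weak edges kept only when 8-connected to a
strong edge). When thresholds are not given, the high threshold is the Otsu
split of the *square-root-compressed* gradient-magnitude histogram (mapped
back to magnitude units), with low = high/2. The compression is essential:
the raw gradient histogram is dominated by the spheroid boundary's extreme
magnitudes, and an Otsu split on it lands above the much weaker single-cell
edges the periphery exists to capture. Because the rule is recomputed per
image it also adapts to noise: moderate camera noise raises the gradient
floor and the threshold with it. Background subtraction before periphery
extraction is available behind a flag but off by default — it helps only
under extreme gradients or severe under-exposure, and systematically
shrinks the detected periphery on normally exposed images.

## Density quantification

The three masks are unioned into an overlay (they typically overlap — for a
compact spheroid the periphery ring lies inside the halo). The overlay is
split into 16 × 16 *pixel* tiles; each tile scores the mean of its
binarized values stretched to 0–255 (fully covered tile = 255, empty = 0,
half = 127.5). Tiles cut by the frame edge are averaged over their actual
pixel count, so the 0–255 range is preserved without padding. The per-tile
values, expanded back to full resolution, are then averaged across adjacent
tiles with a Gaussian filter (sigma = tile size by default) and clipped,
giving a smooth density surface whose maximum sits at 255 over a compact
core. The size measure is the plain sum of the surface over the frame.

Two readings of "16 × 16 sub-images" are possible: tiles of 16 × 16 pixels,
or a 16 × 16 grid of tiles. The package uses pixel tiles, so the density
map's spatial resolution is independent of image size; the tile size is a
configuration parameter for anyone preferring the other reading. The
integral is likewise taken over the expanded, smoothed map rather than over
the 16-fold-smaller tile grid; for tile-aligned structure the two agree up
to the factor `tile_size^2`, and the expanded form keeps the map and the
measure on one grid. Integration after a mass-conserving tile average means
that without smoothing the integral equals 255 × (foreground pixel count)
exactly — a property the tests exploit as an oracle.

Sizes are finally expressed per sample as `relative_size =
integrated_density[day] / integrated_density[day 0]`, so day 0 is exactly 1
by construction. The normalization cancels the arbitrary units of the
density integral and, importantly, largely cancels static structure —
collagen impurities or extraneous cells present from day 0 contribute a
common offset to every day's integral, pulling the ratio toward 1 rather
than inflating it.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `preprocess.blur_sigma_fraction` | 0.125 | fraction of min(H, W) | illumination-field blur; must span the spheroid |
| `preprocess.gamma` | 1 | — | contrast restoration for over-bright images |
| `preprocess.periphery_background_subtraction` | off | — | rescue mode for extreme gradients |
| `core.min_area_fraction` | 0.001 | fraction of image area | rejects dust/debris components |
| `core.max_center_offset` | 0.5 | fraction of half-diagonal | spheroids are centered in the well |
| `core.min_solidity` | 0.7 | — | cores are near-convex |
| `halo.levels` | 256 | steps | flooding granularity across the intensity range |
| `periphery.low`, `periphery.high` | auto | gradient units | Canny hysteresis; auto = sqrt-Otsu rule |
| `periphery.sigma` | 1 | px | pre-Canny smoothing |
| `density.tile_size` | 16 | px | sub-image edge for tile averaging |
| `density.smoothing_sigma` | tile size | px | adjacent-tile averaging |

The shape-plausibility values are a reconstruction: the original program's
checks are unpublished beyond "considering the shape of the found objects",
so the three criteria above encode that intent with defaults chosen for
near-convex, centered, non-trivially-sized cores, and all are
config-exposed.

## The synthetic-data generator

No micrographs are deposited with the method, so validation runs on
generated scenes with exact ground truth. A scene is a dark core disk
(default radius 60 px, intensity 60) on a bright background (200) in a
256 px frame — proportions matching a ~360 µm spheroid in a ~1.4 mm
low-magnification field at ~5.5 µm/px — with a linear intensity ramp of
configurable width standing in for the dense rim (sharp when narrow,
spread-out when wide), Gaussian-profiled dark blobs for scattered invading
cells (Gaussian rather than hard disks so the edge detector sees realistic
gradients), a mild 0.5 px optical blur (at this scale the microscope PSF is
sub-pixel, so the blur is antialiasing, not resolved optics), one of five
illumination models (flat, linear gradient, corner shadow, exposure offset,
contrast-gain compression), and additive Gaussian camera noise (default
sigma 0.3 gray levels, the regime of a well-exposed 8-bit acquisition —
visible noise is characteristic of under-exposure, which can be emulated by
raising it). The rendered frame is clipped and rounded to whole gray
levels: the generator emits exactly what loading a stored 8-bit micrograph
yields. All randomness (cell placement, noise) flows from one seeded RNG
stream; the illumination model consumes none, so one scene rendered under
the four robustness conditions carries an identical noise field — the
synthetic equivalent of re-imaging one physical sample under varied
lighting. Time series render day 0 as the base scene and grow the core,
add cells, or push the placement ring outward per day, from the same seed,
so a zero-growth series repeats day 0 bit-identically and cell counts are
exact bookkeeping.

What the generator does *not* emulate: collagen fiber texture and matrix
inhomogeneity, out-of-focus light and halos from phase effects, spatially
correlated sensor noise, vignetting interacting with the shadow model, and
biological irregularity of real spheroid outlines. Passing tests therefore
demonstrate that the algorithms implement the method faithfully and behave
as designed under controlled degradations — not that the defaults are
optimal for any particular microscope; the configuration surface exists
for that.

## Numerical choices and degenerate inputs

* Intensities are canonicalized to 0–255 on load regardless of source bit
  depth (16-bit inputs are scaled by their full dtype range; RGB collapses
  by BT.601 luminance), because the density scale is defined on 0–255.
  Indices are 1-based row/column with origin at the top-left, the natural
  convention in R.
* Otsu's threshold on a constant image is a degenerate-input error; the
  core extractor catches it and returns an empty core instead.
* An empty core makes halo extraction meaningless (`extract_halo` errors);
  a core already touching the border returns the core itself as halo with
  a degeneracy flag and a warning.
* Ties among surviving core components go to the largest area, then the
  smallest centroid-to-center distance.
* Background subtraction clips to [0, 255] after the shift; gamma maps the
  endpoints 0 and 255 to themselves and preserves pixel ordering.
* Every stage is deterministic: identical input and configuration give
  bit-identical masks, maps and measurements, which the test suite checks
  end to end.

## Problem sizes

The test suite and the acceptance script run on 256 px (occasionally
128 px) scenes, 8×8 hand-written grids for flooding oracles, and 3–5-day
synthetic series — sizes chosen so the full validation cycle completes in
well under a minute per suite while every tile, flood level and mask
operation is still exercised at full fidelity. A single 256 px image runs
the complete pipeline in roughly a quarter of a second; batch processing
scales linearly in image count.

## Known limitations

* One spheroid per image is assumed (as in the assay design); multiple
  spheroids compete in the plausibility screen and only one wins.
* The halo inherits the watershed's tendency to flood into darker regions
  touching the rim; this is accepted by design and diluted by the density
  averaging, but it means the halo area slightly overstates the rim on
  noisy or debris-laden backgrounds.
* The periphery is a granularity proxy, not a cell detector; its edge
  counts are comparable within an assay, not across optics.
* Non-affine illumination (a deep shadow crossing the spheroid itself)
  shifts the flooding stop level and hence the halo by an amount that
  grows with the shallowness of the spheroid's rim; the robustness bound
  is stated for compact spheroids.
* Proprietary microscope containers (LIF/CZI/ND2), multi-page stacks and
  metadata-embedded calibration are out of scope; convert to TIFF/PNG and
  pass the calibration explicitly.
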