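---
title: "Methods: fragmentation classification, landscape metrics and change arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation classification, landscape metrics and change arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtrack)
```

`fragtrack` quantifies forest loss and fragmentation in binary raster time
series of the kind produced by historical map digitisation and satellite
classification: one forest/non-forest map per epoch, pixel-aligned, in a
projected CRS at a nominal 30 m resolution. This vignette documents the
models, the parameters that matter, the numerical choices made where the
published methodology leaves room, and what the synthetic-data tests do and
do not demonstrate.

## The fragmentation model

The classifier follows the pixel-level fragmentation taxonomy used in
landscape-fragmentation tooling: forest is partitioned into *core*,
*perforated*, *edge* and *patch*, with core further graded by tract size.

1. **Core.** A forest pixel is core when its centre-to-centre Euclidean
   distance to the nearest non-forest pixel exceeds the edge width
   (`edge_width`, default 100 m). Distance is centre-to-centre, not
   edge-to-edge: at 30 m pixels, "more than 100 m from non-forest" therefore
   means at least 4 pixels orthogonally. This convention is fixed so results
   are reproducible bit-exactly; an edge-to-edge convention would shift the
   core belt by half a pixel.
2. **Core grades.** Core pixels are grouped into tracts at the forest
   connectivity (default 8) and graded by tract area: core1 below 250 acres,
   core2 in the closed interval from 250 to 500 acres, core3 above. The
   thresholds default to the exact acre conversion (1.0117141 and
   2.0234282 km²) rather than printed approximations (one common printed
   rounding, "2.2 km²" for 500 acres, is arithmetically wrong); the
   approximate values can be passed explicitly when matching legacy runs.
   The middle interval is closed on both ends, so the boundary areas
   themselves grade as core2.
3. **Holes and perforation.** Non-forest components (hole connectivity,
   default 4) that do not touch the grid boundary and do not exceed
   `max_hole_area_km2` are *holes* — interior openings enclosed by forest.
   A non-core forest pixel is *perforated* when its nearest non-forest
   pixel lies in a hole, *edge* otherwise. When a hole pixel and an
   exterior pixel are exactly equidistant the pixel classifies as edge:
   the tie rule is not published anywhere authoritative, so the package
   fixes one and records it. Equidistance is decided on integer squared
   pixel distances, never on floating-point square roots.
4. **Patch.** Forest patches (forest connectivity) containing no core pixel
   are relabelled patch wholesale. No size cap is applied on top of the
   no-core rule.

Two conventions deserve justification:

- **Connectivity duality.** Forest components use 8-connectivity, holes
  4-connectivity. Using the same connectivity for both lets a diagonal line
  of forest pixels simultaneously connect the forest *and* fail to seal the
  opening it crosses — the standard foreground/background duality avoids
  that contradiction.
- **Boundary policy.** Whether the world beyond the raster is forest or
  non-forest is genuinely open (source analyses rarely state it). Both are
  supported; `outside_is_nonforest` is the default because regional clips
  are usually bounded by non-forest or by the study limit, and the choice is
  written into every class-raster sidecar so downstream users can tell which
  was used. Under the default, a one-pixel ring of virtual non-forest
  suffices for exact distances, because the nearest outside pixel to any
  interior cell always lies in the first ring.

The distance transform is the exact Euclidean transform (via `EBImage`);
connected components come from a 4-connected labelling merged across
diagonal adjacencies by union-find for the 8-connected case, with labels
canonicalised to row-major first-pixel order so outputs are deterministic.
On rasters up to 50 × 50 the classifier is tested pixel-identical against a
brute-force oracle that applies the rules literally with exhaustive
nearest-pixel scans and flood fills.

## Landscape metrics

The metric suite operates on a patch table (8-connected patches, raster
perimeter = exposed pixel faces × pixel size; grid-boundary faces count only
under `outside_is_nonforest`):

| metric | formula | units |
|---|---|---|
| NumP | patch count | – |
| MPS | mean patch area | km² |
| PSSD | population SD of patch areas | km² |
| ED | total edge / total landscape area | m/km² |
| MPE | total edge / NumP | m |
| MSI | mean(0.25 p / √a) | – |
| MPAR | mean(p / a) | m/ha |
| MPFD | mean(2 ln(0.25 p) / ln a) | – |

The raster-adjusted shape formulas are the default because the planimetric
forms (p/(2√(πa)), 2 ln p / ln a) misbehave on pixel data — a single pixel,
the most compact raster object, would score MSI ≈ 1.13 rather than 1. Under
the raster forms a perfect pixel square scores exactly 1 on both MSI and
MPFD, which the tests assert as closed-form references. The planimetric
variants remain available via `formulas = "vector"`. ED divides by total
landscape area (the FRAGSTATS convention for the m/km² unit), not forest
area. PSSD uses the population (÷N) estimator; with patch counts in the
hundreds the distinction from ÷(N−1) is far below reporting precision.
Empty landscapes return `NumP = 0` and missing ratio metrics rather than
errors.

## Change arithmetic

Percent change is `100 (a2 − a1)/a1`; the compound annual rate is
`100 ln(a2/a1)/(t2 − t1)` %/yr, the continuous-compounding rate connecting
two areas. All internal values are signed (loss negative); rounding to 2
decimal places (half-even) happens only in the reporting layer, because the
published tables this package reproduces mix sign conventions (loss printed
as positive magnitude in some columns, negative in others).

The bundled CTML tables (`ctml_table()`) carry one documented quirk: in the
published regional table the 2000–2020 percent-change column was computed
against the 2020 area instead of the 2000 area, unlike every other percent
column (and unlike the class-area table's own 2000–2020 column). The
curated CSV records the denominator epoch per value (`pct_basis`), and the
reproduction tests apply `percent_change` with the published basis rather
than silently asserting the standard one.

Epoch pairs reported are all consecutive pairs plus first-to-last. Grid
summaries assign pixels to cells by pixel centre over half-open intervals,
so every pixel belongs to exactly one cell and zonal areas are exactly
additive; grids anchor at the raster origin. Transition matrices are exact
pixel cross-tabulations, so marginal conservation against the per-epoch
class summaries is an identity, and the tests assert it as such.

## The synthetic-landscape generator

The generator exists so that every analysis stage has a controlled, seedable
input; its defaults encode the study conditions the package targets: 30 m
pixels, epochs 1930/1975/2000/2020, an overall compound loss rate of
−0.27 %/yr, and conflict points falling in converted pixels with probability
0.6.

- **Initial landscape.** Spectral synthesis: white Gaussian noise is shaped
  in the Fourier domain by a radial power-law amplitude filter (power
  spectrum ∝ f^−clumpiness), inverse-transformed, and thresholded at the
  empirical quantile, so the realised cover fraction is exact to one pixel.
  Spectral synthesis was chosen over cluster-growth algorithms because it is
  parameter-light, seed-deterministic, and makes the cover fraction exact by
  construction. `clumpiness = 3` is the default: it produces the
  large-coherent-blob structure (a dominant core-3 tract with an edge belt)
  that a mostly intact forest landscape shows at this resolution.
- **Deforestation.** Each simulated year removes exactly
  `round(A (1 − e^{r/100}))` forest cells. Making the removal *count*
  deterministic and only the removal *locations* random separates estimator
  correctness from Monte-Carlo noise: the compound-rate estimator must
  recover the configured rate to ±0.02 percentage points on a 500 × 500
  raster, with no averaging over replicates. Cleared cells are drawn without
  replacement with weight `exp(edge_bias / (1 + d))`, `d` the pre-step pixel
  distance to non-forest, recomputed each year; `edge_bias = 0` is spatially
  random clearing.
- **Conflict points.** Each point independently lands uniformly inside a
  random loss pixel with probability `p_in_loss` (default 0.6), else
  uniformly inside a non-loss pixel.

What the generator does *not* emulate: terrain, roads, rivers, settlement
gravity, or any spatial covariate of real clearing; the spatial pattern of
historical deforestation in any real landscape; registration error and
classification noise between epochs; forest gain. Passing tests therefore
demonstrate that the estimators and classifiers are correct on landscapes
with controlled autocorrelation and known ground truth — not that any
particular historical reconstruction is accurate. The `edge_bias` parameter
is a free knob for exercising the classifier's response to contrasting
clearing regimes, not an estimate of any real landscape's history.

## Numerical and reporting choices

- Squared pixel distances are compared as integers (exact for an exact
  Euclidean transform), eliminating floating-point tie ambiguity in the
  perforated/edge decision.
- Nodata cells are excluded from area accounting and treated as non-forest
  for fragmentation geometry; maps in one analysis must be pixel-aligned,
  and misalignment is an error, never an implicit resample.
- Nearest-neighbour resampling preserves the georeferenced extent to within
  one target pixel and refuses scale factors above 100, which in practice
  only arise from unit mistakes.
- The minimum-mapping-unit filter (default off; 5000 m² = 0.5 ha in the
  forest-definition convention this package mirrors) removes 8-connected
  patches below threshold and is idempotent.
- Report CSVs round at 2 decimals, half-even; JSON provenance sidecars and
  manifests carry full-precision parameters, package version, seed and
  output checksums.

## Problem sizes and test design

The test suite builds all fixtures in code. Oracle-equivalence runs use 20
random rasters up to 50 × 50 (the scale at which an O(n²) exhaustive
nearest-pixel scan stays pleasant); monotonicity sweeps use 20 fixtures ×
edge widths {0, 50, 100, 200} m; rate recovery uses a single 500 × 500,
90-year run; the qualitative fragmentation signature (NumP up, MPS down, ED
up, MPAR up) uses 20 seeds of a 120 × 120, 20%-loss series and requires at
least 18 of 20 to show the full signature. These sizes were chosen as the
smallest at which each property is sharp: the rate estimator's rounding
error shrinks with forest count, and the signature is a statistical
regularity, not a per-seed certainty.

## Known limitations

- Single-CRS world: no reprojection, no geodesic areas; the package assumes
  projected coordinates with square pixels.
- The class semantics match the published taxonomy, not any specific GIS
  toolbox's binary output; where a toolbox's internal tie rules are
  unpublished, this package's documented rules will not necessarily
  reproduce its pixel-level decisions.
- Landscape-level metrics only, for the forest class only; no contagion,
  proximity or connectivity indices.
- Absolute historical metric values (patch counts in the tens of thousands,
  region-wide edge densities) depend on the undeposited source maps and are
  out of reach by construction; the package reproduces the published
  *arithmetic* exactly and the *qualitative* metric signature
  statistically.
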