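---
title: "Interpretable HER2 IHC scoring: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable HER2 IHC scoring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2quant)
```

## The problem

HER2 (human epidermal growth factor receptor 2) status in breast cancer is
screened by immunohistochemistry: DAB (brown) marks membrane-bound HER2
protein, hematoxylin (blue-violet) counterstains nuclei. A pathologist
grades each slide 0 / 1+ / 2+ / 3+ from three visual criteria -- how dark
the membrane staining is, how many tumor cells are stained, and whether
the staining forms a *complete circumferential ring* around the cell
membrane. 2+ is equivocal and reflexes to ISH testing. The grading is
subjective; `her2quant` computes the three criteria as explicit numerical
indexes and grades slides from them, so every decision can be traced back
to measurable quantities.

The pipeline has three stages:

1. **Tissue masking.** A low-resolution pyramid level is converted to HSV;
   the H and S channels are independently thresholded by Otsu's method and
   combined. White background has near-zero saturation, so the "tissue"
   side of each threshold is the side with the higher mean saturation.
2. **Tumor-tile detection.** Tissue-bearing tiles are scored by a
   pluggable patch classifier; the tile probabilities form a slide-level
   probability map that is binarized at a configurable threshold
   (default 0.5).
3. **Measurement and scoring.** On each tumor tile: the DAB mask is
   extracted by an HSV gate; staining intensity is the mean darkness
   (`1 - luma/255`) over DAB pixels; stains are unmixed by
   optical-density color deconvolution; cells are segmented by
   distance-transform watershed on the hematoxylin map; membrane rings
   are measured against the DAB mask. Tile features aggregate to slide
   features, which are classified by per-class interval thresholds.

## The optical model

Bright-field staining follows the Beer--Lambert law: with per-stain unit
optical-density vectors $v_s$ and per-pixel concentrations $c_s$,

$$I_{ch} = 255 \cdot 10^{-\sum_s c_s\, v_{s,ch}}, \qquad
  \mathrm{OD}_{ch} = -\log_{10}\!\big(\max(I_{ch},1)/255\big).$$

Concentrations mix additively in OD space, so a pixel's OD vector is the
concentration vector times the stain matrix, and unmixing is
multiplication by its inverse (`deconvolve()`). The default stain basis is
the Ruifrok--Johnston H-DAB pair, completed by the unit cross product as
the residual axis; it is fully configurable, and the synthetic ground
truth is defined against whatever basis renders it. The intensity floor
at 1 avoids infinite densities; negative unmixed concentrations (noise
outside the stain simplex) are floored at zero.

`compose_from_od()` is the exact forward model, so composition followed
by deconvolution is an identity up to 8-bit quantization. With
concentrations up to 0.7 OD per stain the worst-channel transmitted
intensity stays above ~24 counts and the round-trip error stays below
0.02 OD, which is the tolerance the tests assert.

## The three indexes

* **Staining intensity**: mean of `1 - luma/255` (Rec. 601 luma) over the
  DAB mask; 0 when the mask is empty, which makes an unstained slide
  score exactly 0.
* **Positive-cell ratio**: positive cells / total cells. A cell is
  positive iff its segmented region contains at least one DAB-mask pixel.
  This "mask-product" rule is the fast equivalent of scanning every
  stained pixel for its owning cell, and the test suite asserts the two
  agree exactly on synthetic patches.
* **Circumferential-membrane cell ratio**: among *positive* cells, the
  fraction whose membrane ring is DAB-covered over at least
  `completeness_cutoff` (default 0.9) of its length. The ring is a band
  of width `ring_width` (default 2 px) straddling the cell-region
  contour. The denominator is the positive-cell count: the reference
  per-class statistics for this index exceed the positive-cell ratios,
  which is only consistent if "circumferential" is read as a fraction of
  the stained population rather than of all cells.

## Cell segmentation

The hematoxylin concentration map is thresholded by Otsu's method,
opened (3 px disc), hole-filled, distance-transformed and
watershed-segmented (`tolerance = 1` merges the shallow multiple maxima
an elongated nucleus produces). Components outside
`[min_area, max_area]` = [30, 5000] px² are removed; components larger
than 3x the median single-cell area count as
`round(area / median area)` cells, which keeps counts honest in clumps
the watershed cannot split. Nuclei are finally expanded into cell
regions by Voronoi-constrained growth (`cell_expand` = 5 px), which is
what the positivity and ring measurements run against.

Two numerical details matter:

* **Histogram thresholds cut half a bin above the returned bin.** Bin
  $b$ collects values rounding to $b/255$, so the value-space cut is
  $(b + 0.5)/255$; cutting at $b/255$ misassigns an entire stain mode
  whose value sits exactly on the bin center.
* **Hierarchical second Otsu pass.** On tissue with a hematoxylin
  stroma wash, the full-histogram threshold separates background from
  tissue, not stroma from nuclei. The upper class is re-thresholded, and
  the refinement is accepted only when its two modes are separated by a
  mean-OD gap above `wash_separation` (default 0.15 OD) -- a plain
  unwashed patch fails the guard and keeps the first threshold.

## Decision layer

Slide aggregation is a cell-count-weighted mean for the two ratios
(tiles with more tumor cells carry more evidence; zero-cell tiles are
excluded) and a plain mean for intensity. Classification uses per-class
intervals for each index -- defaults are a published single-center
min/max table -- with decision boundaries at the midpoints between
adjacent class intervals, values on a boundary assigning upward (the
clinical convention favors flagging). The staining-only method uses the
staining index alone; the integrated method lets each index vote through
its own boundaries and takes the median of the three ordinal votes.
Median voting is symmetric, monotone in every feature, and reduces to
the staining-only answer when all three agree. 2+ results always carry
an explicit reflex-ISH flag and are never auto-resolved.

The guideline rule engine (`apply_csco_rules()`) is a separate, direct
encoding of the clinical criteria on cell-population fractions, with a
strict `>` at every 10% boundary: 10.0% complete intense staining is
*not* 3+; it falls to 2+ because complete staining is present.

## The synthetic generator

`make_patch()` and `make_slide()` render cells through the same
Beer--Lambert model the pipeline inverts: elliptical hematoxylin nuclei
(semi-axes 4--5 px, OD 0.6), DAB membrane annuli of radius 9 px and
thickness 4 px whose stained arc fraction is the per-cell
"completeness", and (on slides) a hematoxylin stroma wash of OD 0.25
over an irregular elliptical tissue blob per tile. At the reference scan
resolution of ~0.5 µm/px these are plausible cell dimensions; the 4 px
membrane (~2 µm) reflects apparent DAB thickness after diffusion and,
practically, survives the pipeline's own 3x3 morphological opening,
which would erase a thinner ring. Membrane arcs displace the wash: a
blue underlay would rotate faint brown out of any hue gate, and real
chromogen deposits dominate the local color anyway.

Placement is rejection sampling with a minimum center separation of
2.5x the membrane radius. At exactly 2x, the inner half of a cell's
membrane annulus lies inside the Voronoi cell of its neighbor, so the
mask-product rule would systematically flag adjacent negative cells --
a property of the geometry, not of the measurement. Two stress modes
remain available: `min_dist_factor = 1.2` (crowded) and
`make_overlapping_pair()`, whose fused nuclei the watershed must split.

Ground truth is exact: the cell table, label image, tissue mask, OD
maps and DAB mask are emitted alongside the rendered image, and
`round(n_cells * positive_fraction)` cells are positive by construction.

Per-class slide targets (staining intensity, positive ratio,
circumferential ratio) are drawn uniformly from sub-intervals of the
default threshold-table intervals. Two constraints shape those
sub-intervals, chosen once and fixed:

* the printed intervals for the two cell ratios *overlap* between 2+
  and 3+, so targets must also lie inside the midpoint decision cells
  or the generated slide would be inherently ambiguous to the very
  classifier the table defines;
* the default brown gate cannot fire below ~0.08 staining intensity
  (saturation of faint DAB falls under the gate's floor), so 1+
  staining targets start at 0.09.

The membrane DAB optical density realizing a staining-intensity target
is obtained by inverting the closed-form intensity-vs-OD curve
(`dab_od_for_intensity()`). The `staining_ambiguous` mode draws 2+/3+
staining targets straddling the 2+/3+ staining boundary while keeping
the cell ratios class-typical; on that fixture the staining-only
classifier errs on roughly half the slides while the integrated median
vote stays correct, which is the qualitative ordering the two methods
show on real cohorts.

What the generator does *not* emulate: scanner noise, focus blur,
stain-batch variation, tissue folds, nuclear pleomorphism, or
overlapping tissue layers. Passing tests therefore demonstrate that the
measurement chain is correct under the stated optical model -- not that
it is robust to the full variability of clinical material. The brown
HSV gate in particular (hue 8--40 deg, S >= 0.08, V in [0.10, 0.98]) is
calibrated against images rendered with the default stain vectors; other
scanners or chromogens will need the config-exposed bounds retuned.

## Classifier backends

The patch classifier is a contract: a batch of RGB tiles in, tumor
probabilities in [0, 1] out. Three backends ship: a deterministic
logistic over color statistics (`heuristic_classifier()`, no training,
used as the pipeline default), a trainable single-hidden-layer neural
network over standardized color-statistic features
(`train_classifier()`, `nnet` backend; the training configuration
mirrors the usual SGD recipe and `epochs` bounds the optimizer
iterations), and a user-supplied prediction function
(`function_classifier()`), which is also how an external deep model
would plug in. The synthetic tumor/non-tumor fixture is separable by
color statistics by construction; the trainable backend reaches >= 0.95
validation accuracy on a 240-tile fixture in seconds. Probability maps
are batch-size- and order-invariant because tiles are scored
independently.

## Problem sizes used by the test suite

The suite validates the generator contract at 40 slides per class
(truth-level checks), exact segmentation on 20 patches of 50 cells,
feature recovery over an 11-point positive-fraction grid with 5 seeds
each, and end-to-end class recovery on 40 rendered slides (10 per
class, 4 tiles of 512 px, 80 cells per tile) plus a 20-slide
ambiguous-staining contrast fixture. These sizes were chosen so the
full suite exercises every stage at realistic per-tile cell densities
while completing in minutes on a single CPU.

## Known limitations

* Vendor WSI formats (.svs) are out of scope; slides enter as multi-page
  TIFF pyramids, PNG patches, or in-memory arrays.
* No stain-color standardization: color-space conversion is relied on to
  separate brown from blue, so extreme stain batches can defeat the
  default HSV gate.
* The 3+ control-tissue layout some labs place next to the main section
  is not detected or excluded.
* Thresholds are single-center by nature; the table is config-exposed
  and should be re-derived per center.
* ISH/FISH analysis is out of scope; 2+ slides are only flagged.
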