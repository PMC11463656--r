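---
title: "Weakly supervised NFT quantification: models, parameters and design choices"
author: "nftquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised NFT quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nftquant)
```

## The problem

Neurofibrillary tangles (NFTs) — intracellular aggregates of
hyperphosphorylated tau — are a defining lesion of Alzheimer disease.
On AT8-stained sections the tau signal is developed with the brown
chromogen DAB, and an expert marks each mature tangle with a single
point at its nucleolus. Points are fast to place but useless for
training pixel-level models; full boundary masks are informative but
prohibitively slow to draw at whole-slide scale. `nftquant` implements
the middle path: it *bootstraps* pixel masks from point annotations
with classical image processing, evaluates any segmentation or
detection against those masks, and condenses whole slides into a
single area-normalised burden score. A deterministic synthetic scene
generator with known per-object ground truth backs every stage, so the
whole pipeline is testable without gigapixel slide data.

## Stain model and DAB extraction

Stains mix additively in optical density (Beer–Lambert): for 8-bit
intensity $I$, $OD = -\log_{10}(I/255)$ per RGB channel, and a pixel's
OD vector is $h\,\mathbf{s}_H + e\,\mathbf{s}_E + d\,\mathbf{s}_{DAB}$
for unit stain vectors $\mathbf{s}$. `rgb_to_hed()` inverts this with
the Ruifrok–Johnston H&E-DAB basis; `hed_to_rgb()` is the forward map
used by the renderer. Because rendering and unmixing share one
`stain_matrix()`, the round trip is self-consistent: mixed densities
up to about 0.6 OD come back within 0.02 OD after 8-bit quantisation
(higher densities drive intensities into the low-count regime where
quantisation noise dominates — a property of 8-bit imaging, not of the
basis).

`dab_binary_mask()` then min–max normalises the DAB channel per tile,
applies Otsu's threshold (256-bin histogram, `>=` is foreground), and
cleans up with morphological opening followed by closing using a disk
of radius 3 px. Choices worth knowing:

* **Normalisation scope is the tile, not the ROI.** The mask pipeline
  operates on 400 px crops; per-tile normalisation adapts to local
  staining intensity. `dab_proportion()` reuses the same routine on
  whole ROIs.
* **Disk radius 3** is the smallest element that removes isolated
  speckle while leaving the ~400 px² minimum plausible tangle masks
  intact; it is exposed as `morph_radius`.
* **Minimum dynamic range** (`min_range = 0.05` OD): min–max rescaling
  of a nearly constant channel only amplifies quantisation noise into
  a meaningless Otsu split, so tiles whose DAB range is below 0.05 OD
  degenerate to an empty mask with a warning. Blank tissue and white
  glass fall well below this; any real DAB object (OD ≳ 0.5) is far
  above it.

## Point-to-mask bootstrapping

For each annotated point, `point_to_mask()` composes three steps:

1. `crop_tile()` — a 400×400 crop centred on the nucleolus, padded
   with white at ROI borders so padding never enters the DAB mask.
2. `dab_binary_mask()` — the stain threshold above.
3. `select_center_blobs()` — the centre-bias filter: label connected
   components (8-connectivity by default), delete those whose centroid
   is farther than `center_bias` px from the tile centre, find the
   largest survivor, and delete survivors smaller than `size_frac`
   (default 0.5) of its area.

The default `center_bias` is 120 px. The first-pass value of 80 px
systematically missed tangles with long contiguous tails from nucleus
to axon (about 7% of tiles); widening to 120 px recovers them, and the
80 px behaviour remains reproducible via configuration. Two boundary
conventions are deliberate and tested exactly: a centroid at exactly
`center_bias` px is *retained* ("within"), and a blob at exactly
`size_frac` × largest is *retained* (only strictly smaller blobs are
removed). The filter runs as a single labelling pass with sequential
criteria; since deleting a component never changes another component's
centroid or area, iterative re-labelling would give the same result.
The centroid is the unweighted foreground centroid, not
intensity-weighted.

`stitch_masks()` places tile masks at their crop origins and ORs them
into the ROI-level ground truth — union semantics make stitching
order-independent and idempotent over overlaps. `mask_size_report()`
surfaces empty masks and over-segmentation outliers (fraction > 0.32
of a tile) rather than hand-editing them, keeping the pipeline fully
automated.

## Tiling and balanced sampling

`build_tile_grid()` lays 1024 px tiles at stride 1024; a tile is
positive iff a point lies in its half-open extent, so a point on a
shared edge belongs to exactly one tile. Clipped border tiles are kept
(inference needs full coverage) but excluded from the training
sampling pool (uniform tile shape). `balanced_sample()` draws with
replacement using inverse-class-frequency weights, making each draw
positive with probability `positive_fraction` (default 0.5) no matter
how rare positive tiles are — on a 1%-positive index, 10,000 draws
land within the 99% binomial interval of 50%.

## Metrics

Pixel level: `agreement_map()` classifies each pixel TP/FP/FN/TN;
`pixel_scores()` derives precision, recall, F1, the class IOUs and
mIOU (their arithmetic mean); `tversky()` generalises F1
(α = β = 0.5 recovers it exactly, verified numerically); `auroc()` is
the normalised Mann–Whitney statistic with midrank ties;
`random_baseline_f1()` gives the chance-level F1 of a null model whose
precision equals class prevalence at fixed recall 0.5. The probability
threshold comparison is inclusive (`>= 0.5`) — the tie case is
measure-zero for real predictors but is pinned down for
reproducibility. Counts micro-average exactly: summing tile-level
confusion counts equals the stitched-ROI counts.

Object level: `masks_to_boxes()` takes tight component extents
(half-open coordinates, so area is pixel count); `merge_boxes()`
merges boxes whose centres lie within 150 px using the transitive
closure of the proximity graph iterated to a fixpoint — chosen over
order-dependent pairwise merging for determinism and idempotence.
`gt_boxes_from_points()` reproduces the ground-truth convention of
taking the mask extent inside the 400 px window around each point.
`match_boxes()` matches greedily by descending IOU; pairs under
`min_iou = 0.001` are discarded (with `min_iou = 0`, any strictly
positive overlap counts). Greedy — not optimal-assignment — matching
is the declared semantic. `average_precision()` uses all-point
interpolation; `nms()` is standard greedy suppression.

## Slide scoring

`sliding_window_segment()` runs a pluggable predictor over
non-overlapping tiles. The shipped backend, `predictor_classical()`,
is the DAB threshold pipeline wrapped in the predictor contract
(tile in, probability map of identical dims out); any learned model
honouring the contract drops in unchanged. The burden score is
`count / tissue_area * median_area`: `count_blobs_downscaled()`
block-max-reduces the mask by 64× and counts 8-connected components
(max, not mean or subsampling, so thin detections survive; blobs
closer than roughly one reduced pixel can fuse — the count is a
burden proxy, not an exact census), and `tissue_mask()` finds tissue
by block-mean downscaling, grayscale optical density, Otsu and hole
filling. Tissue detection presumes the slide contains white
background; a field-of-view that is entirely tissue has no
white/tissue contrast to threshold. `annotator_score()` applies the
same functional form to human point counts over ROI area.
`correlate_with_grades()` reports tie-corrected Spearman's rho
(Pearson on midranks) against CERAD-like ordinal grades, and
`compare_grade_groups()` Welch's t between adjacent grades, computed
in closed form so zero-variance groups degrade gracefully (identical
groups: t = 0, p = 1, flagged) instead of erroring.

## The synthetic scene generator

`render_scene()` composes scenes in OD space: every tissue pixel gets
a haematoxylin tint (OD 0.25), objects add their DAB density, diffuse
background tau is salt-like DAB speckle (per-pixel Bernoulli at rate
`noise`, OD 0.35) and optional Gaussian sensor noise (σ = 2, 8-bit) is
added last. Scenes are bit-exact reproducible from (parameters, seed).
Tangles are rendered by `render_object_mask()` as a filled ellipse
soma with 1–2 tapered triangular protrusions anchored just inside the
soma tips — the minimal shape family matching the morphological
criteria (flame shape, nucleolus inside, 1–2 protrusions). Default
soma semi-axes (45–75 × 28–45 px) put mask areas around 4,000–10,600
px, bracketing the ~8,800 px (5.5% of a 400² tile) that bootstrapped
masks average in practice; no published size *distribution* exists to
calibrate against, so these are round numbers inside the reported
range. Distractors are smaller, fainter, protrusion-free blobs that
carry no point. Placement is rejection sampling with a 300 px minimum
centre separation and a bounded retry budget (capacity error beyond
it). An optional tissue rectangle (`tissue_frac`) leaves white glass
around the tissue so tissue detection has something to find.

What the generator does **not** emulate: pre-tangles and ghost
tangles as distinct stain classes, neuropil texture, stain batch
variation, scanner illumination gradients, tissue folds, or out-of-
focus blur. Passing tests therefore demonstrate algorithmic
correctness of the pipeline's logic — boundary rules, transforms,
metric formulas, score behaviour — not segmentation accuracy on real
histology.

## Numerical and degenerate-input conventions

* Coordinates are 0-based, `x` = column, `y` = row, half-open
  intervals everywhere (tiles, boxes, super-tile frames).
* Rotated ROI extraction uses an inverse-mapped bilinear warp sharing
  its exact affine frame with the point transforms, so extraction and
  point mapping commute within 1 px; angles that are multiples of 90°
  land on integer indices and are exact.
* Chunked storage (5000 px chunks) is lossless by contract; the codec
  (per-chunk PNG) is an implementation detail.
* Zero denominators in metrics yield 0 with a warning; single-class
  AUROC and constant-grade correlations are explicit errors; an empty
  tile mask is a valid, flagged outcome.
* Super-tile grids use `round(W / tile_w)` columns with the final
  row/column resized to the ROI edge — the only remainder rule that
  both tiles the ROI exactly and reproduces the reference count of
  fifteen 4247×3560 frames on a 21,236×10,680 ROI.

## Problem sizes used in the test suite

The suite exercises the pipeline at deliberately modest scales chosen
to be fully representative of the algorithms' behaviour: bootstrapping
recovery runs on twenty 1000×1400 ROIs with five tangles each (noise
0.01), slide scoring on 2560² slides with 0/5/25 tangles at equal
tissue area, and oracle equivalences on dozens to hundreds of small
random instances. Whole-slide arrays only change memory traffic, not
code paths: every operation is tiled, chunked or downscaled by
construction.

## Known limitations

* The classical predictor thresholds stain, so on real tissue it
  cannot distinguish mature tangles from other AT8-positive objects;
  it is the default backend and reference implementation of the
  predictor contract, and a trained model is expected to replace it
  for production inference.
* Blob counting at 1/64 resolution fuses detections closer than about
  one reduced pixel.
* Otsu-based tissue detection requires white background in the frame.
* `dab_proportion()` quantifies all DAB, not tangle-specific signal.
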