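---
title: "Quantifying glial tiling in confocal Z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial tiling in confocal Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliatile)
```

## The biological question

In the Drosophila larval central nervous system, two glial populations
partition the tissue between them. Cortex glia ensheath the neuronal cell
bodies of the outer cortex in a reticular, honeycomb-like membrane mesh;
astrocytes project into the synapse-rich central neuropil and normally keep
out of the cortex. When cortex glia are impaired, their mesh collapses into
globular profiles and astrocyte processes infiltrate the vacated cortical
territory. Quantifying this tiling relationship from three-channel confocal
stacks (astrocyte membrane, cortex-glia membrane, neuronal nuclei) by hand
is slow and rater-dependent; `gliatile` automates it.

Two indices summarize each optical section:

* **AMI** (automated morphology index): the total exposed-edge perimeter of
  the binarized cortex-glia mask, normalized by cortex area and scaled by
  100. A reticular mesh has a large membrane perimeter per unit area; the
  same membrane collapsed into globules has a much smaller one, so AMI
  falls as morphology degrades. For a mask of unit pixels the perimeter is
  counted as exposed unit edges (`4*area - 2*adjacencies`), which makes the
  index exact on binary masks: splitting one square of membrane into `m`
  equal-area tiles multiplies AMI by exactly `sqrt(m)`.
* **AIS** (automated infiltration score): the percentage of the cortex area
  covered by astrocyte signal after excluding astrocyte cell bodies, i.e.
  `100 * |astro mask in cortex| / cortex area`.

## The pipeline

Each plane of a stack passes through four stages.

**1. Denoising.** Unsharp masking,
`out = img + amount * (img - gaussian_blur(img, radius))`, clipped to the
input range; `amount = 2, radius = 20` for the membrane channels and
`amount = 3, radius = 20` for nuclei.

**2. Quality-aware binarization.** Every channel is first thresholded with
Otsu's method (exhaustive between-class-variance maximization over the
distinct pixel values; foreground is strictly above the threshold). Two
diagnostics then decide whether Otsu can be trusted:

* *Blown out*: if despeckling (removing 8-connected components smaller
  than 75 px) inside the middle third of image rows — the neuropil band,
  where bright haze accumulates — removes at least 7% of the white there,
  the threshold has "bitten" into background haze, and the channel is
  re-thresholded with the Triangle (peak-to-chord) method.
* *Blacked out*: if less than 2% of the image is white the channel is
  nearly empty and Otsu's split is arbitrary; nuclei fall back to Li's
  minimum-cross-entropy threshold and astrocytes to Yen's maximum-
  correlation threshold. The cortex-glia channel has no blacked-out branch:
  its mesh always yields substantial foreground in usable sections.

The chosen algorithm and both diagnostics are logged for every plane
(`decisions` table); the decision tree is the most fragile stage of any
such pipeline and must be auditable.

**3. Cortex segmentation.** The cortex region is recovered from the union
of the cortex-glia and nuclei masks by a morphological chain: *dilation
fill* (a background pixel flips to foreground when strictly more than
`thresh = 0.10` of the in-image pixels within a Euclidean disk of radius
`n = 15` are white; one simultaneous pass), *hole filling* (background
components smaller than `hole_size = 5000` px not touching the border),
and `erosions = 10` iterations of 8-neighborhood erosion. The fill closes
the mesh into a solid region; the erosions retract the ~10 px boundary the
fill grew (the 10% disk-fraction contour of a half-plane at `n = 15` lies
~10.35 px out), so the net boundary bias of the default parameters is a
fraction of a pixel. `parameter_grid_search()` evaluates a parameter grid
against manually segmented reference masks, ranking by mean overlap.

**4. Scoring and statistics.** `compute_ami()` and `compute_ais()` produce
the per-plane indices; astrocyte cell bodies are excluded from AIS by a
shape filter (area 50–800 px, extent ≥ 0.6, roundness ≥ 0.5, where
roundness is `4*pi*area/perimeter^2`; a digital disk scores ~0.62).
Per-animal global scores are unweighted plane means. `sliding_window()`
builds dorsal–ventral profiles on a normalized 0–100 depth axis (width 10,
step 1; windows are closed-left/open-right, closed at 100), reporting group
mean ± SEM and a pooled Spearman correlation between AMI and AIS per
window. Group comparisons use Kruskal–Wallis with tie-corrected Dunn post
hoc z-tests (raw and Holm-adjusted); manual-versus-automated validation
uses OLS regression with a 6-point discrepancy flag and refit, and
multi-rater agreement uses ICC(3,k) from the two-way ANOVA decomposition.

## A worked example

Synthetic fixtures stand in for real stacks. The generator renders the
three channels of a known ground-truth geometry: a mesh of cortex-glia
ridges over the cell-body layer, nuclei, astrocyte cell bodies at the
cortex–neuropil interface, and a steered number of infiltrating process
pixels.

```{r example}
spec <- fixture_spec(seed = 7, globularity = 0, infiltration_fraction = 0.02)
plane <- generate_plane(spec)

dn <- unsharp_mask(plane$channels$cortex_glia, 2, 20)
cg <- select_threshold(dn, "cortex_glia")
cg$decision

nuc <- select_threshold(unsharp_mask(plane$channels$nuclei, 3, 20), "nuclei")
astro <- select_threshold(unsharp_mask(plane$channels$astrocyte, 2, 20),
                          "astrocyte")

seg <- segment_cortex(cg$mask, nuc$mask)
overlap_metrics(seg, plane$truth$cortex_mask)

compute_ami(cg$mask, seg)
compute_ais(astro$mask, seg)
```

The same machinery scales to whole experiments through `run_config()` /
`run_pipeline()`, which score every plane of every stack, aggregate,
window, and test, with per-stack error isolation and a configuration hash
recorded in every output file.

```{r pipeline}
manifest <- lapply(1:2, function(i) {
  s <- fixture_spec(n_planes = 2, seed = 20 + i,
                    globularity = (i - 1) * 0.8,
                    infiltration_fraction = 0.01 + (i - 1) * 0.04)
  list(stack = generate_stack(s, animal_id = paste0("a", i),
                              group = c("control", "driver")[i])$stack)
})
res <- run_pipeline(run_config(manifest))
res$global_scores
```

## The synthetic generator as a study condition

The fixtures are not arbitrary test images; their defaults are the
package's study conditions, fixed before the test suite was written.

* **Geometry.** 256×256 planes; the neuropil occupies the middle third of
  rows and the cortex the remainder (inset 14 px from the frame). The
  cortex-glia mesh is the ridge set of a Voronoi diagram over the nuclei
  (pixels nearly equidistant from their two nearest nuclei), so
  *globularity* can be dialed continuously: a fraction of mesh edges,
  chosen by a nested subset scheme, is replaced by globular blobs of
  matched signal so the series is comparable across the dial. The glial
  sheath straddles the cortex–neuropil interface by two rows, and sparse
  midline nuclei sit in the neuropil band — as in real tissue, no
  channel's neuropil band is signal-free, which matters because the
  blown-out diagnostic is deliberately hypersensitive to speck-only bands.
* **Infiltration.** Process pixels descend from both interfaces into the
  cortex along width-2 column corridors; an ordered candidate list is
  truncated at exactly `round(f * cortex_area)` pixels, so the planted
  fraction `f` is the ground truth, exact to one-pixel rounding.
* **Rendering.** Foreground renders at 180 ± 20 and background at 20 ± 10,
  with the levels drawn once per plane and channel; within-plane texture
  comes only from a Gaussian blur (`sigma = 0.4`) and additive noise
  (`sd = 3`), clipped to [0, 255]. Levels are per-plane rather than
  per-pixel because unsharp masking amplifies pixel-scale texture
  threefold; per-pixel level jitter produces isolated supra-threshold
  specks that spuriously trip the blown-out diagnostic in an otherwise
  empty band. The defaults are calibrated so that the default decision
  tree binarizes noiseless fixtures perfectly.
* **Determinism.** All randomness derives from one integer seed, split per
  plane and per stream (geometry and each channel's rendering), so any
  plane can be regenerated independently and identically.

## Numerical and design choices

* Connected components are 8-connected throughout (EBImage's 4-connected
  labeling is extended by a union–find merge over diagonal label pairs).
* Convolutions (Gaussian blur, disk counts for dilation fill) use explicit
  kernels; disk counts are rounded back to exact integers so the fill is
  identical to its brute-force definition.
* Thresholds operate on raw intensity values: Otsu searches all distinct
  values exhaustively; Triangle uses unit-width histogram bins for
  integer-valued images; Li iterates its fixed point to convergence; the
  implementations match scikit-image's to machine precision (Li to its
  iteration tolerance).
* Spearman's rho is mid-rank Pearson, with an exact permutation p-value
  for n ≤ 8 and the t approximation otherwise.
* AMI–globularity comparisons in the tests normalize by the ground-truth
  cortex area, which the fixture series holds constant: at globularity 1
  the mesh is gone, so cortex segmentation from the remaining channels is
  legitimately degraded, and normalizing by the segmented area would mix a
  segmentation failure into a morphology-index property.

## Limitations

* Global thresholds assume reasonably uniform illumination within a plane;
  strong within-plane gradients would need local thresholding, which the
  pipeline does not implement.
* Unsharp masking widens thin bright processes by a halo roughly the size
  of the imaging blur. At the default fixture blur (`sigma = 0.4`) the
  effect is negligible, but at `sigma = 0.8` it inflates AIS of 2-px-wide
  processes by ~50%; with a wide point-spread function, infiltration
  estimates should be read as upper bounds.
* The cell-body shape filter is tuned for roughly disk-shaped somata of
  50–800 px; unusually large or elongated somata will evade it and count
  as infiltration.
* The sliding-window Spearman statistic pools planes across animals within
  a window; it is a descriptive profile statistic, not a mixed-model
  inference.
* Fixtures model one tissue archetype (two cortex bands flanking a
  neuropil band in longitudinal section); they validate the algorithms,
  not anatomical generality.
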