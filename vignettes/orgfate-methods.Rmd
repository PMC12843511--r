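---
title: "Methods: organoid time-lapse morphometrics and outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid time-lapse morphometrics and outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`orgfate` implements an analysis pipeline for 96-well brightfield
time-lapse screens in which each well holds a single organoid and the goal
is to predict, from early frames, a tissue outcome — here the emergence
and size of retinal pigmented epithelium (RPE) and of lenses — that only
becomes visible near the end of the imaging window. The pipeline spans a
synthetic acquisition generator with ground truth, segmentation with
screen QC rules, a fixed 165-feature morphometrics extractor,
pigment/lens quantification with percentile size classes, PC-space
heterogeneity diagnostics, a leave-one-experiment-out prediction harness
with calibration and ensembling, and consensus metrics over attribution
maps.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken where
the design was genuinely open. It states no empirical number that the
test suite or `scripts/acceptance.R` does not itself compute.

# The synthetic acquisition generator

## What it emulates

The generator reproduces the acquisition design of an automated widefield
screen: a 96-well plate imaged every 30 minutes over 72 hours (144
"loops"), each time point a 5-slice z-stack spaced 50 µm, one organoid
per well, roughly 69,120 images per plate. Frames are rendered lazily —
`simulate_experiment()` draws all per-well parameters, and
`render_frame()` deterministically materializes any (well, loop, z)
image — so full plates fit in memory as metadata.

Each organoid is a dark body on a bright background (body around
intensity 100–112 of 255, background around 185), with:

* **growth**: radius `r0 · (1 + g · t)` with `r0` around 120 µm and a
  per-well growth factor `g ~ N(0.55, 0.08)` over the window;
* **shape divergence**: radial harmonics whose amplitude ramps linearly
  with the loop index (up to ±12 % of the radius at the final loop), so
  organoids start near-identical and diverge — the generator analogue of
  increasing morphological heterogeneity over development;
* **batch effects**: a per-experiment illumination offset
  (`sd` = 8 intensity units) and mean-radius shift (`sd` = 6 %);
* **debris speckles**: sparse dark spots (≈ 0.2 % of the organoid area,
  55 units deep), static in the organoid's frame of reference. These both
  add realism and anchor the dynamic range that the pigment quantifier's
  min–max rescaling depends on; real brightfield wells are never
  noise-only;
* **defocus**: Gaussian blur growing with distance from the middle
  z-slice, making slice 3 of 5 the sharpest — matching a workflow in
  which only the middle slice feeds the analysis;
* **exclusions**: each well may suffer an out-of-focus/out-of-frame event
  (probability 0.02 by default); from that loop onward all frames of the
  well are excluded, so the excluded set is upward-closed by construction.

## The latent fate signal

Fated wells carry a subtle texture cue from the first loop: an oriented
sinusoid (pigment fate) or a concentric ripple (lens fate) of amplitude
`signal_strength` (default 2 intensity units, "subtle"; 0 disables it;
the desk-scale recovery benchmark uses 6, "strong"). The two cues live at
distinct spatial wavelengths (12 µm and 24 µm, floored at 4 px), so their
second-order statistics are separable — without this, an organoid fated
for one tissue is indistinguishable in texture statistics from one fated
for the other, and no classifier can attribute the cue to the right
outcome. The cue is invisible to plain thresholding but detectable by
variance-of-Laplacian-type statistics, emulating a determination signal
that precedes visibility and defeats human inspection.

Visible structures appear late: pigment from loop 136 of 144 and the lens
from loop 118 by default (the proportional positions of roughly 68 h and
59 h in a 72 h window), each growing in over six loops.

## Ground truth consistency

Tissue areas are drawn from log-normal distributions (medians ≈ 6,000 µm²
for pigment and ≈ 22,000 µm² for lens, chosen so the published class
cutoffs fall inside the distributions), then **capped to what fits inside
the grown organoid** and, for pigment, replaced by the exact rasterized
area of the rendered granule union. The stored `rpe_area_um2` therefore
equals the number of rendered pigment pixels times `um_per_px²` — the
generator never claims more tissue than it draws.

Pigment is rendered as a **union of melanin granules** (discs of 6–12 µm
radius filling a circular envelope to ≈ 55 %) rather than a solid patch.
This is both closer to real granular pigmentation and essential for the
quantifier: Sauvola's local threshold with a 15 px window cannot detect
the interior of a uniform dark region much larger than its window, while
granules with tissue gaps keep local contrast everywhere.

## Calibration

No µm/px calibration is published for the emulated microscopes, so the
scale is a configuration convention: `um_per_px = 1.5` by default on
512 px frames (organoid diameter ≈ 2/3 of the frame). Coarser desk-scale
configurations (e.g. 96 px at 5 µm/px) render the same content faster;
areas always convert through `um_per_px²`.

# Segmentation and QC

`segment_frame()` resamples to a 512 px working resolution with an
area-averaging policy and applies a classical segmenter by default:
Gaussian smoothing, a robust dark-side threshold, hole filling, and
keep-largest-component. Any callable with the same soft-mask contract
(e.g. a trained network) can replace it.

Two numerical points deserve note:

* **Multilevel thresholding.** Yen's entropic criterion occasionally
  prefers a small very-dark class (debris, pigment) over the
  organoid/background split — a known behaviour of the criterion when a
  tight background mode meets a heavy dark tail. The ROI finder detects
  this (the candidate is tiny, or its immediate surround is tissue-dark
  rather than background-bright) and recomputes Yen's threshold on the
  brighter remainder, up to three times.
* **Intermeans refinement.** Yen's cut sits close to the dark mode, which
  places the boundary high on the blurred edge ramp and dilates masks by
  1–2 px. One intermeans step (threshold midway between the class means)
  moves the boundary to the ramp midpoint, making mask areas stable under
  resampling round trips (the package tests demand ≤ 5 % drift for smooth
  discs; the implementation achieves well under 1 %).

`postprocess_mask()` binarizes at half the soft-mask maximum, counts
connected components and the bounding box at the working resolution, and
rejects frames with more than one mask or a bounding-box side above
360 px (at 512 px working resolution; the limit scales proportionally at
other working sizes). The accepted mask is resampled to the original
shape with the linear-interpolation policy. Whether the original screen
applied the 360 px rule at working or native resolution is not
documented; working resolution is used here because it matches the
360 × 360 crop contract of the image-classifier path.

# The 165-feature morphometrics registry

The registry pins exactly 165 named features per (organoid, loop):

* 30 standard region/intensity descriptors (areas, bounding box,
  centroids, eccentricity, axis lengths, orientation, perimeter,
  solidity, Feret diameter, Euler number, extent, intensity statistics);
* 110 moment features: binary and intensity-weighted raw, central and
  normalized moments to order 3, plus both Hu invariant sets;
* 5 inertia-tensor features; 4 further geometry descriptors (weighted
  local centroid, convex perimeter, radius of gyration);
* the 7 custom shape formulas — aspect ratio, roundness
  `4·area/(π·major²)`, compactness `perimeter²/area`, circularity =
  form factor `4π·area/perimeter²`, effective diameter `2√(area/π)`,
  convexity `convex perimeter / perimeter`;
* the 9 custom intensity formulas — blur (variance of the 4-neighbour
  Laplacian response within the mask), ROI and image contrast, median,
  modal value, integrated and raw integrated density, skewness and
  kurtosis of the in-mask intensity distribution.

Conventions fixed for determinism: moments use zero-based
bounding-box-local (row, col) coordinates, so they are translation
invariant; intensity standard deviation is the population form; skewness
and kurtosis (excess) use population moments and are defined as 0 for a
flat distribution; the modal value bins intensities to integers and
breaks ties toward the smallest intensity; the perimeter uses the
weighted border-pixel estimator so a rasterized disc has circularity near
1. The feature count — the one hard constraint — is enforced by the
registry and asserted on every extraction.

# Tissue quantification and size classes

`quantify_rpe_area()` mirrors the published measurement chain: organoid
ROI by Yen's global threshold (with the multilevel fallback above),
8-bit conversion, min–max rescaling within the ROI, then Sauvola's local
threshold (radius 15 px, k = 0.5, r = 128) with pigment taken as the
darker-than-local-context side. The original description leaves the
orientation convention implicit; selecting the below-threshold side is
the standard dark-object convention and is what makes a pigment-free
organoid yield a near-zero area. Out-of-ROI pixels are set dark so the
ROI rim is never darker than its local context.

Lens areas are circles: `π(r·um_per_px)²` from a radius or two-point
diameter annotation; in synthetic mode `fit_lens_circle()` recovers the
radius of the bright in-mask disc (with the rim eroded away first).

`assign_size_class()` maps absent → 0 and otherwise bins by the 33rd/66th
percentiles of pooled positive areas (classes 1/2/3), boundaries closed
on the lower bin — matching "below the 33rd percentile" phrasing; the
exact closure at the cutoffs is not documented and is fixed here for
determinism. `bin_center_distance()` normalizes each sample's distance to
its bin's midpoint (0 = centre, 1 = edge) with the outer bins bounded by
the pooled minimum and maximum.

# Heterogeneity and embedding fidelity

Morphometrics are z-scaled and projected to 20 principal components;
every quantitative distance lives in this PC space. When a subset (e.g.
untreated wells) is analysed, scaling is fitted before subsetting to
preserve the numerical space. Inter-organoid heterogeneity is the mean
pairwise Euclidean distance per loop; intra-organoid change is the
distance between consecutive loops per organoid, winsorized at the
2.5th/97.5th percentiles of the pooled series (SEM = sd/√n per loop).
Embedding fidelity uses the Jaccard index of 30-nearest-neighbour sets
between spaces and the fraction of 30 nearest neighbours sharing the
organoid label; ties break by row index. Whether the original analysis
fitted PCA per experiment or pooled is not documented; both are
supported, with the pooled fit used by `heterogeneity_trend()`.

# Prediction harness

`make_loeo_splits()` makes one fold per experiment (that experiment is
the test set) and splits the remaining organoids 90/10 into training and
validation at the organoid level, so every frame of an organoid lands on
one side; `floor`, minimum one validation organoid. Leakage is asserted,
not assumed.

Tabular classifiers consume features z-scaled then min–max-scaled to
[0, 1] with statistics fitted on training rows only. The roster (random
forest, multinomial logistic, QDA) sits behind a `fit`/`predict_proba`
contract; `halving_search()` provides a successive-halving random search
(reduction factor 3, 5-fold CV) for tuning.

The image path crops a 360 × 360 square centred on the mask, pads with
the background median where needed, resamples to 224 × 224, scales to
[0, 1] and standardizes organoid pixels only. The default model is a
deliberately small trainable classifier — a fixed seeded bank of random
3 × 3 convolution filters (two ReLU/mean-pool blocks) feeding pooled
activation statistics into a multinomial-logistic head trained by
mini-batch gradient descent with class weights `n/(K·n_c)`,
gradient-norm clipping at 1.0, the learning rate halved after 7 epochs
without validation-loss improvement, and the best state kept by
validation loss. Large pretrained networks remain pluggable behind the
same contract; the point exercised here is the harness, not the
architecture. One deliberate deviation from the source workflow: its
scheduler monitored test-set F1, which leaks test information; this
implementation monitors validation loss.

Calibration is single-temperature scaling fitted on validation logits (a
1-D convex problem solved by golden-section search on log T); it never
changes predicted labels. Ensembles average calibrated probabilities
weighted by each member's best validation F1 — validation, not test,
because the test set must stay untouched; the source description is
ambiguous on this point. Baseline twins are trained on seeded
organoid-level label permutations.

Evaluation is the weighted-average F1 per loop; curves are summarized per
experiment by trapezoidal AUC normalized by the time span (the mean F1
over the window), compared across methods by paired Wilcoxon signed-rank
tests with Holm–Bonferroni adjustment. Zero differences use Pratt's
method (kept in the ranking, excluded from the statistic) because the
source does not state a policy and Pratt is deterministic under ties;
all differences zero yields p = 1. `morphology_cluster_targets()`
generates the four-class unsupervised target: z-scale, 15 PCs, seeded
k-means with 10 restarts.

# Saliency consensus

Attribution maps are inputs (any backend, or `simulate_saliency_maps()`
which crosses models × methods × loops with controllable hotspot sharing
and a scrambled baseline condition). Maps are z-scored inside the
organoid mask; all metrics ignore out-of-mask content. The four analyses:

1. **Pairwise method Dice** at the top 1 %, 5 % and 10 % of in-mask
   saliency, averaged over the three thresholds;
2. **Cross-model rank correlation**: average ranks of |saliency| followed
   by product-moment correlation (= Spearman);
3. **Top-10 % entropy** (natural log; the base is a convention recorded
   here) and **centre-of-mass drift** between consecutive loops;
4. **Superpixel votes**: SLIC-style localized k-means within the mask
   (50 segments, compactness 0.1, 10 iterations, connectivity not
   enforced), each region scored by mean saliency per method, a vote when
   the score is in the top 10 % of region scores, reporting the fraction
   of regions with ≥ 2/3/4 method votes.

Ties in top-fraction selection break by pixel index. Region voting uses
z-scored maps, consistent with the preceding normalization step (the
source does not fully pin this down).

# Problem sizes and what the tests show

The desk-scale recovery benchmark uses 3 experiments × 24 wells ×
36 loops at 96 px / 5 µm-per-px with the strong cue (amplitude 6),
training a random forest per leave-one-experiment-out fold next to its
shuffled-label twin and comparing mean test F1 over the first third of
loops. The heterogeneity trend uses 16 wells × 36 loops with ground-truth
masks. Quantification accuracy is checked at the default 512 px scale.
These sizes make the full suite and the acceptance script complete in
minutes on one CPU while still exercising every stage end to end.

Passing tests show that the pipeline recovers what the generator planted:
a latent texture cue, granular pigment of known area, a monotone
divergence schedule. Real micrographs differ in ways the generator does
not emulate — uneven illumination within a frame, organoid translucency
structure, focus drift, multi-organoid debris, annotation noise beyond
the modeled disagreement — so green tests certify the machinery, not
biological performance; absolute F1 values on real data depend on
dataset scale and model capacity outside this package's scope.

# Known limitations

* The classical default segmenter assumes a dark organoid on a bright
  background; other contrasts need a custom segmenter behind the same
  contract.
* Sauvola-based pigment quantification systematically misses uniform
  pigment regions much larger than its window; the granular rendering
  sidesteps this, but the limitation is inherited from the method itself.
* The exact composition of the 165-feature registry beyond the named
  descriptors is this package's pinned choice; only the count and the
  named features are contractual.
* The SLIC implementation does not enforce region connectivity;
  fragmented regions are possible on elongated masks.
* Saliency maps are consumed, not produced: no attribution algorithms are
  implemented here.
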