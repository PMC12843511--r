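# orgfate

Tools for 96-well brightfield time-lapse screens of single organoids,
built around one question: can a tissue outcome that only becomes visible
late in development — pigmented epithelium (RPE) or a lens in retinal
organoids — be predicted from frames taken long before it appears?

The package provides the full analysis chain as composable,
data-frame-first functions:

* a **seeded synthetic acquisition generator** reproducing the screen
  design (96 wells, images every 30 min over 72 h = 144 time points,
  5-slice z-stacks 50 µm apart, one organoid per well) with a
  controllable latent fate cue, late-appearing tissue structures,
  batch effects and ground-truth masks/areas;
* **segmentation + QC**: classical dark-object segmentation at a 512 px
  working resolution, binarization at half the soft-mask maximum, and the
  screen exclusion rules (multiple masks, bounding box over 360 px);
* a **165-feature morphometrics registry** per (organoid, time point):
  standard region properties, binary and intensity-weighted image
  moments, and custom shape/intensity formulas such as
  circularity = 4π·area/perimeter² and blur = Var(Laplacian) in the mask;
* **tissue quantification**: pigment area by Yen global + Sauvola local
  thresholding (radius 15 px, k = 0.5, r = 128) on the min–max-rescaled
  ROI; lens areas as circles π(r·µm/px)²; four size classes split at the
  33rd/66th percentiles of pooled positive areas;
* **heterogeneity diagnostics** in a 20-component PC space: mean pairwise
  inter-organoid distance per time point, winsorized frame-to-frame
  intra-organoid change, k-nearest-neighbour Jaccard embedding fidelity;
* a **leave-one-experiment-out prediction harness**: organoid-grouped
  90/10 train/validation splits, leakage-safe scaling, a classifier
  roster plus a small trainable convolutional stand-in, temperature
  calibration, validation-F1-weighted ensembling, per-timepoint weighted
  F1 curves, time-normalized trapezoidal AUC, and paired Wilcoxon +
  Holm–Bonferroni comparisons against shuffled-label baselines;
* **saliency consensus metrics** over attribution maps: top-percentile
  Dice between methods, Spearman rank agreement between models, top-10 %
  entropy, centre-of-mass drift, and SLIC superpixel region votes.

## Tests

```r
testthat::test_dir("tests/testthat", package = "orgfate",
                   load_package = "installed")
```

## Worked example

```r
library(orgfate)

# a small synthetic screen: 2 experiments x 12 wells, 36 half-hour loops
cfg  <- acquisition_config(n_experiments = 2, wells_per_plate = 12,
                           duration_h = 18, frame_px = 96, um_per_px = 5,
                           seed = 1)
fate <- fate_spec(rpe_visible_loop = 34, lens_visible_loop = 30,
                  signal_strength = 6, exclusion_prob = 0)
ds <- simulate_experiment(cfg, fate)
ds
#> <organoid_dataset> 2 experiment(s) x 12 wells x 36 loops x 5 z-slices (96 px frames)

# segment one frame and extract the 165 morphometrics
img  <- render_frame(ds, "E001", "A01", loop = 10)
soft <- segment_frame(img, working_px = 96)
seg  <- postprocess_mask(soft, dim(img), size_limit_px = 68)
seg
#> <segmentation_result> accepted (components=1, bbox=55x54, reason=none)
feats <- extract_features(img, seg$mask)
ncol(feats)
#> [1] 165

# quantify pigment from the stereo-style image and bin into size classes
q <- quantify_rpe_area(render_stereo(ds, "E001", "A01"), um_per_px = 5)
cuts <- class_cutoffs(4541.73, 7548.51, "RPE")
assign_size_class(q$area_um2, present = q$area_um2 > 0, cuts)

# end-to-end: features -> leave-one-experiment-out outcome prediction
# against a shuffled-label baseline, early-window test F1 gap
bench <- run_outcome_benchmark(benchmark_dataset(signal_strength = 6,
                                                 seed = 1),
                               task = "rpe_emergence", seed = 1)
round(bench$early_gap, 2)
#> [1] 0.3
plot_f1_curves(bench$curves)
```

The gap printed above is the difference in mean test-set weighted F1 over
the first third of time points between the trained classifier and its
shuffled-label twin: a positive gap means the latent fate cue planted by
the generator was recovered from frames taken long before the tissue is
visible. With `signal_strength = 0` the same pipeline reports a gap
statistically indistinguishable from zero.

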