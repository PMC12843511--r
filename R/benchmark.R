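# Desk-scale end-to-end benchmark: generate a synthetic multi-experiment
# dataset, run segmentation + morphometrics, train outcome classifiers per
# leave-one-experiment-out fold alongside shuffled-label baseline twins, and
# summarize the early-window test F1 gap.

#' Build the desk-scale benchmark dataset
#'
#' Three experimental replicates of 24 wells imaged over 36 loops at a
#' coarse pixel calibration (96 px frames, 5 um/px), with tissue
#' visibility placed late in the window in proportion to the full design.
#'
#' @param signal_strength Amplitude of the latent fate cue (0 disables it).
#' @param seed Integer seed.
#' @param n_experiments,wells_per_plate,n_loops,frame_px,um_per_px
#'   Desk-scale acquisition geometry.
#' @return An `organoid_dataset`.
#' @export
benchmark_dataset <- function(signal_strength = 6, seed = 1L,
                              n_experiments = 3L, wells_per_plate = 24L,
                              n_loops = 36L, frame_px = 96L, um_per_px = 5) {
  cfg <- acquisition_config(
    n_experiments = n_experiments, wells_per_plate = wells_per_plate,
    duration_h = n_loops / 2, interval_min = 30, n_z = 5,
    frame_px = frame_px, um_per_px = um_per_px, seed = seed)
  fate <- fate_spec(
    rpe_prob = 0.5, lens_prob = 0.5,
    rpe_visible_loop = max(2L, round(136 / 144 * n_loops)),
    lens_visible_loop = max(2L, round(118 / 144 * n_loops)),
    signal_strength = signal_strength,
    exclusion_prob = 0)
  simulate_experiment(cfg, fate)
}

#' Run the outcome-prediction benchmark with baseline twins
#'
#' End-to-end: renders middle-slice frames, segments them with the
#' classical segmenter, extracts the 165 morphometrics, builds
#' leave-one-experiment-out splits, and trains — per fold — an outcome
#' classifier plus a shuffled-label baseline twin. Reports per-loop test
#' F1 curves and the early-window (first third of loops) mean F1 gap with
#' the baseline's dispersion across folds.
#'
#' @param ds Dataset from [benchmark_dataset()] (or compatible).
#' @param task `"rpe_emergence"` or `"lens_emergence"`.
#' @param model Tabular classifier kind (default `"rf"`).
#' @param features Optional precomputed morphometrics table (reused across
#'   calls to avoid re-rendering).
#' @param seed Integer seed.
#' @return List: `curves` (tibble of per-loop test F1, `condition` in
#'   trained/baseline, per fold), `early_gap` (trained minus baseline mean
#'   early F1), `baseline_sem_early` (SEM of the baseline early F1 across
#'   folds), `features`, `splits`.
#' @export
run_outcome_benchmark <- function(ds, task = c("rpe_emergence",
                                               "lens_emergence"),
                                  model = "rf", features = NULL,
                                  seed = 1L) {
  task <- match.arg(task)
  if (is.null(features))
    features <- compute_morphometrics(ds, working_px = ds$cfg$frame_px)
  out <- dataset_outcomes(ds)
  labels <- tibble::tibble(
    experiment_id = out$experiment_id, well_id = out$well_id,
    label = if (task == "rpe_emergence")
      ifelse(out$rpe_present, "present", "absent")
    else ifelse(out$lens_present, "present", "absent"))
  splits <- make_loeo_splits(labels, seed = seed)
  assert_no_leakage(splits)
  folds <- unique(splits$fold_id)
  curves <- purrr::map_dfr(folds, function(f) {
    sp <- splits[splits$fold_id == f, ]
    purrr::map_dfr(c(trained = FALSE, baseline = TRUE), function(shuf) {
      run <- train_feature_classifier(features, labels, sp, model = model,
                                      shuffle_labels = shuf,
                                      seed = derive_seed(seed, f, 107L))
      cv <- f1_over_time(run, "test")
      cv$condition <- if (shuf) "baseline" else "trained"
      cv
    })
  })
  early <- seq_len(max(1L, ds$cfg$n_loops %/% 3L))
  early_f1 <- dplyr::filter(curves, .data$loop %in% early) |>
    dplyr::group_by(.data$condition, .data$fold_id) |>
    dplyr::summarise(f1 = mean(.data$f1), .groups = "drop")
  mean_by <- function(cond) mean(early_f1$f1[early_f1$condition == cond])
  base <- early_f1$f1[early_f1$condition == "baseline"]
  list(curves = curves,
       early_f1 = early_f1,
       early_gap = mean_by("trained") - mean_by("baseline"),
       baseline_sem_early = stats::sd(base) / sqrt(length(base)),
       features = features, splits = splits, task = task)
}

#' Inter-organoid heterogeneity trend on a synthetic dataset
#'
#' Computes the morphometrics (ground-truth masks), fits the 20-component
#' PC space, and returns the per-loop mean pairwise inter-organoid
#' distance with its Spearman correlation against loop index.
#'
#' @param ds An `organoid_dataset`.
#' @param loops Loops to analyse (default: all).
#' @param n_components PC-space dimensionality (default 20).
#' @return List: `per_loop` tibble, `spearman_rho`, `pc_space`.
#' @export
heterogeneity_trend <- function(ds, loops = seq_len(ds$cfg$n_loops),
                                n_components = 20L) {
  feats <- compute_morphometrics(ds, loops = loops, use_true_mask = TRUE)
  space <- suppressWarnings(fit_pc_space(feats, n_components))
  pcs <- project_pc_space(space, feats)
  per_loop <- inter_organoid_distance(pcs)
  rho <- stats::cor(per_loop$loop, per_loop$mean_distance,
                    method = "spearman")
  list(per_loop = per_loop, spearman_rho = rho, pc_space = space,
       features = feats)
}
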