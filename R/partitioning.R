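# Leave-one-experiment-out splits, two-annotator consensus ground truth,
# and the balanced expert-panel subset sampler.

#' Leave-one-experiment-out split plans
#'
#' One fold per experiment: that experiment is the test set; the organoids
#' of the remaining experiments are split 90/10 into training and internal
#' validation at the organoid level, so all frames of an organoid fall on
#' one side. The validation count per fold is `floor(val_frac * n)` with a
#' minimum of one organoid.
#'
#' @param organoids Tibble with `experiment_id` and `well_id` (one row per
#'   organoid).
#' @param val_frac Validation fraction of non-test organoids (default 0.10).
#' @param seed Integer seed.
#' @return Tibble with one row per (fold, organoid): `fold_id`,
#'   `test_experiment`, `experiment_id`, `well_id`,
#'   `partition` in `{"train", "validation", "test"}`.
#' @export
make_loeo_splits <- function(organoids, val_frac = 0.10, seed = 1L) {
  stopifnot(all(c("experiment_id", "well_id") %in% names(organoids)))
  org <- dplyr::distinct(organoids, .data$experiment_id, .data$well_id)
  exps <- sort(unique(org$experiment_id))
  if (length(exps) < 2) stop("need at least 2 experiments")
  counts <- table(org$experiment_id)
  if (any(counts == 0)) stop("experiment with zero organoids")
  purrr::map_dfr(seq_along(exps), function(f) {
    test_exp <- exps[f]
    rest <- org[org$experiment_id != test_exp, ]
    n_val <- max(1L, floor(val_frac * nrow(rest)))
    val_idx <- with_seed(derive_seed(seed, f, 31L),
                         sample(nrow(rest), n_val))
    rest$partition <- "train"
    rest$partition[val_idx] <- "validation"
    test <- org[org$experiment_id == test_exp, ]
    test$partition <- "test"
    out <- dplyr::bind_rows(rest, test)
    out$fold_id <- f
    out$test_experiment <- test_exp
    out[, c("fold_id", "test_experiment", "experiment_id", "well_id",
            "partition")]
  })
}

#' Assert that a split plan has no organoid-level leakage
#'
#' Checks, per fold, that the three partitions are disjoint at the organoid
#' level and jointly cover every organoid.
#' @param splits Output of [make_loeo_splits()].
#' @return Invisibly TRUE; errors otherwise.
#' @export
assert_no_leakage <- function(splits) {
  for (f in unique(splits$fold_id)) {
    s <- splits[splits$fold_id == f, ]
    key <- paste(s$experiment_id, s$well_id)
    if (anyDuplicated(key))
      stop("organoid assigned to multiple partitions in fold ", f)
  }
  n_org <- length(unique(paste(splits$experiment_id, splits$well_id)))
  per_fold <- table(splits$fold_id)
  if (any(per_fold != n_org)) stop("split plan does not cover all organoids")
  invisible(TRUE)
}

#' Two-annotator consensus ground truth
#'
#' Agreement yields the common label at high confidence; disagreement
#' yields low confidence, with a seeded fair coin choosing which
#' annotator's label enters the ground truth. The disagreement rate is
#' reported alongside.
#'
#' @param ann1,ann2 Label vectors of the same length (same organoid order).
#' @param seed Integer seed for the coin flips.
#' @return List: `labels` tibble (`label`, `confidence`, `chosen_annotator`)
#'   and `disagreement_rate`.
#' @export
consensus_ground_truth <- function(ann1, ann2, seed = 1L) {
  if (length(ann1) != length(ann2)) stop("annotators labelled different sets")
  if (anyNA(ann1) || anyNA(ann2)) stop("missing label from an annotator")
  agree <- ann1 == ann2
  coin <- with_seed(derive_seed(seed, 17L),
                    stats::runif(length(ann1)) < 0.5)
  label <- ifelse(agree, ann1, ifelse(coin, ann1, ann2))
  chosen <- ifelse(agree, NA_integer_, ifelse(coin, 1L, 2L))
  list(labels = tibble::tibble(
         label = label,
         confidence = ifelse(agree, "high", "low"),
         chosen_annotator = chosen),
       disagreement_rate = mean(!agree))
}

#' Balanced expert-panel image assignment
#'
#' Bins loops into equal timeframes and assigns, per (experiment, well,
#' timeframe), one image to each annotator: sampling without replacement
#' when the pool holds at least `n_annotators` unique images, with
#' replacement otherwise (so a file may repeat across, never within, an
#' annotator). Wells missing a timeframe entirely are skipped for all
#' annotators, keeping loads equal. One seeded stream per
#' (experiment, well, timeframe) keeps existing assignments stable when
#' wells are added.
#'
#' @param metadata Tibble of available images: `experiment_id`, `well_id`,
#'   `loop`, `image_id` (middle-slice rows).
#' @param n_annotators Number of annotators (default 6).
#' @param n_timeframes Number of equal loop bins (default 6).
#' @param n_loops Total loops (default: max loop in metadata).
#' @param seed Integer seed.
#' @return List: `tasks` tibble (`annotator`, `experiment_id`, `well_id`,
#'   `timeframe`, `loop`, `image_id`) and `n_duplicates` (assignments of a
#'   file to more than one annotator).
#' @export
expert_subset_assignment <- function(metadata, n_annotators = 6L,
                                     n_timeframes = 6L, n_loops = NULL,
                                     seed = 1L) {
  stopifnot(all(c("experiment_id", "well_id", "loop", "image_id") %in%
                names(metadata)))
  if (is.null(n_loops)) n_loops <- max(metadata$loop)
  if (n_loops %% n_timeframes != 0)
    stop("loops do not bin into equal timeframes")
  per_tf <- n_loops / n_timeframes
  md <- dplyr::mutate(metadata,
                      timeframe = as.integer(ceiling(.data$loop / per_tf)))
  exps <- sort(unique(md$experiment_id))
  tasks <- dplyr::group_by(md, .data$experiment_id, .data$well_id,
                           .data$timeframe) |>
    dplyr::group_modify(function(d, key) {
      e <- match(key$experiment_id, exps)
      wkey <- sum(utf8ToInt(key$well_id))
      pick <- with_seed(derive_seed(seed, e, wkey, key$timeframe, 41L), {
        if (nrow(d) >= n_annotators) sample(nrow(d), n_annotators)
        else sample(nrow(d), n_annotators, replace = TRUE)
      })
      tibble::tibble(annotator = seq_len(n_annotators),
                     loop = d$loop[pick], image_id = d$image_id[pick])
    }) |>
    dplyr::ungroup()
  # sanity checks mirrored from the sampling design
  loads <- table(tasks$annotator)
  stopifnot(length(unique(loads)) == 1L)
  per_ann_dup <- dplyr::group_by(tasks, .data$annotator) |>
    dplyr::summarise(d = anyDuplicated(.data$image_id), .groups = "drop")
  stopifnot(all(per_ann_dup$d == 0L))
  dup <- sum(table(tasks$image_id) - 1L)
  list(tasks = tasks, n_duplicates = dup)
}
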