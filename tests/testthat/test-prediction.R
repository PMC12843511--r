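fake_features <- function(n_exp = 3, per_exp = 10, loops = 4, seed = 1,
                          informative = TRUE) {
  set.seed(seed)
  wells <- tidyr::expand_grid(experiment_id = sprintf("E%03d", 1:n_exp),
                              well_id = sprintf("W%02d", 1:per_exp))
  wells$label <- rep_len(c("present", "absent"), nrow(wells))
  rows <- tidyr::expand_grid(wells, loop = seq_len(loops))
  p <- 8
  X <- matrix(rnorm(nrow(rows) * p), ncol = p)
  if (informative)
    X[, 1] <- X[, 1] + ifelse(rows$label == "present", 2, -2)
  colnames(X) <- feature_registry()$name[seq_len(p)]
  list(features = dplyr::bind_cols(rows[, c("experiment_id", "well_id",
                                            "loop")],
                                   tibble::as_tibble(X)),
       labels = wells)
}

test_that("feature scaling is fitted on training rows only", {
  set.seed(2)
  Xtr <- matrix(rnorm(200, 5, 2), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  sc <- fit_feature_scaler(Xtr)
  Ztr <- apply_feature_scaler(sc, Xtr)
  expect_equal(unname(apply(Ztr, 2, min)), rep(0, 4))
  expect_equal(unname(apply(Ztr, 2, max)), rep(1, 4))
  # out-of-sample rows may exceed [0, 1]: statistics came from training only
  Xte <- matrix(rnorm(40, 9, 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Zte <- apply_feature_scaler(sc, Xte)
  expect_true(any(Zte < 0 | Zte > 1))
})

test_that("the fold harness recovers an informative signal over baseline", {
  fx <- fake_features(informative = TRUE)
  splits <- make_loeo_splits(fx$labels, seed = 1)
  sp <- splits[splits$fold_id == 1, ]
  run <- train_feature_classifier(fx$features, fx$labels, sp, model = "rf",
                                  seed = 1)
  base <- train_feature_classifier(fx$features, fx$labels, sp, model = "rf",
                                   shuffle_labels = TRUE, seed = 1)
  te <- run$predictions[run$predictions$partition == "test", ]
  tb <- base$predictions[base$predictions$partition == "test", ]
  expect_gt(f1_weighted(te$truth, te$pred),
            f1_weighted(tb$truth, tb$pred) + 0.2)
  expect_error(train_feature_classifier(
    fx$features, dplyr::mutate(fx$labels, label = "present"), sp),
    "class")
})

test_that("weighted F1 matches closed forms and a brute-force oracle", {
  expect_equal(f1_weighted(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 50/50 binary truth, constant single-class prediction:
  # predicted class F1 = 2/3 with weight .5; other class 0 -> total 1/3
  truth <- rep(c("p", "n"), 10)
  expect_equal(f1_weighted(truth, rep("p", 20)), 1 / 3)
  set.seed(5)
  for (i in 1:10) {
    t <- sample(letters[1:3], 30, replace = TRUE)
    p <- sample(letters[1:3], 30, replace = TRUE)
    expect_equal(f1_weighted(t, p), brute_weighted_f1(t, p), tolerance = 1e-12)
  }
})

test_that("temperature scaling recovers known scale factors", {
  set.seed(7)
  n <- 4000; K <- 3
  L <- matrix(rnorm(n * K, 0, 2), n, K, dimnames = list(NULL, letters[1:K]))
  P <- exp(L) / rowSums(exp(L))
  y <- vapply(seq_len(n), function(i)
    sample(letters[1:K], 1, prob = P[i, ]), character(1))
  t1 <- temperature_calibrate(L, y)
  expect_lt(abs(t1 - 1), 0.05)
  t3 <- temperature_calibrate(L * 3, y)
  expect_lt(abs(t3 - 3) / 3, 0.10)
  expect_error(temperature_calibrate(matrix(1, 5, 3,
    dimnames = list(NULL, letters[1:3])), c("a", "a", "b", "c", "a")),
    "degenerate")
})

test_that("temperature application rescales probabilities, not labels", {
  fx <- fake_features()
  splits <- make_loeo_splits(fx$labels, seed = 1)
  sp <- splits[splits$fold_id == 1, ]
  crops <- fx$features[, c("experiment_id", "well_id", "loop")]
  set.seed(3)
  crops$input <- lapply(seq_len(nrow(crops)), function(i) {
    lab <- fx$labels$label[match(paste(crops$experiment_id[i], crops$well_id[i]),
                                 paste(fx$labels$experiment_id, fx$labels$well_id))]
    img <- matrix(rnorm(32 * 32, ifelse(lab == "present", 0.3, -0.3), 1), 32)
    list(image = img, mask = matrix(1, 32, 32))
  })
  run <- train_image_classifier(crops, fx$labels, sp, epochs = 15, seed = 2)
  va <- run$predictions$partition == "validation"
  t <- temperature_calibrate(run$logits[va, , drop = FALSE],
                             run$predictions$truth[va])
  cal <- apply_temperature(run, t)
  expect_identical(cal$predictions$pred, run$predictions$pred)
  pcols <- paste0("p_", run$classes)
  expect_false(isTRUE(all.equal(as.matrix(cal$predictions[, pcols]),
                                as.matrix(run$predictions[, pcols]))))
  expect_equal(unname(rowSums(as.matrix(cal$predictions[, pcols]))),
               rep(1, nrow(cal$predictions)), tolerance = 1e-9)
})

test_that("image-classifier contract: crop geometry and organoid-only norm", {
  img <- matrix(100, 500, 500)
  msk <- disc_mask(500, 60, ctr = c(120, 380))
  img[msk > 0] <- 160
  out <- prepare_cnn_input(img, msk)
  expect_equal(dim(out$image), c(224, 224))
  expect_equal(dim(out$mask), c(224, 224))
  # background pixels are untouched by the organoid-only normalization:
  # they keep the plain [0, 1] intensity scale (boundary pixels may mix
  # through resampling, so compare medians and signs)
  bg <- out$image[out$mask == 0]
  expect_equal(stats::median(bg), 100 / 255, tolerance = 1e-6)
  expect_true(all(bg >= 0))                 # standardization would go negative
  # organoid pixels are standardized
  inm <- out$image[out$mask > 0]
  expect_lt(abs(mean(inm)), 0.2)
  expect_true(any(inm < 0))

  # crop exceeding the frame pads with the background value
  msk2 <- disc_mask(500, 60, ctr = c(40, 40))
  out2 <- prepare_cnn_input(img, msk2)
  expect_equal(dim(out2$image), c(224, 224))

  # augmentation off + same inputs -> identical tensors; augmenter is seeded
  outA <- prepare_cnn_input(img, msk)
  expect_identical(out$image, outA$image)
  aug1 <- make_augmenter(seed = 5)
  aug2 <- make_augmenter(seed = 5)
  a1 <- prepare_cnn_input(img, msk, augment = aug1)
  a2 <- prepare_cnn_input(img, msk, augment = aug2)
  expect_identical(a1$image, a2$image)
})

test_that("the tiny image classifier beats its shuffled-label twin", {
  # enough organoids that a label permutation sits near chance agreement
  fx <- fake_features(per_exp = 20, loops = 3)
  splits <- make_loeo_splits(fx$labels, seed = 2)
  sp <- splits[splits$fold_id == 2, ]
  crops <- fx$features[, c("experiment_id", "well_id", "loop")]
  set.seed(11)
  crops$input <- lapply(seq_len(nrow(crops)), function(i) {
    lab <- fx$labels$label[match(paste(crops$experiment_id[i], crops$well_id[i]),
                                 paste(fx$labels$experiment_id, fx$labels$well_id))]
    base <- matrix(rnorm(32 * 32, 0, 0.5), 32)
    if (lab == "present") base <- base + 0.8 * sin(outer(1:32, 1:32, "+") / 2)
    list(image = base, mask = matrix(1, 32, 32))
  })
  run <- train_image_classifier(crops, fx$labels, sp, epochs = 25, seed = 3)
  twin <- train_image_classifier(crops, fx$labels, sp, epochs = 25,
                                 shuffle_labels = TRUE, seed = 3)
  te <- run$predictions$partition == "test"
  f_run <- f1_weighted(run$predictions$truth[te], run$predictions$pred[te])
  f_twin <- f1_weighted(twin$predictions$truth[te], twin$predictions$pred[te])
  expect_gt(f_run, f_twin + 0.2)
  # class-weight formula: weight_c proportional to n / (K * n_c)
  n_c <- table(run$predictions$truth[run$predictions$partition == "train"])
  w <- sum(n_c) / (length(n_c) * n_c)
  expect_equal(unname(w / w[1]), unname((1 / n_c) / (1 / n_c[1])))
})

test_that("ensembling follows the stated weighting rules", {
  fx <- fake_features()
  splits <- make_loeo_splits(fx$labels, seed = 1)
  sp <- splits[splits$fold_id == 1, ]
  r1 <- train_feature_classifier(fx$features, fx$labels, sp, "rf", seed = 1)
  r2 <- train_feature_classifier(fx$features, fx$labels, sp, "logreg",
                                 seed = 1)
  pcols <- paste0("p_", r1$classes)

  only1 <- ensemble_predict(list(r1, r2), weights = c(1, 0))
  expect_equal(as.matrix(only1$predictions[, pcols]),
               as.matrix(r1$predictions[, pcols]), tolerance = 1e-12)

  eq <- ensemble_predict(list(r1, r2), weights = c(1, 1))
  expect_equal(as.matrix(eq$predictions[, pcols]),
               (as.matrix(r1$predictions[, pcols]) +
                as.matrix(r2$predictions[, pcols])) / 2, tolerance = 1e-12)

  expect_error(ensemble_predict(list()), "empty")

  # ensemble weighted by validation F1 at least matches the weaker member
  # on test F1 over repeated draws
  set.seed(20)
  wins <- 0
  for (i in 1:5) {
    fxi <- fake_features(seed = 100 + i)
    spi <- make_loeo_splits(fxi$labels, seed = i)
    spi <- spi[spi$fold_id == 1, ]
    a <- train_feature_classifier(fxi$features, fxi$labels, spi, "rf",
                                  seed = i)
    b <- train_feature_classifier(fxi$features, fxi$labels, spi, "logreg",
                                  seed = i)
    en <- ensemble_predict(list(a, b))
    f <- vapply(list(a, b, en), function(r) {
      te <- r$predictions$partition == "test"
      f1_weighted(r$predictions$truth[te], r$predictions$pred[te])
    }, numeric(1))
    if (f[3] >= min(f[1:2]) - 1e-9) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("per-loop F1 curves and their AUC have the stated forms", {
  fx <- fake_features()
  splits <- make_loeo_splits(fx$labels, seed = 1)
  sp <- splits[splits$fold_id == 1, ]
  run <- train_feature_classifier(fx$features, fx$labels, sp, "rf", seed = 1)
  run$predictions$pred <- run$predictions$truth     # force perfection
  cv <- f1_over_time(run, "test")
  expect_true(all(cv$f1 == 1))
  expect_equal(nrow(cv), 4L)

  expect_equal(f1_curve_auc(1:10, rep(0.7, 10)), 0.7)
  expect_equal(f1_curve_auc(c(1, 3, 7), rep(0.4, 3)), 0.4)
  expect_equal(f1_curve_auc(c(0, 1), c(0, 1)), 0.5)
})

test_that("bin-distance stratification partitions the evaluated samples", {
  fx <- fake_features()
  splits <- make_loeo_splits(fx$labels, seed = 1)
  sp <- splits[splits$fold_id == 1, ]
  run <- train_feature_classifier(fx$features, fx$labels, sp, "rf", seed = 1)
  d <- dplyr::distinct(run$predictions, .data$experiment_id, .data$well_id)
  set.seed(4)
  d$distance <- runif(nrow(d))
  out <- f1_by_bin_distance(run, d)
  n_test <- sum(run$predictions$partition == "test")
  expect_equal(sum(out$n), n_test)
  expect_true(all(out$f1 >= 0 & out$f1 <= 1))

  # errors concentrated near bin edges depress F1 toward distance 1
  run2 <- run
  te <- run2$predictions$partition == "test"
  d2 <- dplyr::inner_join(run2$predictions[te, ], d,
                          by = c("experiment_id", "well_id"))
  flip <- d2$distance > 0.8
  run2$predictions$pred[te][flip] <-
    ifelse(d2$truth[flip] == "present", "absent", "present")
  run2$predictions$pred[te][!flip] <- d2$truth[!flip]
  out2 <- f1_by_bin_distance(run2, d)
  expect_lt(out2$f1[nrow(out2)], out2$f1[1])
})

test_that("wilcoxon with Pratt zeros and Holm adjustment are correct", {
  # identical curves -> all differences zero -> p = 1
  expect_equal(wilcoxon_signed_rank_pratt(1:5, 1:5)$p_value, 1)

  # agrees with the classical test when there are no zeros or ties
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30, 0.8)
  ours <- wilcoxon_signed_rank_pratt(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, correct = TRUE, exact = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 0.02)

  # Holm on (.01, .02, .04) -> (.03, .04, .04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "holm"), c(0.03, 0.04, 0.04))
})

test_that("classifier comparison pairs experiments and adjusts p-values", {
  curves <- tidyr::expand_grid(method = c("m1", "m2", "m3"),
                               test_experiment = sprintf("E%d", 1:6),
                               loop = 1:5)
  set.seed(2)
  curves$f1 <- ifelse(curves$method == "m1", 0.8, 0.5) +
    rnorm(nrow(curves), 0, 0.02)
  cmp <- compare_classifiers(curves)
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$p_adj >= cmp$p_value))
  best <- cmp[cmp$method_a == "m1" & cmp$method_b == "m2", ]
  expect_lt(best$p_value, 0.05)
  expect_equal(glance(cmp)$n_pairs, 3L)

  # unpaired experiments are dropped with a warning
  curves2 <- curves[!(curves$method == "m2" &
                      curves$test_experiment == "E6"), ]
  wrn <- capture_warnings(cmp2 <- compare_classifiers(curves2))
  expect_true(any(grepl("unpaired", wrn)))
  expect_equal(cmp2$n_pairs[cmp2$method_a == "m1" & cmp2$method_b == "m2"], 5L)
})

test_that("morphology clusters recover separated blobs deterministically", {
  set.seed(15)
  centers <- matrix(rnorm(4 * 20, sd = 30), 4, 20)
  X <- centers[rep(1:4, each = 12), ] + matrix(rnorm(48 * 20), 48, 20)
  colnames(X) <- feature_registry()$name[1:20]
  tab <- dplyr::bind_cols(
    tibble::tibble(experiment_id = "E001", well_id = sprintf("W%02d", 1:48),
                   loop = 10L),
    tibble::as_tibble(X))
  out <- morphology_cluster_targets(tab, n_pcs = 15, k = 4, seed = 1)
  expect_setequal(unique(out$morphology_cluster), 0:3)
  expect_equal(adjusted_rand_index(out$morphology_cluster,
                                   rep(1:4, each = 12)), 1)
  out2 <- morphology_cluster_targets(tab, n_pcs = 15, k = 4, seed = 1)
  expect_identical(out$morphology_cluster, out2$morphology_cluster)
  expect_error(morphology_cluster_targets(tab[1:3, ], k = 4), "k organoids")
})

test_that("halving search returns a ranked candidate table", {
  set.seed(44)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- ifelse(X[, 1] + rnorm(n, 0, 0.5) > 0, "a", "b")
  sampler <- function(i) list(num.trees = sample(c(10, 50, 100), 1),
                              min.node.size = sample(c(1, 5, 20), 1))
  out <- halving_search(X, y, sampler, model = "rf", n_candidates = 6,
                        min_resource = 60, seed = 2)
  expect_equal(nrow(out), 6L)
  expect_true(all(diff(out$score) <= 1e-9))
  expect_equal(sum(out$selected), 1L)
  expect_true(out$selected[1])
})
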