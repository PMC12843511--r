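# Outcome-prediction harness: leakage-safe scaling, tabular and small-image
# classifiers, temperature calibration, F1-weighted ensembling, per-loop
# weighted-F1 evaluation, and the paired statistical comparison.

# ---- scaling -------------------------------------------------------------

#' Fit the train-only feature scaler
#'
#' Z-scales each feature then min–max rescales onto \[0, 1\], with all
#' statistics taken from training rows only; validation and test rows are
#' later transformed with these fitted statistics (values may fall outside
#' \[0, 1\], which is intended).
#' @param X Numeric matrix of training rows.
#' @return List of class `feature_scaler`.
#' @export
fit_feature_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  Z <- scale(X[, keep, drop = FALSE], mu[keep], sd[keep])
  lo <- apply(Z, 2, min); hi <- apply(Z, 2, max)
  rng <- pmax(hi - lo, 1e-12)
  structure(list(mu = mu[keep], sd = sd[keep], lo = lo, rng = rng,
                 cols = colnames(X)[keep]),
            class = "feature_scaler")
}

#' Apply a fitted feature scaler
#' @param scaler A `feature_scaler`.
#' @param X Numeric matrix.
#' @return Scaled matrix restricted to the fitted columns.
#' @export
apply_feature_scaler <- function(scaler, X) {
  Z <- scale(X[, scaler$cols, drop = FALSE], scaler$mu, scaler$sd)
  sweep(sweep(Z, 2, scaler$lo), 2, scaler$rng, "/")
}

# ---- tabular classifiers -------------------------------------------------

classifier_spec <- function(kind, params = list()) {
  switch(kind,
    rf = list(
      fit = function(X, y, seed) {
        args <- c(list(x = X, y = factor(y), probability = TRUE,
                       num.trees = params$num.trees %||% 200,
                       mtry = params$mtry,
                       min.node.size = params$min.node.size,
                       seed = seed, num.threads = 1), list())
        do.call(ranger::ranger, args[!vapply(args, is.null, logical(1))])
      },
      predict_proba = function(model, X)
        stats::predict(model, data = X, num.threads = 1)$predictions),
    logreg = list(
      fit = function(X, y, seed) {
        d <- data.frame(y = factor(y), X)
        nnet::multinom(y ~ ., data = d, trace = FALSE,
                       decay = params$decay %||% 1e-4, maxit = 200,
                       MaxNWts = 100000)
      },
      predict_proba = function(model, X) {
        p <- stats::predict(model, newdata = data.frame(X), type = "probs")
        if (is.null(dim(p))) p <- cbind(1 - p, p)   # binary case
        colnames(p) <- model$lev
        p
      }),
    qda = list(
      fit = function(X, y, seed) MASS::qda(X, grouping = factor(y)),
      predict_proba = function(model, X) stats::predict(model, X)$posterior),
    stop("unknown classifier kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

join_labels <- function(features, labels) {
  lab_col <- setdiff(names(labels), c("experiment_id", "well_id"))[1]
  out <- dplyr::inner_join(features, labels,
                           by = c("experiment_id", "well_id"))
  out$.label <- out[[lab_col]]
  out
}

#' Train and evaluate a tabular-morphometrics classifier on one fold
#'
#' Scales features with train-only statistics, fits the requested
#' classifier on training frames, and predicts class probabilities for
#' validation and test frames. Any model obeying the
#' `fit`/`predict_proba` contract can be passed as `spec`.
#'
#' @param features Morphometrics tibble (`experiment_id`, `well_id`,
#'   `loop`, feature columns).
#' @param labels Tibble `experiment_id`, `well_id`, label column (one row
#'   per organoid).
#' @param split One fold of [make_loeo_splits()] output.
#' @param model `"rf"`, `"logreg"` or `"qda"`; ignored when `spec` given.
#' @param spec Optional custom `list(fit, predict_proba)`.
#' @param params Hyperparameters handed to the model spec.
#' @param shuffle_labels Train on seeded label permutation (baseline twin).
#' @param seed Integer seed.
#' @return Object of class `prediction_run`: `predictions` tibble with
#'   truth, predicted label and class probabilities per (organoid, loop),
#'   `best_val_f1`, model metadata.
#' @export
train_feature_classifier <- function(features, labels, split, model = "rf",
                                     spec = NULL, params = list(),
                                     shuffle_labels = FALSE, seed = 1L) {
  stopifnot(length(unique(split$fold_id)) == 1L)
  spec <- spec %||% classifier_spec(model, params)
  d <- join_labels(features, labels)
  d <- dplyr::inner_join(
    d, split[, c("experiment_id", "well_id", "partition")],
    by = c("experiment_id", "well_id"))
  fcols <- intersect(feature_registry()$name, names(d))
  tr <- d[d$partition == "train", ]
  if (length(unique(tr$.label)) < 2)
    stop("training fold lacks a class")
  if (shuffle_labels) {
    org <- dplyr::distinct(tr, .data$experiment_id, .data$well_id, .data$.label)
    org$.shuffled <- with_seed(derive_seed(seed, 53L),
                               sample(org$.label))
    tr <- dplyr::inner_join(dplyr::select(tr, -".label"),
      dplyr::transmute(org, experiment_id = .data$experiment_id,
                       well_id = .data$well_id, .label = .data$.shuffled),
      by = c("experiment_id", "well_id"))
  }
  scaler <- fit_feature_scaler(as.matrix(tr[, fcols]))
  Xtr <- apply_feature_scaler(scaler, as.matrix(tr[, fcols]))
  fit <- with_seed(derive_seed(seed, 59L),
                   spec$fit(Xtr, tr$.label, derive_seed(seed, 59L)))
  Xall <- apply_feature_scaler(scaler, as.matrix(d[, fcols]))
  P <- spec$predict_proba(fit, Xall)
  cls <- colnames(P)
  pred <- cls[max.col(P, ties.method = "first")]
  preds <- dplyr::bind_cols(
    d[, c("experiment_id", "well_id", "loop", "partition")],
    tibble::tibble(truth = as.character(d$.label), pred = pred),
    tibble::as_tibble(P, .name_repair = ~ paste0("p_", cls)))
  val <- preds[preds$partition == "validation", ]
  best_val_f1 <- if (nrow(val)) f1_weighted(val$truth, val$pred) else NA_real_
  structure(list(predictions = preds, classes = cls,
                 best_val_f1 = best_val_f1, model = model,
                 fold_id = split$fold_id[1],
                 test_experiment = split$test_experiment[1],
                 shuffled = shuffle_labels, scaler = scaler, fit = fit),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat("<prediction_run> model=", x$model, " fold=", x$fold_id,
      " test=", x$test_experiment,
      if (isTRUE(x$shuffled)) " (shuffled-label baseline)" else "",
      "; best validation F1=", round(x$best_val_f1, 3), "\n", sep = "")
  invisible(x)
}

# ---- hyperparameter search -----------------------------------------------

#' Successive-halving random hyperparameter search
#'
#' Samples `n_candidates` parameter settings, scores each rung by k-fold
#' cross-validated weighted F1 on a growing training subsample (resource =
#' rows, starting at `min_resource`, multiplied by `factor` per rung), and
#' keeps the best `1/factor` of candidates each rung.
#'
#' @param X Feature matrix, `y` labels.
#' @param sampler Function `(i) -> named list` of hyperparameters.
#' @param model Classifier kind for [train_feature_classifier()]'s roster.
#' @param n_candidates Initial number of sampled settings.
#' @param factor Reduction factor per rung (default 3).
#' @param min_resource Rows used in the first rung.
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return Tibble of candidates with final scores, best first.
#' @export
halving_search <- function(X, y, sampler, model = "rf", n_candidates = 9L,
                           factor = 3L, min_resource = 64L, cv_folds = 5L,
                           seed = 1L) {
  cand <- lapply(seq_len(n_candidates), sampler)
  scores <- rep(NA_real_, n_candidates)
  alive <- seq_len(n_candidates)
  resource <- min_resource
  rung <- 0L
  while (length(alive) > 1L) {
    n_use <- min(resource, length(y))
    idx <- with_seed(derive_seed(seed, rung, 61L), sample(length(y), n_use))
    folds <- rep_len(seq_len(cv_folds), n_use)
    for (ci in alive) {
      spec <- classifier_spec(model, cand[[ci]])
      f1s <- vapply(seq_len(cv_folds), function(k) {
        tr <- idx[folds != k]; te <- idx[folds == k]
        if (length(unique(y[tr])) < 2) return(NA_real_)
        fit <- with_seed(derive_seed(seed, rung, ci, k),
                         spec$fit(X[tr, , drop = FALSE], y[tr],
                                  derive_seed(seed, rung, ci, k)))
        P <- spec$predict_proba(fit, X[te, , drop = FALSE])
        pred <- colnames(P)[max.col(P, ties.method = "first")]
        f1_weighted(as.character(y[te]), pred)
      }, numeric(1))
      scores[ci] <- mean(f1s, na.rm = TRUE)
    }
    keep <- max(1L, floor(length(alive) / factor))
    alive <- alive[order(scores[alive], decreasing = TRUE)][seq_len(keep)]
    resource <- resource * factor
    rung <- rung + 1L
    if (n_use == length(y)) break
  }
  ord <- order(scores, decreasing = TRUE)
  tibble::tibble(candidate = ord, score = scores[ord],
                 params = cand[ord], selected = ord == ord[1])
}

# ---- image path ----------------------------------------------------------

#' Prepare a mask-centred normalized crop for image classifiers
#'
#' Crops a `crop_px` square centred on the mask centroid (padding with the
#' background median where the crop exceeds the frame), downsamples to
#' `out_px`, scales intensities to \[0, 1\], then standardizes the organoid
#' pixels only — background pixels are left untouched by the
#' normalization. Augmentation, when given, runs before normalization.
#'
#' @param image Grayscale matrix on 0..255.
#' @param mask Binary mask, same shape.
#' @param crop_px Crop side (default 360).
#' @param out_px Output side (default 224).
#' @param augment Optional function `(image, mask) -> list(image, mask)`.
#' @return List `image`, `mask`, both `out_px` square.
#' @export
prepare_cnn_input <- function(image, mask, crop_px = 360L, out_px = 224L,
                              augment = NULL) {
  stopifnot(all(dim(image) == dim(mask)), sum(mask) > 0)
  idx <- which(mask > 0, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  bgval <- stats::median(image[mask == 0])
  half <- crop_px %/% 2L
  r0 <- ctr[1] - half; c0 <- ctr[2] - half
  rr <- r0:(r0 + crop_px - 1L); cc <- c0:(c0 + crop_px - 1L)
  crop <- matrix(bgval, crop_px, crop_px)
  mcrop <- matrix(0, crop_px, crop_px)
  rok <- rr >= 1 & rr <= nrow(image); cok <- cc >= 1 & cc <= ncol(image)
  crop[rok, cok] <- image[rr[rok], cc[cok]]
  mcrop[rok, cok] <- mask[rr[rok], cc[cok]]
  if (!is.null(augment)) {
    a <- augment(crop, mcrop)
    crop <- a$image; mcrop <- a$mask
  }
  img <- resize_image(crop, out_px, out_px, method = "area") / 255
  msk <- (resize_image(mcrop, out_px, out_px, method = "area") > 0.5) * 1
  inm <- img[msk > 0]
  if (length(inm) > 1 && stats::sd(inm) > 0)
    img[msk > 0] <- (inm - mean(inm)) / stats::sd(inm)
  list(image = img, mask = msk)
}

#' Seeded augmentation hook for image training
#'
#' Random 90-degree rotation, flips, intensity jitter and a small random
#' rescale, applied jointly to image and mask.
#' @param seed Integer seed; each call advances its own stream.
#' @return Function usable as `augment` in [prepare_cnn_input()].
#' @export
make_augmenter <- function(seed = 1L) {
  counter <- 0L
  function(image, mask) {
    counter <<- counter + 1L
    with_seed(derive_seed(seed, counter, 67L), {
      k <- sample(0:3, 1)
      rot <- function(m, k) { for (i in seq_len(k)) m <- t(m[nrow(m):1, ]); m }
      image <- rot(image, k); mask <- rot(mask, k)
      if (stats::runif(1) < 0.5) { image <- image[nrow(image):1, ]
                                   mask <- mask[nrow(mask):1, ] }
      gain <- stats::runif(1, 0.9, 1.1); bias <- stats::runif(1, -8, 8)
      image <- pmin(pmax(image * gain + bias, 0), 255)
      list(image = image, mask = mask)
    })
  }
}

# fixed seeded random-filter convolution bank (the "few convolution blocks")
make_conv_bank <- function(seed = 7L, n_filters = 8L) {
  with_seed(derive_seed(seed, 71L), {
    list(f1 = lapply(seq_len(n_filters),
                     function(i) matrix(stats::rnorm(9, 0, 1 / 3), 3, 3)),
         f2 = lapply(seq_len(n_filters),
                     function(i) matrix(stats::rnorm(9, 0, 1 / 3), 3, 3)))
  })
}

conv3 <- function(img, k) {
  p <- mirror_pad(img, 1L)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (dr in -1:1) for (dc in -1:1)
    out <- out + k[dr + 2, dc + 2] * p[(2 + dr):(n + 1 + dr),
                                       (2 + dc):(m + 1 + dc)]
  out
}

pool2 <- function(img) {
  n <- 2L * (nrow(img) %/% 2L); m <- 2L * (ncol(img) %/% 2L)
  resize_image(img[1:n, 1:m, drop = FALSE], n %/% 2L, m %/% 2L, "area")
}

conv_features <- function(img, bank) {
  feats <- numeric(0)
  for (i in seq_along(bank$f1)) {
    a <- pmax(conv3(img, bank$f1[[i]]), 0)
    a <- pool2(a)
    b <- pmax(conv3(a, bank$f2[[i]]), 0)
    b <- pool2(b)
    n2 <- nrow(b) %/% 2L; m2 <- ncol(b) %/% 2L
    quads <- c(mean(b[1:n2, 1:m2]), mean(b[1:n2, (m2 + 1):ncol(b)]),
               mean(b[(n2 + 1):nrow(b), 1:m2]),
               mean(b[(n2 + 1):nrow(b), (m2 + 1):ncol(b)]))
    feats <- c(feats, mean(b), stats::sd(b), max(b), quads)
  }
  feats
}

softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Train the small image classifier on one fold
#'
#' Desk-scale stand-in for the GPU-trained networks behind the same
#' contract: a fixed seeded bank of random 3x3 convolution filters (two
#' blocks with ReLU and mean pooling) feeds pooled activation statistics
#' into a trainable multinomial-logistic head. The head is trained by
#' mini-batch gradient descent with class weights `n / (K * n_c)`,
#' gradient-norm clipping at 1.0, learning rate halved when the validation
#' loss plateaus (patience 7), and the best state kept by validation loss.
#' A baseline twin is obtained with `shuffle_labels = TRUE`.
#'
#' @param crops Tibble with `experiment_id`, `well_id`, `loop` and a list
#'   column `input` of [prepare_cnn_input()] outputs.
#' @param labels Per-organoid label tibble.
#' @param split One fold of a split plan.
#' @param epochs Training epochs (default 40).
#' @param lr Initial learning rate.
#' @param batch_size Mini-batch size.
#' @param shuffle_labels Baseline twin switch.
#' @param seed Integer seed.
#' @return A `prediction_run` whose `logits` field carries per-row logits
#'   for temperature calibration.
#' @export
train_image_classifier <- function(crops, labels, split, epochs = 40L,
                                   lr = 0.1, batch_size = 32L,
                                   shuffle_labels = FALSE, seed = 1L) {
  bank <- make_conv_bank(seed)
  d <- join_labels(crops, labels)
  d <- dplyr::inner_join(d,
    split[, c("experiment_id", "well_id", "partition")],
    by = c("experiment_id", "well_id"))
  X <- t(vapply(d$input, function(inp) conv_features(inp$image, bank),
                numeric(7L * length(bank$f1))))
  X <- cbind(1, scale(X))
  X[is.na(X)] <- 0
  y <- as.character(d$.label)
  if (shuffle_labels) {
    org <- dplyr::distinct(d[d$partition != "test", ],
                           .data$experiment_id, .data$well_id, .data$.label)
    org$.shuffled <- with_seed(derive_seed(seed, 73L), sample(org$.label))
    m <- match(paste(d$experiment_id, d$well_id),
               paste(org$experiment_id, org$well_id))
    y[!is.na(m)] <- as.character(org$.shuffled[m[!is.na(m)]])
  }
  cls <- sort(unique(y[d$partition == "train"]))
  if (length(cls) < 2) stop("training fold lacks a class")
  K <- length(cls)
  yi <- match(y, cls)
  tr <- which(d$partition == "train" & !is.na(yi))
  va <- which(d$partition == "validation" & !is.na(yi))
  n_c <- tabulate(yi[tr], K)
  cw <- length(tr) / (K * pmax(n_c, 1))      # class weights n/(K*n_c)
  W <- matrix(0, K, ncol(X))
  best <- list(loss = Inf, W = W)
  wait <- 0L
  nll <- function(W, rows) {
    P <- softmax(X[rows, , drop = FALSE] %*% t(W))
    -mean(cw[yi[rows]] * log(pmax(P[cbind(seq_along(rows), yi[rows])], 1e-12)))
  }
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep, 79L), sample(tr))
    for (s in seq(1, length(ord), by = batch_size)) {
      rows <- ord[s:min(s + batch_size - 1L, length(ord))]
      Xb <- X[rows, , drop = FALSE]
      P <- softmax(Xb %*% t(W))
      Yb <- matrix(0, length(rows), K)
      Yb[cbind(seq_along(rows), yi[rows])] <- 1
      G <- t((P - Yb) * cw[yi[rows]]) %*% Xb / length(rows)
      gn <- sqrt(sum(G^2))
      if (gn > 1) G <- G / gn               # gradient-norm clipping at 1.0
      W <- W - lr * G
    }
    vloss <- if (length(va)) nll(W, va) else nll(W, tr)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, W = W); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= 7L) { lr <- lr / 2; wait <- 0L }  # halve on plateau
    }
  }
  W <- best$W
  L <- X %*% t(W)
  colnames(L) <- cls
  P <- softmax(L)
  pred <- cls[max.col(P, ties.method = "first")]
  preds <- dplyr::bind_cols(
    d[, c("experiment_id", "well_id", "loop", "partition")],
    tibble::tibble(truth = as.character(d$.label), pred = pred),
    tibble::as_tibble(P, .name_repair = ~ paste0("p_", cls)))
  val <- preds[preds$partition == "validation", ]
  structure(list(predictions = preds, classes = cls,
                 best_val_f1 = if (nrow(val))
                   f1_weighted(val$truth, val$pred) else NA_real_,
                 model = "tiny_convnet", fold_id = split$fold_id[1],
                 test_experiment = split$test_experiment[1],
                 shuffled = shuffle_labels, logits = L, weights = W),
            class = "prediction_run")
}

# ---- calibration and ensembling ------------------------------------------

#' Temperature calibration of logits
#'
#' Finds the single scalar `T > 0` minimizing the cross-entropy of
#' `softmax(logits / T)` against the validation labels; a monotone
#' transform, so predicted labels are unchanged.
#'
#' @param logits Matrix (rows = samples, cols = classes), column names are
#'   class labels.
#' @param labels True labels of the rows.
#' @return Fitted temperature (scalar).
#' @export
temperature_calibrate <- function(logits, labels) {
  stopifnot(is.matrix(logits), nrow(logits) == length(labels))
  if (max(abs(sweep(logits, 1, rowMeans(logits)))) < 1e-12)
    stop("degenerate logits: all classes equal")
  yi <- match(as.character(labels), colnames(logits))
  stopifnot(!anyNA(yi))
  nll <- function(logT) {
    P <- softmax(logits / exp(logT))
    -mean(log(pmax(P[cbind(seq_len(nrow(P)), yi)], 1e-12)))
  }
  opt <- stats::optimize(nll, interval = log(c(0.05, 50)))
  exp(opt$minimum)
}

#' Apply a temperature to a run's logits
#' @param run A `prediction_run` with logits.
#' @param temperature Scalar from [temperature_calibrate()].
#' @return The run with recalibrated probability columns (labels unchanged).
#' @export
apply_temperature <- function(run, temperature) {
  stopifnot(inherits(run, "prediction_run"), !is.null(run$logits))
  P <- softmax(run$logits / temperature)
  for (i in seq_along(run$classes))
    run$predictions[[paste0("p_", run$classes[i])]] <- P[, i]
  run$temperature <- temperature
  run
}

#' F1-weighted ensemble of prediction runs
#'
#' Averages calibrated class probabilities across runs with weights equal
#' to each run's best validation F1; the argmax of the weighted average is
#' the ensemble label.
#'
#' @param runs List of `prediction_run`s over the same evaluation rows.
#' @param weights Optional weights; default `best_val_f1` of each run.
#' @return A `prediction_run` with the ensemble predictions.
#' @export
ensemble_predict <- function(runs, weights = NULL) {
  if (length(runs) == 0) stop("empty run list")
  cls <- runs[[1]]$classes
  for (r in runs)
    if (!identical(r$classes, cls)) stop("mismatched class sets across runs")
  if (is.null(weights))
    weights <- vapply(runs, function(r) r$best_val_f1, numeric(1))
  stopifnot(all(is.finite(weights)), sum(weights) > 0)
  key_cols <- c("experiment_id", "well_id", "loop", "partition", "truth")
  base <- runs[[1]]$predictions[, key_cols]
  pcols <- paste0("p_", cls)
  P <- matrix(0, nrow(base), length(cls))
  for (i in seq_along(runs)) {
    Pi <- as.matrix(runs[[i]]$predictions[, pcols])
    stopifnot(nrow(Pi) == nrow(base))
    P <- P + weights[i] * Pi
  }
  P <- P / sum(weights)
  preds <- dplyr::bind_cols(base,
    tibble::tibble(pred = cls[max.col(P, ties.method = "first")]),
    tibble::as_tibble(P, .name_repair = ~ pcols))
  structure(list(predictions = preds, classes = cls,
                 best_val_f1 = NA_real_, model = "ensemble",
                 fold_id = runs[[1]]$fold_id,
                 test_experiment = runs[[1]]$test_experiment,
                 shuffled = FALSE, member_weights = weights),
            class = "prediction_run")
}

# ---- evaluation ----------------------------------------------------------

#' Weighted-average F1 score
#'
#' Per-class F1 averaged with class-frequency weights over the classes
#' present in the truth; a class with zero precision+recall contributes 0.
#' @param truth,pred Label vectors.
#' @return Scalar in \[0, 1\].
#' @export
f1_weighted <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  out <- 0
  for (c in unique(truth)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    out <- out + f1 * mean(truth == c)
  }
  out
}

#' Per-loop weighted F1 curve of a run
#'
#' @param run A `prediction_run`.
#' @param partition Evaluation set (default `"test"`).
#' @return Tibble of class `f1_curve`: `loop`, `n`, `f1`, plus run
#'   metadata columns.
#' @export
f1_over_time <- function(run, partition = "test") {
  p <- run$predictions[run$predictions$partition == partition, ]
  if (nrow(p) == 0) stop("no predictions in partition ", partition)
  out <- dplyr::group_by(p, .data$loop) |>
    dplyr::summarise(n = dplyr::n(),
                     f1 = f1_weighted(.data$truth, .data$pred),
                     .groups = "drop")
  out$model <- run$model
  out$fold_id <- run$fold_id
  out$test_experiment <- run$test_experiment
  out$partition <- partition
  class(out) <- c("f1_curve", class(out))
  out
}

#' Weighted F1 stratified by bin-centre distance
#'
#' For size-class tasks: bins evaluation samples by their normalized
#' distance to the centre of the assigned size bin and reports weighted F1
#' per stratum (empty strata are omitted).
#'
#' @param run A `prediction_run`.
#' @param distances Tibble `experiment_id`, `well_id`, `distance`.
#' @param breaks Stratum boundaries on \[0, 1\].
#' @param partition Evaluation set.
#' @return Tibble `stratum`, `lo`, `hi`, `n`, `f1`.
#' @export
f1_by_bin_distance <- function(run, distances,
                               breaks = seq(0, 1, by = 0.2),
                               partition = "test") {
  p <- run$predictions[run$predictions$partition == partition, ]
  p <- dplyr::inner_join(p, distances, by = c("experiment_id", "well_id"))
  p$stratum <- cut(p$distance, breaks, include.lowest = TRUE)
  dplyr::group_by(p, .data$stratum) |>
    dplyr::summarise(lo = breaks[as.integer(.data$stratum[1])],
                     hi = breaks[as.integer(.data$stratum[1]) + 1L],
                     n = dplyr::n(),
                     f1 = f1_weighted(.data$truth, .data$pred),
                     .groups = "drop")
}

#' Time-normalized trapezoidal AUC of an F1 curve
#'
#' Trapezoidal integral of F1 over the available time points divided by the
#' time span — the mean F1 across the window; equals `c` for a constant
#' curve at `c` on any grid.
#' @param loop Time points (need not be contiguous).
#' @param f1 F1 values.
#' @return Scalar.
#' @export
f1_curve_auc <- function(loop, f1) {
  o <- order(loop)
  loop <- loop[o]; f1 <- f1[o]
  if (length(loop) == 1) return(f1)
  span <- loop[length(loop)] - loop[1]
  sum(diff(loop) * (utils::head(f1, -1) + utils::tail(f1, -1)) / 2) / span
}

#' Paired Wilcoxon signed-rank test with Pratt zero handling
#'
#' Zero differences are kept in the ranking of absolute differences and
#' excluded from the test statistic (Pratt's method); the p-value uses the
#' normal approximation with tie, zero and continuity corrections. All
#' differences zero gives p = 1.
#' @param x,y Paired numeric vectors.
#' @return List `statistic` (sum of positive-difference ranks), `p_value`.
#' @export
wilcoxon_signed_rank_pratt <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  n0 <- sum(d == 0)
  if (n0 == n) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[d != 0])
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(statistic = W, p_value = 1))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  list(statistic = W, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare classifiers by per-experiment F1-curve AUC
#'
#' Summarizes each method's F1 curves as one time-normalized AUC per
#' experiment, then tests every method pair with the paired Wilcoxon
#' signed-rank test (Pratt zeros) across experiments, adjusting p-values
#' with Holm–Bonferroni. Experiments missing from either method of a pair
#' are dropped with a warning.
#'
#' @param curves Tibble `method`, `test_experiment`, `loop`, `f1` (bind
#'   [f1_over_time()] outputs with a `method` column).
#' @return Tibble of class `classifier_comparison`: `method_a`, `method_b`,
#'   `n_pairs`, `statistic`, `p_value`, `p_adj`, plus attribute `auc`
#'   (per-experiment AUC table).
#' @export
compare_classifiers <- function(curves) {
  stopifnot(all(c("method", "test_experiment", "loop", "f1") %in%
                names(curves)))
  auc <- dplyr::group_by(curves, .data$method, .data$test_experiment) |>
    dplyr::summarise(auc = f1_curve_auc(.data$loop, .data$f1),
                     .groups = "drop")
  methods <- sort(unique(auc$method))
  if (length(methods) < 2) stop("need >= 2 methods")
  pairs <- utils::combn(methods, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- auc[auc$method == pairs[1, i], ]
    b <- auc[auc$method == pairs[2, i], ]
    common <- intersect(a$test_experiment, b$test_experiment)
    if (length(common) < max(nrow(a), nrow(b)))
      warning("dropping unpaired experiments for ",
              pairs[1, i], " vs ", pairs[2, i])
    av <- a$auc[match(common, a$test_experiment)]
    bv <- b$auc[match(common, b$test_experiment)]
    t <- wilcoxon_signed_rank_pratt(av, bv)
    tibble::tibble(method_a = pairs[1, i], method_b = pairs[2, i],
                   n_pairs = length(common), statistic = t$statistic,
                   p_value = t$p_value)
  })
  rows$p_adj <- stats::p.adjust(rows$p_value, method = "holm")
  attr(rows, "auc") <- auc
  class(rows) <- c("classifier_comparison", class(rows))
  rows
}

#' Morphology-cluster targets from final-loop features
#'
#' Z-scales the final-loop morphometrics, projects onto 15 principal
#' components and k-means-clusters (k = 4, seeded, fixed restarts); the
#' cluster labels serve as a four-class prediction target.
#'
#' @param final_features Final-loop morphometrics tibble.
#' @param n_pcs Principal components (default 15).
#' @param k Clusters (default 4).
#' @param nstart k-means restarts (default 10).
#' @param seed Integer seed.
#' @return Tibble `experiment_id`, `well_id`, `morphology_cluster` (0..k-1).
#' @export
morphology_cluster_targets <- function(final_features, n_pcs = 15L, k = 4L,
                                       nstart = 10L, seed = 1L) {
  ids <- final_features[, intersect(c("experiment_id", "well_id", "loop"),
                                    names(final_features))]
  if (nrow(final_features) < k) stop("need at least k organoids")
  space <- suppressWarnings(fit_pc_space(final_features, n_pcs))
  P <- pc_matrix(project_pc_space(space, final_features))
  km <- with_seed(derive_seed(seed, 83L),
                  stats::kmeans(P, centers = k, nstart = nstart,
                                iter.max = 50))
  out <- ids
  out$morphology_cluster <- km$cluster - 1L
  attr(out, "kmeans") <- km
  out
}
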