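# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit pixel/pair loops, direct formulas) so they
# cannot share code paths with the implementations they check.

disc_mask <- function(n, r, ctr = c(n / 2 + 0.5, n / 2 + 0.5)) {
  X <- matrix(seq_len(n), n, n) - ctr[1]
  Y <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr[2]
  (sqrt(X^2 + Y^2) <= r) * 1
}

ellipse_mask <- function(n, a, b, ctr = c(n / 2 + 0.5, n / 2 + 0.5)) {
  X <- matrix(seq_len(n), n, n) - ctr[1]
  Y <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr[2]
  ((X / a)^2 + (Y / b)^2 <= 1) * 1
}

tiny_dataset <- function(seed = 42, wells = 4L, loops = 6L, frame_px = 96L,
                         um_per_px = 5, n_experiments = 1L,
                         signal_strength = 6, exclusion_prob = 0,
                         rpe_visible = loops - 1L, lens_visible = loops - 2L) {
  cfg <- acquisition_config(
    n_experiments = n_experiments, wells_per_plate = wells,
    duration_h = loops / 2, interval_min = 30, frame_px = frame_px,
    um_per_px = um_per_px, seed = seed)
  simulate_experiment(cfg, fate_spec(
    rpe_visible_loop = rpe_visible, lens_visible_loop = lens_visible,
    signal_strength = signal_strength, exclusion_prob = exclusion_prob))
}

# ---- oracles --------------------------------------------------------------

brute_sauvola <- function(image, radius = 15L, k = 0.5, r = 128) {
  n <- nrow(image); m <- ncol(image)
  mirror_idx <- function(i, len) {
    # reflect without repeating the edge pixel (matches mirror padding)
    while (i < 1 || i > len) {
      if (i < 1) i <- 2 - i
      if (i > len) i <- 2 * len - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- numeric((2 * radius + 1)^2)
    t <- 0L
    for (di in -radius:radius) for (dj in -radius:radius) {
      t <- t + 1L
      vals[t] <- image[mirror_idx(i + di, n), mirror_idx(j + dj, m)]
    }
    mu <- mean(vals)
    sd <- sqrt(mean((vals - mu)^2))
    thr <- mu * (1 + k * (sd / r - 1))
    out[i, j] <- as.numeric(image[i, j] > thr)
  }
  out
}

brute_custom_intensity <- function(image, mask) {
  px <- which(mask > 0)
  I <- image[px]
  # 4-neighbour Laplacian with mirror padding, explicit loops
  n <- nrow(image); m <- ncol(image)
  refl <- function(i, len) if (i < 1) 2 - i else if (i > len) 2 * len - i else i
  lap <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    lap[i, j] <- image[refl(i - 1, n), j] + image[refl(i + 1, n), j] +
      image[i, refl(j - 1, m)] + image[i, refl(j + 1, m)] - 4 * image[i, j]
  }
  lv <- lap[px]
  blur <- if (length(lv) > 1) sum((lv - mean(lv))^2) / (length(lv) - 1) else 0
  mu <- mean(I)
  m2 <- mean((I - mu)^2)
  list(
    blur = blur,
    roi_contrast = max(I) - min(I),
    image_contrast = max(image) - min(image),
    median_intensity = stats::median(I),
    modal_value = {
      u <- sort(unique(round(I)))
      cnt <- vapply(u, function(x) sum(round(I) == x), numeric(1))
      u[which.max(cnt)]
    },
    integrated_density = mu * length(I),
    raw_integrated_density = sum(I),
    skewness = if (m2 > 0) mean((I - mu)^3) / m2^(3 / 2) else 0,
    kurtosis = if (m2 > 0) mean((I - mu)^4) / m2^2 - 3 else 0
  )
}

brute_mean_pairwise <- function(M) {
  n <- nrow(M)
  tot <- 0
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sqrt(sum((M[i, ] - M[j, ])^2))
    cnt <- cnt + 1
  }
  tot / cnt
}

brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

brute_com <- function(map, mask, q = 0.10) {
  px <- which(mask > 0)
  m <- max(1L, floor(q * length(px)))
  o <- order(-map[px], px)
  sel <- px[o[seq_len(m)]]
  v <- pmax(map[sel], 0)
  if (sum(v) <= 0) v <- rep(1, length(sel))
  p <- v / sum(v)
  rr <- (sel - 1) %% nrow(map) + 1
  cc <- (sel - 1) %/% nrow(map) + 1
  c(sum(p * rr), sum(p * cc))
}

brute_entropy <- function(map, mask, q = 0.10) {
  px <- which(mask > 0)
  m <- max(1L, floor(q * length(px)))
  o <- order(-map[px], px)
  v <- map[px][o[seq_len(m)]]
  p <- v / sum(v)
  -sum(p * log(p))
}

brute_dice <- function(a_idx, b_idx) {
  2 * length(intersect(a_idx, b_idx)) / (length(a_idx) + length(b_idx))
}

brute_weighted_f1 <- function(truth, pred) {
  classes <- unique(truth)
  total <- 0
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + f1 * sum(truth == cl) / length(truth)
  }
  total
}

brute_yen <- function(v) {
  # direct maximization of Yen's criterion over thresholds, explicit sums
  v <- pmin(pmax(round(v), 0), 255)
  p <- vapply(0:255, function(g) mean(v == g), numeric(1))
  best <- -Inf; best_t <- 0
  for (t in 0:254) {
    P1 <- sum(p[1:(t + 1)])
    P1sq <- sum(p[1:(t + 1)]^2)
    P2sq <- sum(p[(t + 2):256]^2)
    crit <- log(max(P1 * (1 - P1), 1e-30)^2 /
                max(P1sq * P2sq, 1e-30))
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
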