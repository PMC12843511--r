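# Consensus metrics over attribution (saliency) maps: in-mask z-scoring,
# pairwise method Dice at top-fraction thresholds, cross-model rank
# correlation, top-q entropy, centre-of-mass drift, and superpixel region
# votes. Attribution algorithms themselves are inputs; a seeded synthetic
# generator provides method/model map families with controllable agreement.

#' Z-score a saliency map inside the organoid mask
#'
#' In-mask pixels are standardized to mean 0, sd 1; out-of-mask pixels are
#' set to `NA` and excluded from every downstream metric.
#' @param map Real-valued matrix.
#' @param mask Binary matrix, same shape, at least 2 in-mask pixels.
#' @return Standardized matrix with `NA` outside the mask.
#' @export
zscore_within_mask <- function(map, mask) {
  stopifnot(all(dim(map) == dim(mask)))
  v <- map[mask > 0]
  if (length(v) < 2) stop("mask too small to standardize")
  s <- stats::sd(v)
  if (s == 0) stop("constant in-mask map")
  out <- matrix(NA_real_, nrow(map), ncol(map))
  out[mask > 0] <- (v - mean(v)) / s
  out
}

# indices (into the mask) of the top-fraction in-mask pixels, ties broken
# by pixel index for determinism
top_fraction_idx <- function(map, mask, frac) {
  px <- which(mask > 0)
  m <- max(1L, floor(frac * length(px)))
  v <- map[px]
  o <- order(-v, px)
  px[o[seq_len(m)]]
}

#' Pairwise Dice agreement of attribution methods
#'
#' For one model and frame: binarizes each method's map to its top 1%, 5%
#' and 10% in-mask pixels and reports, per method pair, the Dice
#' coefficient averaged over the three thresholds.
#'
#' @param maps Named list of real-valued matrices (one per method).
#' @param mask Shared binary organoid mask.
#' @param top_fracs Fractions (default `c(0.01, 0.05, 0.10)`).
#' @return Tibble `method_a`, `method_b`, `dice`.
#' @export
pairwise_method_dice <- function(maps, mask,
                                 top_fracs = c(0.01, 0.05, 0.10)) {
  stopifnot(length(maps) >= 2, !is.null(names(maps)))
  sets <- lapply(top_fracs, function(f)
    lapply(maps, top_fraction_idx, mask = mask, frac = f))
  nm <- names(maps)
  pairs <- utils::combn(nm, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dice <- vapply(sets, function(s) {
      2 * length(intersect(s[[a]], s[[b]])) /
        (length(s[[a]]) + length(s[[b]]))
    }, numeric(1))
    tibble::tibble(method_a = a, method_b = b, dice = mean(dice))
  })
}

#' Cross-model rank correlation of one attribution method
#'
#' Converts the in-mask absolute saliencies of each model to average ranks
#' and correlates ranks between model pairs (Spearman's rho).
#' @param maps Named list of matrices (one per model), shared mask.
#' @param mask Binary mask with >= 3 in-mask pixels.
#' @return Tibble `model_a`, `model_b`, `rho`.
#' @export
cross_model_rank_correlation <- function(maps, mask) {
  px <- which(mask > 0)
  if (length(px) < 3) stop("need >= 3 in-mask pixels")
  stopifnot(length(maps) >= 2, !is.null(names(maps)))
  R <- vapply(maps, function(m) rank(abs(m[px])), numeric(length(px)))
  pairs <- utils::combn(names(maps), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    tibble::tibble(model_a = pairs[1, i], model_b = pairs[2, i],
                   rho = stats::cor(R[, pairs[1, i]], R[, pairs[2, i]]))
  })
}

#' Shannon entropy of the top-q saliency probability map
#'
#' Selects the top-q in-mask pixels, normalizes their saliency to a
#' probability vector and returns its Shannon entropy in nats (lower =
#' more focused). Nonpositive total mass in the top set falls back to the
#' uniform distribution with a warning.
#' @param map Real-valued matrix.
#' @param mask Binary mask with >= 10 in-mask pixels.
#' @param q Top fraction (default 0.10).
#' @return Entropy in `[0, log(m)]` for `m` selected pixels.
#' @export
topq_entropy <- function(map, mask, q = 0.10) {
  stopifnot(sum(mask > 0) >= 10)
  px <- top_fraction_idx(map, mask, q)
  v <- map[px]
  if (any(v <= 0) || sum(v) <= 0) {
    if (sum(pmax(v, 0)) <= 0) {
      warning("nonpositive saliency mass in top set; uniform fallback")
      return(log(length(v)))
    }
    v <- pmax(v, 0)
  }
  p <- v / sum(v)
  p <- p[p > 0]
  -sum(p * log(p))
}

# centre of mass (row, col) of the top-q probability map
topq_center_of_mass <- function(map, mask, q = 0.10) {
  px <- top_fraction_idx(map, mask, q)
  v <- pmax(map[px], 0)
  if (sum(v) <= 0) v <- rep(1, length(px))
  p <- v / sum(v)
  rr <- (px - 1) %% nrow(map) + 1
  cc <- (px - 1) %/% nrow(map) + 1
  c(sum(p * rr), sum(p * cc))
}

#' Centre-of-mass drift of saliency over time
#'
#' Computes the centre of mass of the top-q probability map at each loop
#' and the Euclidean displacement between consecutive loops (in map
#' pixels); a step across a missing loop is skipped.
#'
#' @param maps List of matrices ordered by loop.
#' @param masks List of binary masks (recycled if length 1).
#' @param loops Integer loop indices (default `seq_along(maps)`).
#' @param q Top fraction (default 0.10).
#' @return Tibble `loop_from`, `loop_to`, `drift`.
#' @export
center_of_mass_drift <- function(maps, masks, loops = seq_along(maps),
                                 q = 0.10) {
  stopifnot(length(maps) >= 2, length(loops) == length(maps))
  if (length(masks) == 1) masks <- rep(masks, length(maps))
  com <- t(mapply(topq_center_of_mass, maps, masks,
                  MoreArgs = list(q = q)))
  keep <- which(diff(loops) == 1L)
  tibble::tibble(loop_from = loops[keep], loop_to = loops[keep + 1L],
                 drift = sqrt(rowSums((com[keep + 1L, , drop = FALSE] -
                                       com[keep, , drop = FALSE])^2)))
}

#' SLIC-style superpixels within a mask
#'
#' Localized k-means over in-mask pixels in (row, col, intensity) space.
#' Centres start on a regular grid inside the mask; the distance is
#' `sqrt(d_int^2 + (d_xy / S)^2 * m^2)` with `S` the grid spacing and `m`
#' the compactness, iterated a fixed number of times. Regions are clipped
#' to the mask; connectivity is not enforced.
#'
#' @param image Intensity matrix (scaled to \[0, 1\] internally).
#' @param mask Binary mask.
#' @param n_segments Target segment count (default 50).
#' @param compactness Spatial weight (default 0.1).
#' @param iterations Lloyd iterations (default 10).
#' @return Integer matrix of region labels (0 outside the mask).
#' @export
slic_superpixels <- function(image, mask, n_segments = 50L,
                             compactness = 0.1, iterations = 10L) {
  px <- which(mask > 0)
  stopifnot(length(px) >= n_segments)
  rr <- (px - 1) %% nrow(mask) + 1
  cc <- (px - 1) %/% nrow(mask) + 1
  v <- image[px]
  rngv <- range(v)
  v <- if (diff(rngv) > 0) (v - rngv[1]) / diff(rngv) else v * 0
  S <- sqrt(length(px) / n_segments)
  # grid-seeded centres inside the mask
  gr <- seq(min(rr) + S / 2, max(rr), by = S)
  gc <- seq(min(cc) + S / 2, max(cc), by = S)
  cand <- expand.grid(r = gr, c = gc)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    d2 <- (rr - cand$r[i])^2 + (cc - cand$c[i])^2
    min(d2) <= 2 * S^2
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) > n_segments)
    cand <- cand[round(seq(1, nrow(cand), length.out = n_segments)), ]
  ctr <- cbind(cand$r, cand$c,
               vapply(seq_len(nrow(cand)), function(i) {
                 v[which.min((rr - cand$r[i])^2 + (cc - cand$c[i])^2)]
               }, numeric(1)))
  m2 <- compactness^2
  lab <- integer(length(px))
  for (it in seq_len(iterations)) {
    D <- vapply(seq_len(nrow(ctr)), function(k) {
      (v - ctr[k, 3])^2 + ((rr - ctr[k, 1])^2 + (cc - ctr[k, 2])^2) / S^2 * m2
    }, numeric(length(px)))
    lab <- max.col(-D, ties.method = "first")
    for (k in seq_len(nrow(ctr))) {
      sel <- lab == k
      if (any(sel))
        ctr[k, ] <- c(mean(rr[sel]), mean(cc[sel]), mean(v[sel]))
    }
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[px] <- match(lab, sort(unique(lab)))
  out
}

#' Superpixel region votes across attribution methods
#'
#' Scores each superpixel region by its mean saliency per method; a region
#' receives that method's vote when its score lies in the top 10% of the
#' frame's region scores (at least one region always votes). Reports the
#' fraction of regions voted for by at least 2, 3 and 4 methods.
#'
#' @param maps Named list of (z-scored) saliency matrices per method.
#' @param segments Integer label matrix from [slic_superpixels()].
#' @param q Top fraction of region scores (default 0.10).
#' @return List: `votes` tibble (`region`, one logical column per method)
#'   and `agreement` tibble (`min_methods` in 2..4, `fraction`).
#' @export
superpixel_votes <- function(maps, segments, q = 0.10) {
  regions <- sort(unique(segments[segments > 0]))
  stopifnot(length(regions) >= 1, length(maps) >= 2)
  votes <- tibble::tibble(region = regions)
  for (nm in names(maps)) {
    sc <- vapply(regions, function(rg)
      mean(maps[[nm]][segments == rg], na.rm = TRUE), numeric(1))
    m <- max(1L, floor(q * length(regions)))
    top <- order(-sc, regions)[seq_len(m)]
    votes[[nm]] <- seq_along(regions) %in% top
  }
  nv <- rowSums(as.matrix(votes[, names(maps)]))
  agreement <- tibble::tibble(
    min_methods = 2:4,
    fraction = vapply(2:4, function(k) mean(nv >= k), numeric(1)))
  list(votes = votes, agreement = agreement)
}

#' Synthetic saliency-map store
#'
#' Generates a seeded family of attribution maps for crossed models,
#' methods and loops over one organoid mask: each map is a smooth random
#' field plus Gaussian hotspots. `shared_frac` controls how many hotspots
#' all methods share (1 = identical hotspot sets, 0 = independent), and
#' `model_coupling` how strongly models agree for a given method; the
#' baseline condition scrambles the hotspots.
#'
#' @param mask Binary organoid mask.
#' @param models,methods Character vectors of ids.
#' @param loops Integer loops to generate.
#' @param shared_frac Fraction of hotspots shared across methods.
#' @param model_coupling Weight of the method-common field across models.
#' @param n_hotspots Hotspots per map (default 3).
#' @param seed Integer seed.
#' @return Tibble `model`, `method`, `loop`, `condition`, list-columns
#'   `map` and `mask`.
#' @export
simulate_saliency_maps <- function(mask, models = c("netA", "netB"),
                                   methods = c("GC", "IG", "OCC"),
                                   loops = 1:3, shared_frac = 0.5,
                                   model_coupling = 0.8, n_hotspots = 3L,
                                   seed = 1L) {
  px <- which(mask > 0)
  rr <- (px - 1) %% nrow(mask) + 1
  cc <- (px - 1) %/% nrow(mask) + 1
  hotspot_field <- function(centers, width) {
    f <- numeric(length(px))
    for (i in seq_len(nrow(centers)))
      f <- f + exp(-((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2) /
                     (2 * width^2))
    f
  }
  width <- sqrt(length(px)) / 8
  rows <- list(); k <- 0L
  for (li in seq_along(loops)) {
    shared_ctr <- with_seed(derive_seed(seed, li, 89L), {
      s <- sample(length(px), n_hotspots)
      cbind(rr[s], cc[s])
    })
    for (mo in seq_along(models)) for (me in seq_along(methods)) {
      own_ctr <- with_seed(derive_seed(seed, li, mo, me, 97L), {
        s <- sample(length(px), n_hotspots)
        cbind(rr[s], cc[s])
      })
      n_sh <- round(shared_frac * n_hotspots)
      ctr <- rbind(shared_ctr[seq_len(n_sh), , drop = FALSE],
                   own_ctr[seq_len(n_hotspots - n_sh), , drop = FALSE])
      base_field <- hotspot_field(ctr, width)
      own_field <- hotspot_field(own_ctr, width)
      fld <- model_coupling * base_field + (1 - model_coupling) * own_field
      noise <- with_seed(derive_seed(seed, li, mo, me, 101L),
                         stats::rnorm(length(px), 0, 0.1))
      for (cond in c("trained", "baseline")) {
        val <- if (cond == "trained") fld + noise
          else with_seed(derive_seed(seed, li, mo, me, 103L),
                         sample(fld) + stats::rnorm(length(px), 0, 0.1))
        m <- matrix(NA_real_, nrow(mask), ncol(mask))
        m[px] <- val
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          model = models[mo], method = methods[me], loop = loops[li],
          condition = cond, map = list(m), mask = list(mask))
      }
    }
  }
  dplyr::bind_rows(rows)
}
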