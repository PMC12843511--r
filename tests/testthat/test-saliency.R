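test_that("in-mask z-scoring standardizes and is affine invariant", {
  set.seed(1)
  mask <- disc_mask(40, 14)
  map <- matrix(rnorm(1600), 40, 40)
  z <- zscore_within_mask(map, mask)
  expect_lt(abs(mean(z[mask > 0])), 1e-12)
  expect_lt(abs(sd(z[mask > 0]) - 1), 1e-12)
  expect_true(all(is.na(z[mask == 0])))
  z2 <- zscore_within_mask(3 * map + 17, mask)
  expect_equal(z, z2, tolerance = 1e-12)
  one <- matrix(0, 40, 40); one[5, 5] <- 1
  expect_error(zscore_within_mask(map, one), "small")
  expect_error(zscore_within_mask(matrix(2, 40, 40), mask), "constant")
})

test_that("pairwise method Dice has its limits and the random baseline", {
  mask <- disc_mask(40, 15)
  set.seed(2)
  m1 <- matrix(rnorm(1600), 40, 40)
  same <- pairwise_method_dice(list(a = m1, b = m1), mask)
  expect_equal(same$dice, 1)

  # disjoint top sets: strictly increasing vs decreasing in-mask values
  px <- which(mask > 0)
  up <- matrix(0, 40, 40); up[px] <- seq_along(px)
  down <- matrix(0, 40, 40); down[px] <- rev(seq_along(px))
  expect_equal(pairwise_method_dice(list(a = up, b = down), mask)$dice, 0)

  # two independent uniform maps at top 10%: expected Dice ~ 0.10
  set.seed(3)
  d <- replicate(500, {
    a <- matrix(0, 40, 40); a[px] <- runif(length(px))
    b <- matrix(0, 40, 40); b[px] <- runif(length(px))
    pairwise_method_dice(list(a = a, b = b), mask,
                         top_fracs = 0.10)$dice
  })
  expect_lt(abs(mean(d) - 0.10), 0.01)

  # symmetry in the two arguments
  set.seed(4)
  m2 <- matrix(rnorm(1600), 40, 40)
  ab <- pairwise_method_dice(list(a = m1, b = m2), mask)$dice
  ba <- pairwise_method_dice(list(a = m2, b = m1), mask)$dice
  expect_equal(ab, ba)
})

test_that("cross-model rank correlation equals Spearman on |saliency|", {
  mask <- disc_mask(24, 9)
  set.seed(5)
  m1 <- matrix(rnorm(576), 24, 24)
  mono <- sign(m1) * (abs(m1))^3             # strictly monotone in |x|
  out <- cross_model_rank_correlation(list(a = m1, b = mono), mask)
  expect_equal(out$rho, 1)

  px <- which(mask > 0)
  rev_map <- matrix(0, 24, 24)
  rev_map[px] <- max(abs(m1[px])) + 1 - abs(m1[px])  # reversed rank order
  out2 <- cross_model_rank_correlation(list(a = m1, b = rev_map), mask)
  expect_equal(out2$rho, -1)

  # oracle match on random 50-pixel fixtures with ties
  for (i in 1:5) {
    small <- disc_mask(12, 3.8)
    a <- matrix(sample(1:8, 144, replace = TRUE), 12, 12)
    b <- matrix(sample(1:8, 144, replace = TRUE), 12, 12)
    got <- cross_model_rank_correlation(list(a = a, b = b), small)$rho
    want <- brute_spearman(abs(a[small > 0]), abs(b[small > 0]))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("top-q entropy spans [0, log m] and tracks concentration", {
  mask <- disc_mask(40, 15)
  px <- which(mask > 0)
  m <- floor(0.1 * length(px))

  flat <- matrix(0, 40, 40); flat[px] <- 1 + seq_along(px) * 1e-9
  expect_equal(topq_entropy(flat, mask), log(m), tolerance = 1e-4)

  peak <- matrix(0, 40, 40); peak[px] <- 1e-9; peak[px[1]] <- 1e9
  expect_lt(topq_entropy(peak, mask), 1e-4)

  # entropy decreases monotonically as mass concentrates
  ent <- vapply(c(0.5, 1, 2, 4, 8), function(alpha) {
    g <- matrix(0, 40, 40)
    g[px] <- exp(-alpha * seq_along(px) / length(px))
    topq_entropy(g, mask)
  }, numeric(1))
  expect_true(all(diff(ent) < 0))

  neg <- matrix(0, 40, 40); neg[px] <- -abs(rnorm(length(px)))
  expect_warning(e <- topq_entropy(neg, mask), "uniform")
  expect_equal(e, log(m))

  set.seed(6)
  r <- matrix(0, 40, 40); r[px] <- runif(length(px))
  expect_equal(topq_entropy(r, mask), brute_entropy(r, mask),
               tolerance = 1e-9)
})

test_that("centre-of-mass drift has closed forms and matches the oracle", {
  mask <- matrix(1, 50, 50)
  set.seed(7)
  base <- matrix(runif(2500), 50, 50)
  static <- center_of_mass_drift(list(base, base, base), list(mask))
  expect_true(all(static$drift == 0))

  # a localized blob translated by (3, 4) px inside a fixed mask
  blob <- function(cr, cc) {
    X <- matrix(1:50, 50, 50); Y <- t(X)
    exp(-((X - cr)^2 + (Y - cc)^2) / 18)
  }
  mask_in <- matrix(0, 50, 50); mask_in[5:45, 5:45] <- 1
  dr <- center_of_mass_drift(list(blob(20, 22), blob(23, 26)), list(mask_in))
  expect_equal(dr$drift, 5, tolerance = 0.05)

  com <- orgfate:::topq_center_of_mass(base, mask_in)
  expect_equal(com, brute_com(base, mask_in), tolerance = 1e-9)

  # a missing intermediate loop is skipped
  sk <- center_of_mass_drift(list(base, base, base), list(mask),
                             loops = c(1, 2, 5))
  expect_equal(nrow(sk), 1L)
})

test_that("superpixels cover the mask and region votes aggregate methods", {
  mask <- disc_mask(64, 26)
  set.seed(8)
  img <- matrix(runif(64 * 64), 64, 64)
  seg <- slic_superpixels(img, mask, n_segments = 50)
  expect_true(all((seg > 0) == (mask > 0)))
  expect_gte(length(unique(seg[seg > 0])), 30)
  expect_lte(length(unique(seg[seg > 0])), 50)

  px <- which(mask > 0)
  m1 <- matrix(0, 64, 64); m1[px] <- runif(length(px))
  votes_same <- superpixel_votes(list(a = m1, b = m1, c = m1), seg)
  agg <- votes_same$agreement
  expect_equal(agg$fraction[agg$min_methods == 2],
               agg$fraction[agg$min_methods == 3])
  expect_gt(agg$fraction[agg$min_methods == 2], 0)

  # methods with disjoint hotspot regions share no votes: give each method
  # full-rank region scores so the top sets are determined, and elevate
  # different region blocks
  regions <- sort(unique(seg[seg > 0]))
  R <- length(regions)
  m <- max(1L, floor(0.1 * R))
  per_region <- function(vals) {
    out <- matrix(0, 64, 64)
    for (i in seq_len(R)) out[seg == regions[i]] <- vals[i]
    out
  }
  hot_a <- per_region(c(rep(100, m), seq_len(R - m)))
  hot_b <- per_region(c(seq_len(R - m), rep(100, m)))
  dv <- superpixel_votes(list(a = hot_a, b = hot_b), seg)
  expect_equal(dv$agreement$fraction[dv$agreement$min_methods == 2], 0)
})

test_that("random independent maps match a permutation-simulation oracle", {
  mask <- disc_mask(48, 20)
  set.seed(9)
  img <- matrix(runif(48 * 48), 48, 48)
  seg <- slic_superpixels(img, mask, n_segments = 40)
  regions <- sort(unique(seg[seg > 0]))
  R <- length(regions)
  m <- max(1L, floor(0.1 * R))
  px <- which(mask > 0)
  obs <- replicate(60, {
    maps <- lapply(1:3, function(i) {
      mm <- matrix(0, 48, 48); mm[px] <- runif(length(px)); mm
    })
    names(maps) <- c("a", "b", "c")
    superpixel_votes(maps, seg)$agreement$fraction[1]   # >= 2 methods
  })
  # oracle: 3 independent random m-subsets of R regions
  sim <- replicate(2000, {
    picks <- replicate(3, sample(R, m))
    mean(tabulate(unlist(picks), R) >= 2)
  })
  expect_lt(abs(mean(obs) - mean(sim)), 3 * sd(sim) / sqrt(60) + 0.02)
})

test_that("the synthetic saliency store is seeded and shapes agreement", {
  mask <- disc_mask(48, 20)
  st <- simulate_saliency_maps(mask, seed = 4)
  expect_equal(nrow(st), 2 * 3 * 3 * 2)      # models x methods x loops x cond
  st2 <- simulate_saliency_maps(mask, seed = 4)
  expect_identical(st$map, st2$map)

  # stronger hotspot sharing raises cross-method Dice
  dice_at <- function(sf) {
    s <- simulate_saliency_maps(mask, shared_frac = sf, seed = 6)
    fr <- s[s$loop == 1 & s$model == "netA" & s$condition == "trained", ]
    maps <- lapply(fr$map, zscore_within_mask, mask = mask)
    names(maps) <- fr$method
    mean(pairwise_method_dice(maps, mask)$dice)
  }
  expect_gt(dice_at(1), dice_at(0))
})
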