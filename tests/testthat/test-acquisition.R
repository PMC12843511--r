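test_that("acquisition arithmetic and metadata counts follow the design", {
  cfg <- acquisition_config(wells_per_plate = 96, duration_h = 72,
                            interval_min = 30, n_z = 5)
  expect_equal(cfg$n_loops, 144L)
  expect_equal(96 * cfg$n_loops * cfg$n_z, 69120)

  cfg2 <- acquisition_config(wells_per_plate = 2, duration_h = 1,
                             interval_min = 30)
  expect_equal(cfg2$n_loops, 2L)

  expect_error(acquisition_config(duration_h = 1, interval_min = 25),
               "integer")
  expect_error(acquisition_config(wells_per_plate = 0), "positive")

  ds <- tiny_dataset(wells = 3, loops = 4)
  fr <- dataset_frames(ds)
  expect_equal(nrow(fr), 3 * 4 * 5)
})

test_that("simulation is bit-identical under the same seed", {
  ds1 <- tiny_dataset(seed = 9, wells = 2, loops = 4)
  ds2 <- tiny_dataset(seed = 9, wells = 2, loops = 4)
  expect_identical(dataset_outcomes(ds1), dataset_outcomes(ds2))
  f1 <- render_frame(ds1, "E001", "A01", 2, 4)
  f2 <- render_frame(ds2, "E001", "A01", 2, 4)
  expect_identical(f1, f2)
  ds3 <- tiny_dataset(seed = 10, wells = 2, loops = 4)
  expect_false(identical(render_frame(ds3, "E001", "A01", 2, 4), f1))
})

test_that("middle z-slice is the sharpest and defocus grows outward", {
  ds <- tiny_dataset(wells = 1, loops = 4)
  m <- true_mask(ds, "E001", "A01", 2)
  lv <- vapply(1:5, function(z) {
    img <- render_frame(ds, "E001", "A01", 2, z)
    lp <- orgfate:::laplacian_variance(img, m)
  }, numeric(1))
  expect_equal(which.max(lv), 3L)
  expect_true(lv[3] > lv[2] && lv[3] > lv[4])
  expect_true(lv[2] > lv[1] && lv[4] > lv[5])
})

test_that("visible structures appear only after their visibility loops", {
  ds <- tiny_dataset(seed = 3, wells = 12, loops = 8,
                     rpe_visible = 7, lens_visible = 6)
  w <- ds$wells
  rpe_well <- w$well_id[w$rpe_present][1]
  none_well <- w$well_id[!w$rpe_present & !w$lens_present][1]
  expect_false(is.na(rpe_well))
  expect_false(is.na(none_well))

  # pre-visibility frame of a fated well: no pigment-dark pixels (debris
  # speckles stay above 25; rendered pigment reaches far lower)
  pre <- render_frame(ds, "E001", rpe_well, 3)
  post <- render_frame(ds, "E001", rpe_well, 8)
  m <- true_mask(ds, "E001", rpe_well, 3)
  m8 <- true_mask(ds, "E001", rpe_well, 8)
  expect_equal(sum(pre[m > 0] < 25), 0)
  expect_gt(sum(post[m8 > 0] < 25), 0)

  # non-fated well at the last loop: no pigment, no bright lens interior
  last <- render_frame(ds, "E001", none_well, 8)
  mm <- true_mask(ds, "E001", none_well, 8)
  expect_equal(sum(last[mm > 0] < 25), 0)
  erode_mask <- function(mk) (matrix(EBImage::imageData(EBImage::erode(
    EBImage::Image(mk * 1), EBImage::makeBrush(7, "disc"))),
    nrow(mk), ncol(mk)) > 0.5) * 1
  expect_equal(sum(last[erode_mask(mm) > 0] > 160), 0)
  lens_well <- w$well_id[w$lens_present][1]
  lens_last <- render_frame(ds, "E001", lens_well, 8)
  lens_mask <- erode_mask(true_mask(ds, "E001", lens_well, 8))
  lv <- lens_last[lens_mask > 0]
  expect_gt(sum(lv > stats::median(lv) + 40), 50)
  nv <- last[erode_mask(mm) > 0]
  expect_equal(sum(nv > stats::median(nv) + 40), 0)
})

test_that("true masks are single-component and exclusions are upward-closed", {
  ds <- tiny_dataset(seed = 8, wells = 20, loops = 6, exclusion_prob = 0.5)
  for (i in seq_len(5)) {
    m <- true_mask(ds, "E001", ds$wells$well_id[i], 6)
    lab <- orgfate:::label_components(m)
    expect_equal(max(lab), 1L)
  }
  for (wid in ds$wells$well_id) {
    ex <- excluded_loops(ds, "E001", wid)
    if (length(ex) > 0) {
      expect_equal(ex, seq.int(min(ex), ds$cfg$n_loops))
    }
  }
  fr <- dataset_frames(ds)
  by_well <- split(fr[fr$z == 1, ], fr$well_id[fr$z == 1])
  for (d in by_well) {
    excl <- d$loop[d$excluded]
    if (length(excl)) expect_equal(excl, seq.int(min(excl), max(d$loop)))
  }
})

test_that("zero signal strength makes pre-visibility texture exchangeable", {
  # permutation oracle on the blur statistic of loop-1 frames
  ds <- tiny_dataset(seed = 21, wells = 24, loops = 4, signal_strength = 0)
  stat <- vapply(ds$wells$well_id, function(wid) {
    img <- render_frame(ds, "E001", wid, 1)
    orgfate:::laplacian_variance(img, true_mask(ds, "E001", wid, 1))
  }, numeric(1))
  fated <- ds$wells$fated_rpe
  obs <- abs(mean(stat[fated]) - mean(stat[!fated]))
  set.seed(1)
  perm <- replicate(500, {
    f <- sample(fated)
    abs(mean(stat[f]) - mean(stat[!f]))
  })
  p <- mean(perm >= obs)
  expect_gt(p, 0.05)
})

test_that("strong signal strength separates fated wells from loop 1", {
  ds <- tiny_dataset(seed = 21, wells = 24, loops = 4, signal_strength = 6)
  stat <- vapply(ds$wells$well_id, function(wid) {
    img <- render_frame(ds, "E001", wid, 1)
    orgfate:::laplacian_variance(img, true_mask(ds, "E001", wid, 1))
  }, numeric(1))
  fated <- ds$wells$fated_rpe
  obs <- mean(stat[fated]) - mean(stat[!fated])
  expect_gt(obs, 0)
  set.seed(1)
  perm <- replicate(500, {
    f <- sample(fated)
    mean(stat[f]) - mean(stat[!f])
  })
  expect_lt(mean(perm >= obs), 0.05)
})

test_that("16-bit frames carry identical content on the wider scale", {
  ds <- tiny_dataset(wells = 1, loops = 4)
  f8 <- render_frame(ds, "E001", "A01", 2)
  f16 <- render_frame(ds, "E001", "A01", 2, bit_depth = 16)
  expect_equal(max(f16), max(f8) * 257)
  expect_equal(orgfate:::to_uint8(f16), orgfate:::to_uint8(f8))
})
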