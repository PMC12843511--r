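#' Acquisition configuration for the synthetic time-lapse generator
#'
#' Describes the imaging design being emulated: a 96-well plate imaged every
#' 30 minutes over 72 hours (144 loops) as 5-slice z-stacks spaced 50 um,
#' one organoid per well. The defaults reproduce that design; the number of
#' loops is derived and must come out integer.
#'
#' @param n_experiments Number of experimental replicates (plates).
#' @param wells_per_plate Wells per plate (default 96).
#' @param duration_h Imaging duration in hours (default 72).
#' @param interval_min Loop interval in minutes (default 30).
#' @param n_z Number of z-slices per stack (default 5).
#' @param z_spacing_um Slice spacing in micrometres (default 50).
#' @param frame_px Synthetic frame side length in pixels (default 512).
#' @param um_per_px Micrometres per pixel (default 1.5); no calibration is
#'   published for the emulated microscopes, so absolute areas are set by
#'   this configurable convention.
#' @param seed Integer seed controlling every random draw of the generator.
#' @return A list of class `acquisition_config` with an added `n_loops`.
#' @export
acquisition_config <- function(n_experiments = 1L, wells_per_plate = 96L,
                               duration_h = 72, interval_min = 30,
                               n_z = 5L, z_spacing_um = 50,
                               frame_px = 512L, um_per_px = 1.5,
                               seed = 1L) {
  n_loops <- duration_h * 60 / interval_min
  if (abs(n_loops - round(n_loops)) > 1e-9)
    stop("duration_h * 60 / interval_min must be an integer number of loops")
  if (wells_per_plate < 1L) stop("wells_per_plate must be positive")
  stopifnot(n_experiments >= 1L, n_z >= 1L, frame_px >= 32L, um_per_px > 0)
  structure(list(
    n_experiments = as.integer(n_experiments),
    wells_per_plate = as.integer(wells_per_plate),
    duration_h = duration_h, interval_min = interval_min,
    n_loops = as.integer(round(n_loops)),
    n_z = as.integer(n_z), z_spacing_um = z_spacing_um,
    frame_px = as.integer(frame_px), um_per_px = um_per_px,
    seed = as.integer(seed)
  ), class = "acquisition_config")
}

#' Fate specification for the synthetic generator
#'
#' Controls the latent fate signal and the visible tissue structures.
#' Fated organoids carry a subtle oriented-texture cue from the first loop
#' (second-order statistics, invisible to plain thresholding); the visible
#' structures — dark pigment (RPE) patches and a bright lens disc — are only
#' rendered from their visibility loops onward, mirroring tissue that
#' becomes visible late in the imaging window (lens around 59 h, pigment
#' around 68 h of the 72 h covered).
#'
#' @param rpe_prob,lens_prob Per-well probabilities of being fated.
#' @param rpe_visible_loop,lens_visible_loop 1-based loop indices at which
#'   the structures start being rendered (defaults 136 and 118 of 144).
#' @param signal_strength Amplitude (8-bit intensity units) of the
#'   pre-visibility texture cue; 0 means no predictive cue exists.
#' @param rpe_area_dist,lens_area_dist Distribution of final areas in um^2:
#'   `list(family = "lognormal", meanlog=, sdlog=)`.
#' @param batch_effects Per-experiment heterogeneity:
#'   `list(illumination_sd=, radius_shift_sd=)`.
#' @param exclusion_prob Per-well probability of an out-of-focus/out-of-frame
#'   event; once it occurs all later loops of that well are excluded.
#' @return A list of class `fate_spec`.
#' @export
fate_spec <- function(rpe_prob = 0.5, lens_prob = 0.5,
                      rpe_visible_loop = 136L, lens_visible_loop = 118L,
                      signal_strength = 2,
                      rpe_area_dist = list(family = "lognormal",
                                           meanlog = log(6000), sdlog = 0.5),
                      lens_area_dist = list(family = "lognormal",
                                            meanlog = log(22000), sdlog = 0.4),
                      batch_effects = list(illumination_sd = 8,
                                           radius_shift_sd = 0.06),
                      exclusion_prob = 0.02) {
  stopifnot(rpe_prob >= 0, rpe_prob <= 1, lens_prob >= 0, lens_prob <= 1,
            signal_strength >= 0, exclusion_prob >= 0, exclusion_prob <= 1)
  structure(list(rpe_prob = rpe_prob, lens_prob = lens_prob,
                 rpe_visible_loop = as.integer(rpe_visible_loop),
                 lens_visible_loop = as.integer(lens_visible_loop),
                 signal_strength = signal_strength,
                 rpe_area_dist = rpe_area_dist,
                 lens_area_dist = lens_area_dist,
                 batch_effects = batch_effects,
                 exclusion_prob = exclusion_prob),
            class = "fate_spec")
}

draw_area <- function(dist, n) {
  switch(dist$family,
         lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
         gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
         uniform = stats::runif(n, dist$min, dist$max),
         stop("unknown area distribution family: ", dist$family))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Granular pigment layout: melanin granule discs filling a circular
# envelope to ~55% until their union reaches the target area. Positions and
# radii are in pixels relative to the (integer) patch centre; the union is
# rasterized on the same integer lattice used at render time, so the stored
# area is exactly the rendered pigment pixel count.
granule_layout <- function(target_px, gr_min_px, gr_max_px, seed) {
  if (target_px <= 0) return(NULL)
  R <- sqrt(target_px / (pi * 0.55))
  half <- as.integer(ceiling(R + gr_max_px + 1))
  side <- 2L * half + 1L
  with_seed(seed, {
    acc <- matrix(FALSE, side, side)
    xs <- seq_len(side) - half - 1L
    X <- matrix(xs, side, side)
    Y <- t(X)
    dx <- dy <- r <- numeric(0)
    for (i in 1:2000) {
      rr <- sqrt(stats::runif(1)) * R
      th <- stats::runif(1, 0, 2 * pi)
      gx <- rr * cos(th); gy <- rr * sin(th)
      gr <- stats::runif(1, gr_min_px, gr_max_px)
      acc <- acc | ((X - gx)^2 + (Y - gy)^2 <= gr^2)
      dx <- c(dx, gx); dy <- c(dy, gy); r <- c(r, gr)
      if (sum(acc) >= target_px) break
    }
    list(dx = dx, dy = dy, r = r, area_px = sum(acc), half = half)
  })
}

well_names <- function(n) {
  if (n <= 96L) {
    rows <- rep(LETTERS[1:8], each = 12L)
    cols <- rep(1:12, times = 8L)
    sprintf("%s%02d", rows[seq_len(n)], cols[seq_len(n)])
  } else sprintf("W%03d", seq_len(n))
}

#' Simulate a multi-well time-lapse dataset
#'
#' Draws per-experiment batch effects (illumination offset, mean organoid
#' radius), per-well fates, final tissue areas, growth and shape-divergence
#' parameters, centre drift and exclusion events, and returns a lazy dataset
#' object. Frames are rendered on demand by [render_frame()] so the dataset
#' scales to full plates without holding every image in memory; two datasets
#' built with the same configuration and seed are bit-identical.
#'
#' @param cfg An [acquisition_config()].
#' @param fate A [fate_spec()].
#' @return An object of class `organoid_dataset` with tibble `wells`
#'   (one row per organoid: ids, fates, geometry, outcome ground truth,
#'   `excluded_from`) and the two configs.
#' @export
simulate_experiment <- function(cfg, fate = fate_spec()) {
  stopifnot(inherits(cfg, "acquisition_config"), inherits(fate, "fate_spec"))
  if (fate$rpe_visible_loop > cfg$n_loops || fate$lens_visible_loop > cfg$n_loops)
    stop("visibility loops must lie within the acquisition window")
  px <- cfg$frame_px
  base_radius_um <- 120                      # initial organoid radius, um
  wells <- purrr::map_dfr(seq_len(cfg$n_experiments), function(e) {
    batch <- with_seed(derive_seed(cfg$seed, e, 7L), list(
      illum = stats::rnorm(1, 0, fate$batch_effects$illumination_sd),
      radius_shift = stats::rnorm(1, 0, fate$batch_effects$radius_shift_sd)
    ))
    purrr::map_dfr(seq_len(cfg$wells_per_plate), function(w) {
      with_seed(derive_seed(cfg$seed, e, w, 11L), {
        fated_rpe <- stats::runif(1) < fate$rpe_prob
        fated_lens <- stats::runif(1) < fate$lens_prob
        r0_um <- base_radius_um * (1 + batch$radius_shift) *
          stats::rlnorm(1, 0, 0.08)
        growth <- stats::rnorm(1, 0.55, 0.08)
        # shape-divergence harmonics: amplitude ramps with loop index
        harm_a <- stats::runif(3, 0.4, 1)
        harm_k <- sample(2:6, 3)
        harm_phi <- stats::runif(3, 0, 2 * pi)
        drift_angle <- stats::runif(1, 0, 2 * pi)
        drift_rate <- stats::rnorm(1, 0, 0.02)  # px per loop
        tex_angle <- stats::runif(1, 0, pi)
        # pigment and lens develop on opposite sides so the bright lens
        # never occludes the dark pigment patch
        lens_angle <- stats::runif(1, 0, 2 * pi)
        rpe_angle <- lens_angle + pi + stats::runif(1, -0.5, 0.5)
        # target areas are capped to what fits inside the grown organoid so
        # the stored ground truth equals what is actually rendered; pigment
        # is granular (melanin granule discs), and its stored area is the
        # exact rasterized union of the granules
        r_final_um <- r0_um * (1 + growth)
        r_final_px <- r_final_um / cfg$um_per_px
        rpe_granules <- NULL
        rpe_area <- 0
        if (fated_rpe) {
          target_px <- min(draw_area(fate$rpe_area_dist, 1) / cfg$um_per_px^2,
                           0.55 * pi * (0.38 * r_final_px)^2)
          rpe_granules <- granule_layout(
            target_px,
            gr_min_px = max(1.2, 6 / cfg$um_per_px),
            gr_max_px = max(2.0, 12 / cfg$um_per_px),
            seed = derive_seed(cfg$seed, e, w, 13L))
          rpe_area <- rpe_granules$area_px * cfg$um_per_px^2
        }
        lens_area <- if (fated_lens)
          min(draw_area(fate$lens_area_dist, 1), pi * (0.35 * r_final_um)^2)
          else 0
        n_spk <- max(3L, round(0.002 * pi * (r_final_um / cfg$um_per_px)^2))
        spk_rel_r <- sqrt(stats::runif(n_spk)) * 0.9
        spk_theta <- stats::runif(n_spk, 0, 2 * pi)
        excl <- stats::runif(1) < fate$exclusion_prob
        excluded_from <- if (excl)
          sample(seq_len(cfg$n_loops), 1) else NA_integer_
        tibble::tibble(
          experiment_id = sprintf("E%03d", e),
          well_id = well_names(cfg$wells_per_plate)[w],
          fated_rpe = fated_rpe, fated_lens = fated_lens,
          r0_um = r0_um, growth = growth,
          harm = list(list(a = harm_a, k = harm_k, phi = harm_phi)),
          drift_angle = drift_angle, drift_rate = drift_rate,
          tex_angle = tex_angle, rpe_angle = rpe_angle,
          lens_angle = lens_angle,
          speckles = list(list(rel_r = spk_rel_r, theta = spk_theta)),
          rpe_granules = list(rpe_granules),
          illum = batch$illum,
          rpe_present = fated_rpe, rpe_area_um2 = rpe_area,
          lens_present = fated_lens, lens_area_um2 = lens_area,
          excluded_from = excluded_from
        )
      })
    })
  })
  structure(list(cfg = cfg, fate = fate, wells = wells),
            class = "organoid_dataset")
}

#' @export
print.organoid_dataset <- function(x, ...) {
  cat("<organoid_dataset> ", x$cfg$n_experiments, " experiment(s) x ",
      x$cfg$wells_per_plate, " wells x ", x$cfg$n_loops, " loops x ",
      x$cfg$n_z, " z-slices (", x$cfg$frame_px, " px frames)\n", sep = "")
  invisible(x)
}

#' Frame metadata table for a dataset
#'
#' One row per (experiment, well, loop, z) with the exclusion flag; the row
#' count equals wells x loops x z per plate.
#' @param ds An `organoid_dataset`.
#' @return A tibble.
#' @export
dataset_frames <- function(ds) {
  stopifnot(inherits(ds, "organoid_dataset"))
  grid <- tidyr::expand_grid(
    ds$wells[, c("experiment_id", "well_id", "excluded_from")],
    loop = seq_len(ds$cfg$n_loops), z = seq_len(ds$cfg$n_z)
  )
  dplyr::mutate(grid,
    excluded = !is.na(.data$excluded_from) & .data$loop >= .data$excluded_from,
    excluded_from = NULL)
}

#' Ground-truth outcome table
#'
#' Per-organoid tissue outcomes: presence flags and final areas (um^2) for
#' pigmented epithelium and lens. Size classes can be added with
#' [assign_size_class()]; an absent tissue is class 0 by definition.
#' @param ds An `organoid_dataset`.
#' @return A tibble with one row per organoid.
#' @export
dataset_outcomes <- function(ds) {
  stopifnot(inherits(ds, "organoid_dataset"))
  ds$wells[, c("experiment_id", "well_id", "rpe_present", "rpe_area_um2",
               "lens_present", "lens_area_um2")]
}

well_row <- function(ds, experiment_id, well_id) {
  i <- which(ds$wells$experiment_id == experiment_id &
             ds$wells$well_id == well_id)
  if (length(i) != 1L) stop("unknown well: ", experiment_id, "/", well_id)
  ds$wells[i, ]
}

# organoid radius (px) at a loop, and the visible-structure ramp 0..1
radius_px_at <- function(ds, w, loop) {
  frac <- (loop - 1) / max(1L, ds$cfg$n_loops - 1L)
  (w$r0_um / ds$cfg$um_per_px) * (1 + w$growth * frac)
}

structure_ramp <- function(loop, visible_loop, ramp_loops = 6L) {
  if (loop < visible_loop) 0 else min(1, (loop - visible_loop + 1) / ramp_loops)
}

# polar geometry of a well's organoid at a loop (no noise, no blur)
organoid_geometry <- function(ds, w, loop) {
  px <- ds$cfg$frame_px
  r_base <- radius_px_at(ds, w, loop)
  frac <- (loop - 1) / max(1L, ds$cfg$n_loops - 1L)
  ctr <- px / 2 + 0.5 +
    c(cos(w$drift_angle), sin(w$drift_angle)) * w$drift_rate * (loop - 1)
  xs <- seq_len(px) - ctr[1]
  ys <- seq_len(px) - ctr[2]
  X <- matrix(xs, px, px)
  Y <- matrix(ys, px, px, byrow = TRUE)
  D <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  h <- w$harm[[1]]
  div_amp <- 0.12 * frac                     # shape divergence ramps up
  mod <- 1 + div_amp * (h$a[1] * cos(h$k[1] * TH + h$phi[1]) +
                        h$a[2] * cos(h$k[2] * TH + h$phi[2]) +
                        h$a[3] * cos(h$k[3] * TH + h$phi[3])) / sum(h$a)
  list(X = X, Y = Y, D = D, TH = TH, r_eff = r_base * mod, ctr = ctr,
       r_base = r_base)
}

#' Ground-truth organoid mask
#'
#' Rasterizes the noiseless organoid silhouette (a single connected
#' component) for one well at one loop.
#' @param ds An `organoid_dataset`.
#' @param experiment_id,well_id Well identifiers.
#' @param loop 1-based loop index.
#' @return Binary matrix (`frame_px` square).
#' @export
true_mask <- function(ds, experiment_id, well_id, loop) {
  w <- well_row(ds, experiment_id, well_id)
  g <- organoid_geometry(ds, w, loop)
  (g$D <= g$r_eff) * 1
}

#' Render one synthetic brightfield frame
#'
#' The organoid appears as a dark body on a bright background with seeded
#' speckle texture. Away from the middle slice a z-dependent defocus blur is
#' applied, making the middle slice the sharpest. Fated wells carry the
#' latent oriented-texture cue from loop 1; pigment patches and the bright
#' lens disc are rendered only from their visibility loops.
#'
#' @param ds An `organoid_dataset`.
#' @param experiment_id,well_id Well identifiers.
#' @param loop 1-based loop index.
#' @param z 1-based slice index (middle slice is `ceiling(n_z / 2)`).
#' @param stereo Render the post-acquisition stereomicroscope-style image:
#'   no defocus, structures at full final size.
#' @param bit_depth 8 (default) or 16; the 16-bit frame carries the same
#'   content on 0..65535, exercising consumers' 8-bit conversion path.
#' @return Numeric matrix on 0..255 (or 0..65535 for `bit_depth = 16`).
#' @export
render_frame <- function(ds, experiment_id, well_id, loop, z = NULL,
                         stereo = FALSE, bit_depth = 8L) {
  stopifnot(inherits(ds, "organoid_dataset"))
  cfg <- ds$cfg
  if (is.null(z)) z <- (cfg$n_z + 1L) %/% 2L
  if (loop < 1L || loop > cfg$n_loops) stop("loop index out of range")
  if (z < 1L || z > cfg$n_z) stop("z index out of range")
  w <- well_row(ds, experiment_id, well_id)
  e <- as.integer(sub("^E", "", experiment_id))
  wi <- match(well_id, well_names(cfg$wells_per_plate))
  g <- organoid_geometry(ds, w, loop)
  px <- cfg$frame_px
  inside <- g$D <= g$r_eff
  edge <- pmin(pmax((g$r_eff - g$D) / 2, 0), 1)   # 2-px soft rim

  bg <- 185 + w$illum
  # gently shaded body (brighter centre, darker rim) over a bright ground
  rel <- pmin(g$D / pmax(g$r_eff, 1e-9), 1)
  body <- 100 + 12 * (1 - rel^2) + w$illum
  img <- matrix(bg, px, px) * (1 - edge) + body * edge

  noise_seed <- derive_seed(cfg$seed, e, wi, loop, z, 23L)
  noise <- with_seed(noise_seed, {
    n1 <- blur_image(matrix(stats::rnorm(px * px), px, px), 1.2) * 3
    n2 <- blur_image(matrix(stats::rnorm(px * px), px, px), 2) * 6
    list(tissue = n1, bg = n2)
  })
  img <- img + noise$tissue * edge + noise$bg * (1 - edge) +
    with_seed(noise_seed + 1L, matrix(stats::rnorm(px * px, 0, 2), px, px))

  # sparse dark debris speckles, static in the organoid's frame of reference
  spk <- w$speckles[[1]]
  sr <- round(g$ctr[1] + spk$rel_r * g$r_base * cos(spk$theta))
  sc <- round(g$ctr[2] + spk$rel_r * g$r_base * sin(spk$theta))
  ok <- sr >= 1 & sr <= px & sc >= 1 & sc <= px
  if (any(ok)) {
    delta <- matrix(0, px, px)
    delta[cbind(sr[ok], sc[ok])] <- 1
    spk_img <- blur_image(delta, 0.7)
    mx <- max(spk_img)
    if (mx > 0) img <- img - 55 * (spk_img / mx) * edge
  }

  # cue wavelength: 12 um, floored at 4 px so the texture stays resolvable
  # when coarse pixel calibrations are simulated
  # cue wavelengths: 12 um (pigment fate) and 24 um (lens fate), floored so
  # the textures stay resolvable at coarse pixel calibrations; the two
  # tissues carry cues at distinct spatial scales so their second-order
  # statistics are separable
  lam <- max(4, 12 / cfg$um_per_px)
  lam_lens <- 2 * lam
  if (ds$fate$signal_strength > 0) {
    if (w$fated_rpe) {
      ph <- g$X * cos(w$tex_angle) + g$Y * sin(w$tex_angle)
      img <- img + ds$fate$signal_strength * sin(2 * pi * ph / lam) * edge
    }
    if (w$fated_lens) {
      img <- img + ds$fate$signal_strength * sin(2 * pi * g$D / lam_lens) * edge
    }
  }

  rpe_ramp <- if (stereo) as.numeric(w$rpe_present)
    else structure_ramp(loop, ds$fate$rpe_visible_loop)
  if (w$rpe_present && rpe_ramp > 0 && !is.null(w$rpe_granules[[1]])) {
    gl <- w$rpe_granules[[1]]
    # pigment grows outward: granules appear centre-first with the ramp
    n_show <- ceiling(rpe_ramp * length(gl$r))
    show <- order(gl$dx^2 + gl$dy^2)[seq_len(n_show)]
    pc <- round(g$ctr + 0.42 * g$r_base * c(cos(w$rpe_angle), sin(w$rpe_angle)))
    r0 <- max(1L, pc[1] - gl$half); r1 <- min(px, pc[1] + gl$half)
    c0 <- max(1L, pc[2] - gl$half); c1 <- min(px, pc[2] + gl$half)
    if (r1 >= r0 && c1 >= c0) {
      Xl <- matrix(r0:r1 - pc[1], r1 - r0 + 1L, c1 - c0 + 1L)
      Yl <- matrix(c0:c1 - pc[2], r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
      ml <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      for (j in show)
        ml <- ml | ((Xl - gl$dx[j])^2 + (Yl - gl$dy[j])^2 <= gl$r[j]^2)
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] -
        70 * ml * edge[r0:r1, c0:c1]
    }
  }
  lens_ramp <- if (stereo) as.numeric(w$lens_present)
    else structure_ramp(loop, ds$fate$lens_visible_loop)
  if (w$lens_present && lens_ramp > 0) {
    full_px2 <- w$lens_area_um2 / cfg$um_per_px^2
    r_lens <- sqrt(lens_ramp * full_px2 / pi)
    lc <- g$ctr + 0.35 * g$r_base * c(cos(w$lens_angle), sin(w$lens_angle))
    LD <- sqrt((g$X + g$ctr[1] - lc[1])^2 + (g$Y + g$ctr[2] - lc[2])^2)
    disc <- pmin(pmax((r_lens - LD) / 1.5, 0), 1)
    img <- img + 55 * disc * edge
  }

  if (!stereo) {
    mid <- (cfg$n_z + 1L) %/% 2L
    sigma <- 1.1 * abs(z - mid)
    if (sigma > 0) img <- blur_image(img, sigma)
  }
  img <- pmin(pmax(img, 0), 255)
  if (bit_depth == 16L) img * 257 else img
}

#' Render the stereomicroscope-style image of a well
#'
#' Convenience wrapper for the post-time-lapse image used for pigment-area
#' quantification: sharp focus, visible structures at final size.
#' @inheritParams render_frame
#' @return Numeric matrix on 0..255.
#' @export
render_stereo <- function(ds, experiment_id, well_id) {
  render_frame(ds, experiment_id, well_id, ds$cfg$n_loops, stereo = TRUE)
}

#' Excluded loops for a well
#'
#' Once an organoid goes out of frame or focus at some loop, that loop and
#' all later loops are excluded; the set is upward-closed by construction.
#' @inheritParams render_frame
#' @return Integer vector of excluded 1-based loop indices (possibly empty).
#' @export
excluded_loops <- function(ds, experiment_id, well_id) {
  w <- well_row(ds, experiment_id, well_id)
  if (is.na(w$excluded_from)) integer(0)
  else seq.int(w$excluded_from, ds$cfg$n_loops)
}

#' Write a dataset to disk
#'
#' Writes per-frame TIFFs under `E{exp}/{well}/L{loop}_Z{z}.tif`, masks as
#' PNG, and the outcome table as CSV. Intended for interoperability spot
#' checks, not for full plates.
#' @param ds An `organoid_dataset`.
#' @param dir Output directory.
#' @param loops,zs Subsets of loops / z-slices to write (defaults: all).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(ds, dir, loops = seq_len(ds$cfg$n_loops),
                          zs = seq_len(ds$cfg$n_z)) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("png", quietly = TRUE))
    stop("writing datasets requires the 'tiff' and 'png' packages")
  for (i in seq_len(nrow(ds$wells))) {
    w <- ds$wells[i, ]
    wd <- file.path(dir, w$experiment_id, w$well_id)
    dir.create(wd, recursive = TRUE, showWarnings = FALSE)
    for (loop in loops) {
      for (z in zs) {
        img <- render_frame(ds, w$experiment_id, w$well_id, loop, z)
        tiff::writeTIFF(img / 255,
                        file.path(wd, sprintf("L%03d_Z%d.tif", loop, z)))
      }
      msk <- true_mask(ds, w$experiment_id, w$well_id, loop)
      png::writePNG(msk, file.path(wd, sprintf("L%03d_mask.png", loop)))
    }
  }
  utils::write.csv(dataset_outcomes(ds),
                   file.path(dir, "outcomes.csv"), row.names = FALSE)
  invisible(dir)
}
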