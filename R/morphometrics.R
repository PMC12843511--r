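# The 165-feature morphometrics registry and extractor.
#
# Conventions (fixed, versioned with the registry):
# * coordinates are (row, col), zero-based and bounding-box-local for all
#   moment features, so moments are translation invariant;
# * intensity statistics use the population standard deviation;
# * skewness = m3/m2^(3/2) and kurtosis = m4/m2^2 - 3 (excess), both from
#   population moments, defined as 0 for a flat intensity distribution;
# * blur is the sample variance of the 4-neighbour Laplacian response over
#   mask pixels; the modal value bins intensities to integers and breaks
#   ties toward the smallest intensity.

registry_version <- "1.0"

moment_names <- function(prefix) {
  as.vector(outer(0:3, 0:3, function(p, q) sprintf("%s_%d%d", prefix, p, q)))
}

#' The fixed morphometrics feature registry
#'
#' An ordered table of exactly 165 named features: 30 standard region and
#' intensity descriptors, 110 binary and intensity-weighted image-moment
#' features (raw/central/normalized orders up to 3 plus both Hu sets),
#' 5 inertia-tensor features, 4 further geometry descriptors, and the 7
#' custom shape plus 9 custom intensity formulas. Order and names are fixed;
#' every accepted frame yields exactly this set.
#'
#' @return Tibble with columns `index`, `name`, `category`.
#' @export
feature_registry <- function() {
  standard <- c("area", "area_convex", "area_filled",
                "bbox_min_row", "bbox_min_col", "bbox_max_row", "bbox_max_col",
                "bbox_width", "bbox_height", "bbox_area",
                "centroid_row", "centroid_col",
                "centroid_local_row", "centroid_local_col",
                "centroid_weighted_row", "centroid_weighted_col",
                "eccentricity", "equivalent_diameter", "euler_number",
                "extent", "feret_diameter_max",
                "axis_major_length", "axis_minor_length", "orientation",
                "perimeter", "solidity",
                "intensity_max", "intensity_mean", "intensity_min",
                "intensity_std")
  std_cat <- c(rep("geometry", 26), rep("intensity", 4))
  moments <- c(moment_names("moment_m"), moment_names("moment_mu"),
               moment_names("moment_nu"), sprintf("moment_hu_%d", 1:7),
               moment_names("moment_wm"), moment_names("moment_wmu"),
               moment_names("moment_wnu"), sprintf("moment_whu_%d", 1:7))
  inertia <- c("inertia_tensor_00", "inertia_tensor_01", "inertia_tensor_11",
               "inertia_eigval_1", "inertia_eigval_2")
  extra <- c("centroid_weighted_local_row", "centroid_weighted_local_col",
             "convex_perimeter", "radius_gyration")
  shape <- c("aspect_ratio", "roundness", "compactness", "circularity",
             "form_factor", "effective_diameter", "convexity")
  intens <- c("blur", "roi_contrast", "image_contrast", "median_intensity",
              "modal_value", "integrated_density", "raw_integrated_density",
              "skewness", "kurtosis")
  nm <- c(standard, moments, inertia, extra, shape, intens)
  cat <- c(std_cat, rep("moments", length(moments)),
           rep("moments", length(inertia)), rep("geometry", length(extra)),
           rep("custom_shape", length(shape)),
           rep("custom_intensity", length(intens)))
  stopifnot(length(nm) == 165L, !anyDuplicated(nm))
  tibble::tibble(index = seq_along(nm), name = nm, category = cat)
}

# registry names cached at install time (names are fixed by version)
.REG_NAMES <- NULL

reg_names <- function() {
  if (is.null(.REG_NAMES)) {
    utils::assignInMyNamespace(".REG_NAMES", feature_registry()$name)
  }
  .REG_NAMES
}

# moments of a point cloud (optionally weighted), orders 0..3
point_moments <- function(r, c, w = NULL) {
  if (is.null(w)) w <- rep(1, length(r))
  m <- matrix(0, 4, 4)
  rp <- cbind(1, r, r^2, r^3)
  cp <- cbind(1, c, c^2, c^3)
  for (p in 0:3) for (q in 0:3) m[p + 1, q + 1] <- sum(w * rp[, p + 1] * cp[, q + 1])
  m
}

central_moments <- function(r, c, w = NULL) {
  if (is.null(w)) w <- rep(1, length(r))
  s <- sum(w)
  point_moments(r - sum(w * r) / s, c - sum(w * c) / s, w)
}

normalized_moments <- function(mu) {
  nu <- matrix(0, 4, 4)
  for (p in 0:3) for (q in 0:3) {
    if (p + q < 2) {
      nu[p + 1, q + 1] <- if (p + q == 0) 1 else 0
    } else {
      nu[p + 1, q + 1] <- mu[p + 1, q + 1] / mu[1, 1]^(1 + (p + q) / 2)
    }
  }
  nu
}

hu_moments <- function(nu) {
  n20 <- nu[3, 1]; n02 <- nu[1, 3]; n11 <- nu[2, 2]
  n30 <- nu[4, 1]; n03 <- nu[1, 4]; n21 <- nu[3, 2]; n12 <- nu[2, 3]
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# weighted border-pixel perimeter estimator (cross-erosion border, weights
# 1, sqrt(2) and (1+sqrt(2))/2 by local border configuration)
mask_perimeter <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(0, n + 2L, m + 2L)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  up <- pad[1:n, 2:(m + 1)]; dn <- pad[3:(n + 2), 2:(m + 1)]
  lf <- pad[2:(n + 1), 1:m]; rt <- pad[2:(n + 1), 3:(m + 2)]
  eroded <- mask * (up * dn * lf * rt)
  border <- mask - eroded
  bp <- matrix(0, n + 2L, m + 2L)
  bp[2:(n + 1), 2:(m + 1)] <- border
  ctr <- bp[2:(n + 1), 2:(m + 1)]
  code <- 10 * (bp[1:n, 1:m] + bp[1:n, 3:(m + 2)] +
                bp[3:(n + 2), 1:m] + bp[3:(n + 2), 3:(m + 2)]) +
          2 * (bp[1:n, 2:(m + 1)] + bp[3:(n + 2), 2:(m + 1)] +
               bp[2:(n + 1), 1:m] + bp[2:(n + 1), 3:(m + 2)]) + ctr
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(w[code[ctr > 0] + 1])
}

convex_hull_info <- function(r, c) {
  pts <- unique(cbind(r, c))
  if (nrow(pts) < 3) {
    len <- if (nrow(pts) == 2) 2 * sqrt(sum((pts[1, ] - pts[2, ])^2)) else 0
    return(list(area = length(r), perimeter = len, hull = pts))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  hp <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), , drop = FALSE])^2)))
  rr <- floor(min(r)):ceiling(max(r))
  cc <- floor(min(c)):ceiling(max(c))
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inside <- pracma::inpolygon(grid[, 1], grid[, 2], hull[, 1], hull[, 2],
                              boundary = TRUE)
  list(area = sum(inside), perimeter = hp, hull = hull)
}

mask_euler_number <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  r1 <- range(idx[, 1]); r2 <- range(idx[, 2])
  sub <- mask[r1[1]:r1[2], r2[1]:r2[2], drop = FALSE]
  n <- nrow(sub); m <- ncol(sub)
  pad <- matrix(0, n + 2L, m + 2L)
  pad[2:(n + 1), 2:(m + 1)] <- sub
  ncomp <- max(label_components(pad))
  inv <- 1 - pad
  lab_bg <- label_components(inv)
  border_labels <- unique(c(lab_bg[1, ], lab_bg[n + 2, ],
                            lab_bg[, 1], lab_bg[, m + 2]))
  holes <- setdiff(unique(lab_bg[lab_bg > 0]), border_labels)
  as.integer(ncomp - length(holes))
}

# full 165-feature vector (internal; names match feature_registry())
.extract_vec <- function(image, mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  n_px <- nrow(idx)
  if (n_px == 0L) stop("empty mask")
  lab <- label_components(mask)
  if (max(lab) > 1L) stop("mask has more than one connected component")
  r <- idx[, 1]; c <- idx[, 2]
  I <- image[idx]
  bb <- c(min(r), min(c), max(r), max(c))
  bw <- bb[4] - bb[2] + 1; bh <- bb[3] - bb[1] + 1
  r0 <- r - bb[1]; c0 <- c - bb[2]        # bbox-local, zero-based
  area <- n_px
  hull <- convex_hull_info(r0, c0)
  filled <- sum(fill_holes(mask))
  cen <- c(mean(r), mean(c))
  wsum <- sum(I)
  wcen <- if (wsum > 0) c(sum(I * r), sum(I * c)) / wsum else cen

  mu <- central_moments(r0, c0)
  m <- point_moments(r0, c0)
  nu <- normalized_moments(mu)
  hu <- hu_moments(nu)
  wm <- point_moments(r0, c0, I)
  wmu <- central_moments(r0, c0, I)
  wnu <- normalized_moments(wmu)
  whu <- hu_moments(wnu)

  cov <- matrix(c(mu[3, 1], mu[2, 2], mu[2, 2], mu[1, 3]), 2) / mu[1, 1]
  ev <- eigen(cov, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  orient <- 0.5 * atan2(2 * mu[2, 2], mu[3, 1] - mu[1, 3])
  inertia <- matrix(c(mu[3, 1], -mu[2, 2], -mu[2, 2], mu[1, 3]), 2) / mu[1, 1]
  iev <- sort(eigen(inertia, symmetric = TRUE)$values, decreasing = TRUE)

  perim <- mask_perimeter(mask)
  feret <- if (nrow(hull$hull) >= 2) {
    hp <- hull$hull
    max(stats::dist(hp))
  } else 0

  # custom intensity formulas
  lvar <- laplacian_variance(image, mask)
  roi_contrast <- max(I) - min(I)
  image_contrast <- max(image) - min(image)
  med <- stats::median(I)
  Ii <- round(I)
  u <- sort(unique(Ii))
  modal <- u[which.max(tabulate(match(Ii, u)))]   # ties -> smallest intensity
  m2 <- mean((I - mean(I))^2)
  skew <- if (m2 > 0) mean((I - mean(I))^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((I - mean(I))^4) / m2^2 - 3 else 0

  out <- c(
    area = area, area_convex = hull$area, area_filled = filled,
    bbox_min_row = bb[1], bbox_min_col = bb[2],
    bbox_max_row = bb[3], bbox_max_col = bb[4],
    bbox_width = bw, bbox_height = bh, bbox_area = bw * bh,
    centroid_row = cen[1], centroid_col = cen[2],
    centroid_local_row = cen[1] - bb[1], centroid_local_col = cen[2] - bb[2],
    centroid_weighted_row = wcen[1], centroid_weighted_col = wcen[2],
    eccentricity = ecc, equivalent_diameter = 2 * sqrt(area / pi),
    euler_number = mask_euler_number(mask),
    extent = area / (bw * bh), feret_diameter_max = feret,
    axis_major_length = major, axis_minor_length = minor,
    orientation = orient, perimeter = perim,
    solidity = area / hull$area,
    intensity_max = max(I), intensity_mean = mean(I),
    intensity_min = min(I), intensity_std = sqrt(m2)
  )
  mom <- c(as.vector(m), as.vector(mu), as.vector(nu), hu,
           as.vector(wm), as.vector(wmu), as.vector(wnu), whu)
  inert <- c(inertia[1, 1], inertia[1, 2], inertia[2, 2], iev[1], iev[2])
  extra <- c(wcen[1] - bb[1], wcen[2] - bb[2], hull$perimeter,
             sqrt((mu[3, 1] + mu[1, 3]) / mu[1, 1]))
  shape <- c(
    aspect_ratio = if (minor > 0) major / minor else NA_real_,
    roundness = if (major > 0) 4 * area / (pi * major^2) else NA_real_,
    compactness = perim^2 / area,
    circularity = if (perim > 0) 4 * pi * area / perim^2 else NA_real_,
    form_factor = if (perim > 0) 4 * pi * area / perim^2 else NA_real_,
    effective_diameter = 2 * sqrt(area / pi),
    convexity = if (perim > 0) hull$perimeter / perim else NA_real_
  )
  intens <- c(blur = lvar, roi_contrast = roi_contrast,
              image_contrast = image_contrast, median_intensity = med,
              modal_value = modal,
              integrated_density = mean(I) * area,
              raw_integrated_density = sum(I),
              skewness = skew, kurtosis = kurt)
  v <- c(out, mom, inert, extra, shape, intens)
  names(v) <- reg_names()
  v
}

#' Extract the 165 morphometrics for one frame
#'
#' Computes the full registry — standard region and intensity descriptors,
#' binary and intensity-weighted image moments, and the custom shape and
#' intensity formulas — on a single-component mask over a grayscale image.
#'
#' @param image Grayscale matrix.
#' @param mask Binary matrix of the same size with exactly one connected
#'   foreground component.
#' @param registry The feature registry (used to assert the contract).
#' @return A 1-row tibble with 165 feature columns in registry order.
#' @export
extract_features <- function(image, mask, registry = feature_registry()) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)))
  v <- .extract_vec(image, mask)
  stopifnot(length(v) == nrow(registry), identical(names(v), registry$name))
  tibble::as_tibble(as.list(v))
}

#' Custom intensity features for one frame
#'
#' The named intensity formulas: blur (variance of the Laplacian response
#' within the mask), ROI and full-image contrast, median intensity, modal
#' value, integrated and raw integrated density, and skewness/kurtosis of
#' the in-mask intensity distribution (0 for a flat distribution).
#' @inheritParams extract_features
#' @return 1-row tibble with 9 columns.
#' @export
compute_custom_intensity_features <- function(image, mask) {
  extract_features(image, mask)[, c("blur", "roi_contrast", "image_contrast",
                                    "median_intensity", "modal_value",
                                    "integrated_density",
                                    "raw_integrated_density",
                                    "skewness", "kurtosis")]
}

#' Custom shape features for one frame
#'
#' aspect_ratio = major/minor axis; roundness = 4·area/(π·major²);
#' circularity = form_factor = 4π·area/perimeter²; compactness =
#' perimeter²/area; effective_diameter = 2·sqrt(area/π); convexity =
#' convex perimeter / perimeter.
#' @param mask Binary single-component matrix.
#' @return 1-row tibble with 7 columns.
#' @export
compute_custom_shape_features <- function(mask) {
  extract_features(mask * 0, mask)[, c("aspect_ratio", "roundness",
                                       "compactness", "circularity",
                                       "form_factor", "effective_diameter",
                                       "convexity")]
}

#' Morphometrics table for a synthetic dataset
#'
#' Renders the requested frames (middle slice by default, or a sum- or
#' maximum-intensity z-projection), segments them (or takes the ground-truth
#' masks), applies the QC rules, and extracts the 165 features for every
#' accepted frame. Excluded loops and rejected frames yield no row.
#'
#' @param ds An `organoid_dataset`.
#' @param loops Loops to process (default: all).
#' @param projection `"none"` (middle slice), `"sum"` or `"max"` across z.
#' @param use_true_mask Use generator ground-truth masks instead of the
#'   segmenter (faster; for fixtures and benchmarks).
#' @param segmenter Segmenter passed to [segment_frame()].
#' @param working_px Segmentation working resolution; defaults to the frame
#'   size so synthetic frames are not resampled.
#' @param size_limit_px QC bounding-box limit, scaled to `working_px`
#'   (360 at a 512 working resolution).
#' @return Tibble keyed by (experiment_id, well_id, loop) with 165 feature
#'   columns; attribute `registry_version` records provenance.
#' @export
compute_morphometrics <- function(ds, loops = seq_len(ds$cfg$n_loops),
                                  projection = c("none", "sum", "max"),
                                  use_true_mask = FALSE,
                                  segmenter = default_segmenter,
                                  working_px = ds$cfg$frame_px,
                                  size_limit_px = round(360 * working_px / 512)) {
  projection <- match.arg(projection)
  reg <- feature_registry()
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(ds$wells))) {
    w <- ds$wells[i, ]
    excl <- if (is.na(w$excluded_from)) Inf else w$excluded_from
    for (loop in loops) {
      if (loop >= excl) next
      img <- if (projection == "none") {
        render_frame(ds, w$experiment_id, w$well_id, loop)
      } else {
        zs <- lapply(seq_len(ds$cfg$n_z), function(z)
          render_frame(ds, w$experiment_id, w$well_id, loop, z))
        if (projection == "sum") Reduce(`+`, zs)
        else Reduce(pmax, zs)
      }
      if (use_true_mask) {
        mask <- true_mask(ds, w$experiment_id, w$well_id, loop)
      } else {
        soft <- segment_frame(img, segmenter, working_px = working_px)
        res <- postprocess_mask(soft, dim(img), size_limit_px = size_limit_px)
        if (!res$accepted) next
        mask <- res$mask
      }
      if (sum(mask) == 0) next
      v <- .extract_vec(img, mask)
      k <- k + 1L
      rows[[k]] <- c(list(experiment_id = w$experiment_id,
                          well_id = w$well_id, loop = loop), as.list(v))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "registry_version") <- registry_version
  out
}
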