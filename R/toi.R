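# Tissue-outcome quantification: pigment area by Yen + Sauvola thresholding,
# lens areas as circles, percentile size classes, and the bin-center-distance
# diagnostic.

#' Sauvola local-threshold parameters
#'
#' @param radius Window radius in pixels (window side `2*radius+1`);
#'   default 15.
#' @param k Sensitivity constant; default 0.5.
#' @param r Dynamic-range constant; default 128 (the recommended value for
#'   8-bit images).
#' @return List of class `sauvola_params`.
#' @export
sauvola_params <- function(radius = 15L, k = 0.5, r = 128) {
  stopifnot(radius >= 1, r > 0)
  structure(list(radius = as.integer(radius), k = k, r = r),
            class = "sauvola_params")
}

#' Sauvola's local thresholding
#'
#' Per-pixel threshold `t = m * (1 + k * (s / r - 1))` with `m`, `s` the
#' mean and (population) standard deviation over the square window of side
#' `2*radius + 1` centred on the pixel, mirror-padded at the borders. A
#' pixel is foreground iff its intensity exceeds its threshold, so bright
#' structure on a dark ground is selected; invert the image first when the
#' structure of interest is dark.
#'
#' @param image 8-bit grayscale matrix.
#' @param p A [sauvola_params()].
#' @return Binary matrix (1 = foreground).
#' @export
sauvola_threshold <- function(image, p = sauvola_params()) {
  stopifnot(inherits(p, "sauvola_params"), is.matrix(image))
  w <- 2L * p$radius + 1L
  if (w > nrow(image) || w > ncol(image))
    stop("Sauvola window larger than image")
  pad <- mirror_pad(image, p$radius)
  S1 <- integral_image(pad)
  S2 <- integral_image(pad^2)
  n <- nrow(image); m <- ncol(image)
  # window sums for each original pixel
  i1 <- 1:n; i2 <- i1 + w; j1 <- 1:m; j2 <- j1 + w
  sum1 <- S1[i2, j2] - S1[i1, j2] - S1[i2, j1] + S1[i1, j1]
  sum2 <- S2[i2, j2] - S2[i1, j2] - S2[i2, j1] + S2[i1, j1]
  npx <- w * w
  mu <- sum1 / npx
  sd <- sqrt(pmax(sum2 / npx - mu^2, 0))
  thr <- mu * (1 + p$k * (sd / p$r - 1))
  (image > thr) * 1
}

#' Quantify pigment (RPE) area in a stereomicroscope-style image
#'
#' Pipeline: (1) organoid ROI by Yen's global threshold (dark side), keep
#' largest component; (2) 8-bit conversion; (3) min–max rescale of
#' intensities within the ROI to 0..255; (4) pigment is darker than the
#' surrounding tissue, so Sauvola local thresholding on the rescaled ROI
#' selects the below-threshold (darker-than-local-context) pixels as
#' pigment; (5) area = pigment pixels within the ROI x `um_per_px`^2.
#'
#' @param stereo_image Grayscale matrix containing one organoid.
#' @param um_per_px Micrometres per pixel.
#' @param p Sauvola parameters.
#' @return Tibble with `area_um2`, `area_px`, `roi_area_px`.
#' @export
quantify_rpe_area <- function(stereo_image, um_per_px = 1,
                              p = sauvola_params()) {
  img8 <- to_uint8(stereo_image)
  roi <- find_dark_roi(img8)
  roi_n <- sum(roi)
  if (roi_n == 0) stop("empty organoid ROI")
  vals <- img8[roi > 0]
  rng <- range(vals)
  if (rng[2] - rng[1] <= 0) {
    warning("flat ROI intensities; pigment area set to 0")
    return(tibble::tibble(area_um2 = 0, area_px = 0L, roi_area_px = roi_n))
  }
  sc_vals <- round((vals - rng[1]) / (rng[2] - rng[1]) * 255)
  # out-of-ROI pixels are dark (0), so windows straddling the ROI border
  # never make the rim look darker than its local context
  scaled <- matrix(0, nrow(img8), ncol(img8))
  scaled[roi > 0] <- sc_vals
  bright <- sauvola_threshold(scaled, p)
  fg <- (1 - bright) * roi                 # pigment = darker-than-local side
  area_px <- sum(fg)
  tibble::tibble(area_um2 = area_px * um_per_px^2,
                 area_px = as.integer(area_px),
                 roi_area_px = as.integer(roi_n))
}

#' Lens area from a circle radius or diameter annotation
#'
#' Lenses are measured as circles: `area = pi * (radius * um_per_px)^2`.
#'
#' @param radius_px Circle radius in pixels, or `NULL` when `diameter_points`
#'   is given.
#' @param um_per_px Micrometres per pixel.
#' @param diameter_points Optional 2x2 matrix of two points spanning the
#'   diameter.
#' @return Area in um^2.
#' @export
quantify_lens_area <- function(radius_px = NULL, um_per_px = 1,
                               diameter_points = NULL) {
  if (is.null(radius_px)) {
    stopifnot(is.matrix(diameter_points), all(dim(diameter_points) == c(2, 2)))
    radius_px <- sqrt(sum((diameter_points[1, ] - diameter_points[2, ])^2)) / 2
  }
  if (radius_px <= 0) stop("radius must be positive")
  pi * (radius_px * um_per_px)^2
}

#' Fit a circle to the bright lens disc of a frame
#'
#' Synthetic-mode helper: splits the in-mask intensities with Yen's
#' threshold, takes the largest bright component and — provided it stands
#' out against the surrounding tissue — returns its equivalent-circle
#' radius.
#' @param image Grayscale matrix.
#' @param mask Binary organoid mask.
#' @param min_contrast Minimum mean intensity excess of the candidate disc
#'   over the in-mask median for a detection (default 25).
#' @return Radius in pixels (0 when no bright disc is found).
#' @export
fit_lens_circle <- function(image, mask, min_contrast = 25) {
  # drop the soft boundary rim, whose bright ramp toward the background
  # would otherwise read as a bright structure
  mask <- (matrix(EBImage::imageData(
    EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(7, "disc"))),
    nrow(mask), ncol(mask)) > 0.5) * 1
  if (sum(mask) < 16) return(0)
  v <- image[mask > 0]
  # multilevel Yen from below: keep re-splitting the bright side until the
  # bright class is a minority (a lens occupies well under half the organoid)
  thr <- yen_threshold(matrix(v, nrow = 1))
  for (it in 1:3) {
    if (mean(v >= thr) <= 0.5) break
    t2 <- yen_threshold(matrix(v[v >= thr], nrow = 1))
    if (t2 <= thr) break
    thr <- t2
  }
  cand <- (image >= thr) * (mask > 0)
  if (sum(cand) == 0) return(0)
  biggest <- keep_largest_component(cand)
  if (mean(image[biggest > 0]) - stats::median(v) < min_contrast) return(0)
  sqrt(sum(biggest) / pi)
}

#' Size-class cutoffs from pooled positive areas
#'
#' The 33rd and 66th percentiles of the positive area measurements pooled
#' over a (training) dataset; together with class 0 for absent tissue this
#' defines the four-level outcome used as the prediction target.
#'
#' @param areas Numeric vector of areas (um^2); non-positive entries are
#'   dropped.
#' @param tissue Label stored with the cutoffs.
#' @return Tibble of class `class_cutoffs` with `tissue`, `q33`, `q66`,
#'   `source`.
#' @export
compute_class_cutoffs <- function(areas, tissue = "RPE") {
  pos <- areas[is.finite(areas) & areas > 0]
  if (length(pos) < 3) stop("need at least 3 positive areas")
  q <- stats::quantile(pos, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  out <- tibble::tibble(tissue = tissue, q33 = q[1], q66 = q[2],
                        source = "computed")
  class(out) <- c("class_cutoffs", class(out))
  out
}

#' Configure size-class cutoffs directly
#' @param q33,q66 Cutoff areas in um^2 (`0 < q33 < q66`).
#' @param tissue Label.
#' @return `class_cutoffs` tibble.
#' @export
class_cutoffs <- function(q33, q66, tissue = "RPE") {
  stopifnot(q33 > 0, q66 > q33)
  out <- tibble::tibble(tissue = tissue, q33 = q33, q66 = q66,
                        source = "configured")
  class(out) <- c("class_cutoffs", class(out))
  out
}

#' Assign the four-level size class
#'
#' Class 0 when the tissue is absent; otherwise 1 for areas up to the 33rd
#' percentile cutoff, 2 up to the 66th, 3 above (boundaries closed on the
#' lower bin).
#'
#' @param area Areas in um^2 (vectorized).
#' @param present Logical presence flags (recycled).
#' @param cutoffs A `class_cutoffs` row.
#' @return Integer classes in 0..3.
#' @export
assign_size_class <- function(area, present, cutoffs) {
  stopifnot(inherits(cutoffs, "class_cutoffs"))
  n <- max(length(area), length(present))
  area <- rep_len(area, n); present <- rep_len(present, n)
  if (any(present & (!is.finite(area) | area <= 0)))
    stop("present tissue must have a positive area")
  cls <- ifelse(!present, 0L,
         ifelse(area <= cutoffs$q33, 1L,
         ifelse(area <= cutoffs$q66, 2L, 3L)))
  as.integer(cls)
}

#' Normalized distance to the centre of the assigned size bin
#'
#' Bins are bounded by (min, q33], (q33, q66], (q66, max], with min/max
#' taken from the pooled positive areas; the distance is 0 at the bin's
#' midpoint and 1 at either edge.
#'
#' @param area Areas (um^2), class >= 1 samples only.
#' @param cls Assigned classes in 1..3.
#' @param cutoffs `class_cutoffs` row.
#' @param pooled_areas Positive areas defining the outer bin bounds.
#' @return Numeric distances in \[0, 1\].
#' @export
bin_center_distance <- function(area, cls, cutoffs, pooled_areas) {
  stopifnot(inherits(cutoffs, "class_cutoffs"), all(cls %in% 1:3))
  pos <- pooled_areas[is.finite(pooled_areas) & pooled_areas > 0]
  lo <- c(min(pos), cutoffs$q33, cutoffs$q66)
  hi <- c(cutoffs$q33, cutoffs$q66, max(pos))
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2
  out <- abs(area - ctr[cls]) / half[cls]
  if (any(out > 1 + 1e-9)) stop("area outside its assigned bin")
  pmin(out, 1)
}
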