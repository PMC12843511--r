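#' Yen's global threshold
#'
#' Maximum-correlation thresholding on the 256-bin histogram of an 8-bit
#' image. Returns the threshold intensity; the caller decides which side is
#' foreground.
#'
#' @param img Numeric matrix; values are binned on 0..255.
#' @return Threshold value (a bin center on 0..255).
#' @export
yen_threshold <- function(img) {
  v <- pmin(pmax(round(img), 0), 255)
  h <- tabulate(as.vector(v) + 1L, nbins = 256L)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p)^2))
  eps <- 1e-30
  n <- 256L
  crit <- log(pmax(P1[-n] * (1 - P1[-n]), eps)^2 /
              pmax(P1sq[-n] * P2sq[-1L], eps))
  which.max(crit) - 1L
}

# Robust organoid ROI on a dark-object-on-bright-ground 8-bit image.
# Yen's threshold occasionally latches onto a small very-dark class (debris
# speckles, pigment) below the organoid/background split; such a candidate
# is recognized because it is tiny or because its immediate surround is
# tissue-dark rather than background-bright, and the threshold is then
# recomputed on the brighter remainder (multilevel Yen).
find_dark_roi <- function(img8, max_iter = 4L) {
  t <- yen_threshold(img8)
  roi <- matrix(0, nrow(img8), ncol(img8))
  for (it in seq_len(max_iter)) {
    dark <- (img8 <= t) * 1
    if (sum(dark) == 0 || sum(dark) == length(dark)) break
    roi <- keep_largest_component(fill_holes(dark))
    if (sum(roi) >= 0.01 * length(img8)) {
      ring <- (matrix(EBImage::imageData(
        EBImage::dilate(EBImage::Image(roi), EBImage::makeBrush(7, "disc"))),
        nrow(roi), ncol(roi)) > 0.5) * 1 - roi
      bg_est <- stats::quantile(img8[img8 >= t], 0.75, names = FALSE)
      if (sum(ring) == 0 || mean(img8[ring > 0]) >= 0.75 * bg_est) break
    }
    t2 <- yen_threshold(matrix(img8[img8 >= t], nrow = 1))
    if (t2 <= t) break
    t <- t2
  }
  attr(roi, "threshold") <- t
  roi
}

default_segmenter <- function(img) {
  sm <- blur_image(img, max(1, nrow(img) / 256))
  i8 <- to_uint8(sm)
  fg <- find_dark_roi(i8)
  if (sum(fg) == 0 || sum(fg) == length(fg)) {
    out <- matrix(0, nrow(img), ncol(img))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  # Yen's cut sits close to the dark mode, placing the boundary high on the
  # blurred edge ramp; one intermeans step moves it to the ramp midpoint so
  # mask areas are resampling-stable
  t <- attr(fg, "threshold")
  t_mid <- (mean(i8[fg > 0]) + mean(i8[fg == 0])) / 2
  out <- keep_largest_component(fill_holes((i8 <= t_mid) * 1))
  if (sum(out) == 0) out <- fg
  attr(out, "threshold") <- NULL
  out
}

#' Segment one frame into a soft organoid mask
#'
#' The frame is resampled to the working resolution (area-averaging policy)
#' and passed to the segmenter, which must return a soft foreground map in
#' \[0, 1\] at that resolution. The default segmenter is classical: Gaussian
#' smoothing, Yen's global threshold (dark side = organoid), hole filling,
#' keep-largest-component; any callable obeying the same contract — e.g. a
#' trained model — can replace it.
#'
#' @param image Grayscale matrix.
#' @param segmenter Function `(image) -> soft mask`; default classical chain.
#' @param working_px Working resolution (default 512).
#' @return Soft mask matrix in \[0, 1\] at `working_px` square; attribute
#'   `flagged` is TRUE when no foreground was found.
#' @export
segment_frame <- function(image, segmenter = default_segmenter,
                          working_px = 512L) {
  stopifnot(is.matrix(image), length(image) > 0)
  work <- resize_image(image, working_px, working_px, method = "area")
  soft <- segmenter(work)
  stopifnot(is.matrix(soft), all(soft >= 0 & soft <= 1))
  soft
}

#' Post-process a soft mask into a QC'd segmentation result
#'
#' Binarizes at half of the mask's maximum, measures connected components
#' and the bounding box at the working resolution, applies the exclusion
#' rules (more than one mask, or a bounding-box side exceeding
#' `size_limit_px`, both judged at working resolution), and resamples the
#' accepted mask back to the original shape with the linear-interpolation
#' policy.
#'
#' @param soft Soft mask in \[0, 1\].
#' @param original_shape Integer `c(nrow, ncol)` of the original frame.
#' @param size_limit_px Maximum allowed bounding-box side (default 360).
#' @return A list of class `segmentation_result`: `mask` (binary, original
#'   resolution), `n_components`, `bbox_w`, `bbox_h`, `accepted`,
#'   `reject_reason` in `{"multi_mask", "too_large", "empty", "none"}`.
#' @export
postprocess_mask <- function(soft, original_shape = dim(soft),
                             size_limit_px = 360L) {
  stopifnot(all(soft >= 0 & soft <= 1))
  mx <- max(soft)
  hard <- if (mx > 0) (soft > 0.5 * mx) * 1 else soft * 0
  lab <- label_components(hard)
  n_comp <- max(lab)
  if (n_comp == 0L) {
    res <- list(mask = matrix(0, original_shape[1], original_shape[2]),
                n_components = 0L, bbox_w = 0L, bbox_h = 0L,
                accepted = FALSE, reject_reason = "empty")
    return(structure(res, class = "segmentation_result"))
  }
  idx <- which(hard > 0, arr.ind = TRUE)
  bbox_h <- diff(range(idx[, 1])) + 1L
  bbox_w <- diff(range(idx[, 2])) + 1L
  reject_reason <- if (n_comp > 1L) "multi_mask"
    else if (max(bbox_w, bbox_h) > size_limit_px) "too_large"
    else "none"
  up <- resize_image(soft, original_shape[1], original_shape[2],
                     method = "linear")
  mask <- if (max(up) > 0) (up > 0.5 * max(up)) * 1 else up * 0
  structure(list(mask = mask, n_components = as.integer(n_comp),
                 bbox_w = as.integer(bbox_w), bbox_h = as.integer(bbox_h),
                 accepted = reject_reason == "none",
                 reject_reason = reject_reason),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", ifelse(x$accepted, "accepted", "rejected"),
      " (components=", x$n_components, ", bbox=", x$bbox_w, "x", x$bbox_h,
      ", reason=", x$reject_reason, ")\n", sep = "")
  invisible(x)
}
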