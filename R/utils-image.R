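# Shared image helpers. Images are plain numeric matrices; grayscale
# intensities live on [0, 255] for 8-bit frames and [0, 1] for soft masks.

#' Resample an image to a new size
#'
#' Two policies are provided, named by behaviour: `"area"` (block averaging,
#' the policy used when going down in resolution so that mass is conserved)
#' and `"linear"` (bilinear interpolation, used when going back up).
#'
#' @param img Numeric matrix.
#' @param nrow_out,ncol_out Target size in pixels.
#' @param method `"area"` or `"linear"`.
#' @return Numeric matrix of size `nrow_out` x `ncol_out`.
#' @export
resize_image <- function(img, nrow_out, ncol_out = nrow_out,
                         method = c("area", "linear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), nrow_out >= 1, ncol_out >= 1)
  if (nrow(img) == nrow_out && ncol(img) == ncol_out) return(img)
  if (method == "area") {
    fr <- nrow(img) / nrow_out
    fc <- ncol(img) / ncol_out
    if (fr >= 1 && fc >= 1 &&
        abs(fr - round(fr)) < 1e-9 && abs(fc - round(fc)) < 1e-9) {
      # exact block mean for integer factors
      fr <- round(fr); fc <- round(fc)
      a <- array(img, c(fr, nrow_out, fc, ncol_out))
      m <- colMeans(a, dims = 1)            # nrow_out x fc x ncol_out
      m <- colMeans(aperm(m, c(2, 1, 3)), dims = 1)
      return(m)
    }
    # non-integer factors: antialias by smoothing then bilinear
    sigma <- max(c(fr, fc)) / 2
    if (sigma > 0.5) img <- blur_image(img, sigma)
  }
  out <- EBImage::resize(EBImage::Image(img), w = nrow_out, h = ncol_out)
  matrix(EBImage::imageData(out), nrow_out, ncol_out)
}

#' Gaussian blur
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns the input.
#' @return Blurred matrix.
#' @export
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- EBImage::gblur(EBImage::Image(img), sigma = sigma,
                        radius = max(3, 2 * ceiling(2 * sigma) + 1))
  matrix(EBImage::imageData(out), nrow(img), ncol(img))
}

#' Convert an image to 8-bit by linear min-max scaling
#'
#' Scales the dynamic range of the input linearly onto 0..255 and rounds
#' half-to-even (the R default), so the conversion is deterministic across
#' input dtypes. A flat image maps to 0.
#' @param img Numeric matrix.
#' @return Integer-valued matrix on 0..255.
#' @export
to_uint8 <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(img), ncol(img)))
  round((img - rng[1]) / (rng[2] - rng[1]) * 255)
}

# mirror-pad a matrix by `p` pixels on each side
mirror_pad <- function(img, p) {
  n <- nrow(img); m <- ncol(img)
  stopifnot(p < n, p < m)
  ri <- c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(m), m - seq_len(p))
  img[ri, ci]
}

# summed-area table with a leading row/col of zeros
integral_image <- function(img) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n + 1L, m + 1L)
  out[-1L, -1L] <- apply(apply(img, 2, cumsum), 1, cumsum) |> t()
  out
}

# label 4-connected components; returns integer matrix (0 = background)
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

# keep the largest connected component of a binary mask
keep_largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return(mask * 1)
  counts <- tabulate(lab[lab > 0L])
  (lab == which.max(counts)) * 1
}

# fill holes of a binary mask
fill_holes <- function(mask) {
  out <- EBImage::fillHull(EBImage::Image(mask * 1))
  matrix(as.numeric(EBImage::imageData(out) > 0.5), nrow(mask), ncol(mask))
}

# discrete 4-neighbour Laplacian with mirror padding
laplacian4 <- function(img) {
  p <- mirror_pad(img, 1L)
  n <- nrow(img); m <- ncol(img)
  ctr <- p[2:(n + 1), 2:(m + 1)]
  p[1:n, 2:(m + 1)] + p[3:(n + 2), 2:(m + 1)] +
    p[2:(n + 1), 1:m] + p[2:(n + 1), 3:(m + 2)] - 4 * ctr
}

# variance of Laplacian response inside the mask (focus/blur metric)
laplacian_variance <- function(img, mask = NULL) {
  lp <- laplacian4(img)
  v <- if (is.null(mask)) as.vector(lp) else lp[mask > 0]
  if (length(v) < 2) return(0)
  stats::var(v)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ix) s <- (s * 1103515245 + as.double(k) * 12820163 + 12345) %% 2147483647
  as.integer(s)
}
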