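#' Convert an image to 8-bit grayscale
#'
#' Color input is collapsed with ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); already-gray input passes through
#' unchanged.
#'
#' @param image A `vein_image` (1- or 3-channel) or a plain matrix/array.
#' @return A single-channel `vein_image` at stage `"gray"`.
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "vein_image")) unclass_image(image) else image
  if (is.matrix(px)) {
    return(vein_image(px, stage = "gray"))
  }
  if (is.array(px) && length(dim(px)) == 3L && dim(px)[3] == 3L) {
    g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    return(vein_image(g, stage = "gray"))
  }
  stop("unsupported channel count: expected 1 or 3 channels", call. = FALSE)
}

# Sobel gradients with replicate padding. Returns list(gx, gy).
sobel_gradients <- function(px) {
  h <- nrow(px); w <- ncol(px)
  up    <- px[c(1, seq_len(h - 1)), , drop = FALSE]
  down  <- px[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  shl <- function(m) m[, c(1, seq_len(w - 1)), drop = FALSE]   # value to the left
  shr <- function(m) m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  gx <- (shr(up) + 2 * shr(px) + shr(down)) - (shl(up) + 2 * shl(px) + shl(down))
  gy <- (shl(down) + 2 * down + shr(down)) - (shl(up) + 2 * up + shr(up))
  list(gx = gx, gy = gy)
}

# Otsu threshold on a numeric vector/matrix via EBImage, on the values' own
# range. Returns the threshold on the input scale.
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  hi <- max(v)
  if (hi <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(v / hi, dim = c(length(v), 1)), levels = 256) * hi
}

#' Crop a gray image to the finger region of interest
#'
#' Finds the finger contour as the largest connected component of pixels
#' whose Sobel gradient magnitude exceeds the Otsu threshold, then crops to
#' the minimum and maximum column (abscissa) of that component, inclusive.
#' The full row range is retained.
#'
#' @param image A `vein_image` at stage `"gray"`.
#' @return The cropped `vein_image` at stage `"roi"`.
#' @export
extract_roi <- function(image) {
  px <- as_pixel_matrix(image)
  g <- sobel_gradients(px)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) stop("no contour found: image has no gradient", call. = FALSE)
  edge <- mag > otsu_threshold(mag)
  if (!any(edge)) stop("no contour found above threshold", call. = FALSE)
  lab <- EBImage::bwlabel(edge * 1)
  counts <- tabulate(lab[lab > 0])
  biggest <- which.max(counts)
  cols <- which(apply(lab == biggest, 2, any))
  vein_image(px[, min(cols):max(cols), drop = FALSE], stage = "roi")
}

# Bilinear sampling of matrix `px` at fractional 1-based coordinates,
# clamped at the borders (edge replication).
bilinear_sample <- function(px, xq, yq) {
  h <- nrow(px); w <- ncol(px)
  xq <- pmin(pmax(xq, 1), w); yq <- pmin(pmax(yq, 1), h)
  x0 <- pmin(floor(xq), w - 1); y0 <- pmin(floor(yq), h - 1)
  fx <- xq - x0; fy <- yq - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- px[i00]; v01 <- px[i00 + h]
  v10 <- px[i00 + 1]; v11 <- px[i00 + h + 1]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Resize an image to the canonical 96 x 64 frame
#'
#' Bilinear interpolation with pixel-center alignment: output pixel center
#' `(i + 0.5)` maps to input coordinate `(i + 0.5) * size_in / size_out`,
#' so constant images stay constant and the 96 x 64 identity is exact.
#'
#' @param image A `vein_image` (stage `"roi"`, or `"gray"` when ROI is
#'   bypassed).
#' @param width,height Target size in pixels (default 96 x 64).
#' @return A `vein_image` at stage `"size_norm"`.
#' @export
normalize_size <- function(image, width = 96L, height = 64L) {
  px <- as_pixel_matrix(image)
  if (nrow(px) < 2 || ncol(px) < 2) {
    stop("degenerate input: both dimensions must be >= 2", call. = FALSE)
  }
  xq <- (seq_len(width) - 0.5) * ncol(px) / width + 0.5
  yq <- (seq_len(height) - 0.5) * nrow(px) / height + 0.5
  out <- matrix(bilinear_sample(px, rep(xq, each = height), rep(yq, times = width)),
                nrow = height, ncol = width)
  vein_image(out, stage = "size_norm")
}

#' Normalize the gray-level distribution
#'
#' The default, histogram equalization, remaps intensities through the
#' empirical CDF so the output histogram is approximately uniform over
#' 0--255; the mapping is monotone, and constant images pass through
#' unchanged. `method = "standardize"` instead centers to mean 127.5 and
#' sd 50, clipped to \[0, 255\].
#'
#' @param image A `vein_image` at stage `"size_norm"` (or earlier).
#' @param method `"equalize"` (default) or `"standardize"`.
#' @return A `vein_image` at stage `"gray_norm"`.
#' @export
normalize_gray <- function(image, method = c("equalize", "standardize")) {
  method <- match.arg(method)
  px <- as_pixel_matrix(image)
  n <- length(px)
  if (method == "standardize") {
    s <- stats::sd(px)
    out <- if (s == 0) px else (px - mean(px)) / s * 50 + 127.5
    return(vein_image(matrix(pmin(pmax(out, 0), 255), nrow(px), ncol(px)),
                      stage = "gray_norm"))
  }
  lev <- pmin(floor(px), 255)            # 256 integer levels
  counts <- tabulate(lev + 1, nbins = 256)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min == n) {                    # constant image: no spread to equalize
    return(vein_image(px, stage = "gray_norm"))
  }
  map <- (cdf - cdf_min) / (n - cdf_min) * 255
  out <- matrix(map[lev + 1], nrow(px), ncol(px))
  vein_image(out, stage = "gray_norm")
}

#' Run the full preprocessing chain on one image
#'
#' Gray conversion, Sobel-contour ROI extraction, bilinear resize to
#' 96 x 64 and gray normalization, in that order. `skip_roi = TRUE` bypasses
#' contour detection, which is appropriate for synthetic images that have no
#' finger silhouette.
#'
#' @param image A `vein_image` or raw matrix/array.
#' @param skip_roi Bypass ROI extraction (default `FALSE`).
#' @param gray_norm Gray normalization method, see [normalize_gray()].
#' @return A 96 x 64 `vein_image` at stage `"gray_norm"`.
#' @export
preprocess_image <- function(image, skip_roi = FALSE,
                             gray_norm = c("equalize", "standardize")) {
  img <- to_grayscale(image)
  if (!skip_roi) img <- extract_roi(img)
  img <- normalize_size(img)
  normalize_gray(img, method = match.arg(gray_norm))
}

#' Preprocess every image of a dataset manifest
#'
#' @param dataset Manifest tibble with an `image` list column
#'   ([generate_dataset()] / [read_dataset()]).
#' @inheritParams preprocess_image
#' @return The manifest with `image` replaced by preprocessed images.
#' @export
preprocess_dataset <- function(dataset, skip_roi = FALSE,
                               gray_norm = c("equalize", "standardize")) {
  gray_norm <- match.arg(gray_norm)
  dataset$image <- purrr::map(dataset$image, preprocess_image,
                              skip_roi = skip_roi, gray_norm = gray_norm)
  dataset
}
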