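#' Configuration of the spatial-pyramid descriptors
#'
#' Holds the bins-per-cell and maximum pyramid level of each descriptor
#' block. At level `l` the image is split into a `2^l x 2^l` grid, so a
#' descriptor with `K` bins and levels `0..L` has length
#' `K * sum(4^(0:L))`. The defaults (bins 4/8/4, levels 2/2/3) give the
#' canonical block lengths 84 (PHG), 168 (PHT) and 340 (PHOG), 592 in total.
#'
#' @param k_gray Gray-histogram bins per cell (PHG), default 4.
#' @param k_tex Texture bins per cell (PHT): one per LBP bit, fixed at 8 in
#'   the canonical setup.
#' @param k_orient Orientation bins per cell over `[0, 180)` degrees (PHOG),
#'   default 4.
#' @param l_gray,l_tex,l_orient Maximum pyramid level of each block
#'   (defaults 2, 2, 3).
#' @param norm Feature normalization: `"sum"` scales each descriptor block
#'   of each image to sum to unity; `"minmax"` instead rescales each feature
#'   to `[0, 1]` by its min/max over a training set (applied at table level,
#'   see [extract_features()]).
#' @param phog_level_weights Optional numeric vector of per-level weights
#'   for the PHOG block (length `l_orient + 1`); uniform when `NULL`.
#' @return A `pyramid_config` list.
#' @export
pyramid_config <- function(k_gray = 4L, k_tex = 8L, k_orient = 4L,
                           l_gray = 2L, l_tex = 2L, l_orient = 3L,
                           norm = c("sum", "minmax"),
                           phog_level_weights = NULL) {
  stopifnot(k_gray >= 1, k_tex >= 1, k_orient >= 1,
            l_gray >= 0, l_tex >= 0, l_orient >= 0)
  if (!is.null(phog_level_weights)) {
    stopifnot(length(phog_level_weights) == l_orient + 1,
              all(phog_level_weights > 0))
  }
  structure(
    list(k_gray = as.integer(k_gray), k_tex = as.integer(k_tex),
         k_orient = as.integer(k_orient),
         l_gray = as.integer(l_gray), l_tex = as.integer(l_tex),
         l_orient = as.integer(l_orient),
         norm = match.arg(norm), phog_level_weights = phog_level_weights),
    class = "pyramid_config")
}

pyramid_length <- function(k, l) as.integer(k * sum(4^(0:l)))

#' @export
print.pyramid_config <- function(x, ...) {
  cat(sprintf(
    "<pyramid_config> PHG %d bins x levels 0..%d (%d) | PHT %d x 0..%d (%d) | PHOG %d x 0..%d (%d) | total %d, norm '%s'\n",
    x$k_gray, x$l_gray, pyramid_length(x$k_gray, x$l_gray),
    x$k_tex, x$l_tex, pyramid_length(x$k_tex, x$l_tex),
    x$k_orient, x$l_orient, pyramid_length(x$k_orient, x$l_orient),
    pyramid_length(x$k_gray, x$l_gray) + pyramid_length(x$k_tex, x$l_tex) +
      pyramid_length(x$k_orient, x$l_orient), x$norm))
  invisible(x)
}

# Cell boundaries for a 2^level grid over n pixels: i * n / 2^level rounded
# half-up (floor(x + 0.5)), so a 97-px side at level 1 splits as {49, 48}.
grid_breaks <- function(n, level) {
  g <- 2^level
  floor((0:g) * n / g + 0.5)
}

#' Partition an image into the cells of one pyramid level
#'
#' Level `l` splits the image into a `2^l x 2^l` grid; cell boundaries fall
#' at `round(i * size / 2^l)` so non-divisible sizes give near-equal cells
#' deterministically. Cells are returned in row-major order.
#'
#' @param image A `vein_image` or numeric matrix.
#' @param level Pyramid level, >= 0.
#' @return List of `4^level` matrices.
#' @export
grid_partition <- function(image, level) {
  px <- if (inherits(image, "vein_image")) as_pixel_matrix(image) else image
  g <- 2^level
  if (nrow(px) < g || ncol(px) < g) {
    stop(sprintf("image %d x %d too small for level %d (needs >= %d px per side)",
                 ncol(px), nrow(px), level, g), call. = FALSE)
  }
  bx <- grid_breaks(ncol(px), level)
  by <- grid_breaks(nrow(px), level)
  cells <- vector("list", g * g)
  for (r in seq_len(g)) for (cc in seq_len(g)) {
    cells[[(r - 1) * g + cc]] <-
      px[(by[r] + 1):by[r + 1], (bx[cc] + 1):bx[cc + 1], drop = FALSE]
  }
  cells
}

# 1-based gray bin per pixel: equal-width bins of 256/K over [0, 255],
# last bin right-closed.
gray_bin <- function(v, k) pmin(floor(v / (256 / k)) + 1, k)

#' Gray histogram of a cell
#'
#' Counts pixels per equal-width intensity bin over \[0, 255\] (bin width
#' `256/K`, last bin closed at 255); the counts sum to the cell area.
#'
#' @param cell Numeric matrix of intensities in \[0, 255\].
#' @param k_gray Number of bins.
#' @return Integer count vector of length `k_gray`.
#' @export
gray_histogram <- function(cell, k_gray = 4L) {
  tabulate(gray_bin(as.numeric(cell), k_gray), nbins = k_gray)
}

# LBP bit planes for the whole image: h x w x 8 array, bit_i = 1 iff
# center > neighbor_i, neighbors clockwise from top-left, replicate padding.
lbp_offsets <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                     c(1, 1), c(1, 0), c(1, -1), c(0, -1))

lbp_planes <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- array(0L, c(h, w, 8L))
  for (b in 1:8) {
    dy <- lbp_offsets[b, 1]; dx <- lbp_offsets[b, 2]
    rows <- pmin(pmax(seq_len(h) + dy, 1), h)
    cols <- pmin(pmax(seq_len(w) + dx, 1), w)
    out[, , b] <- (px > px[rows, cols, drop = FALSE]) * 1L
  }
  out
}

#' LBP code of one pixel
#'
#' Eight binary comparisons against the 8-neighborhood, ordered clockwise
#' from the top-left neighbor: bit `i` is 1 iff the center intensity is
#' strictly greater than neighbor `i` (so a pixel brighter than all its
#' neighbors codes as all ones, and constant regions code as all zeros).
#' Borders use replicate padding.
#'
#' @param image A `vein_image` or numeric matrix.
#' @param x,y Pixel column and row (1-based).
#' @return Integer vector of 8 bits.
#' @export
lbp_code <- function(image, x, y) {
  px <- if (inherits(image, "vein_image")) as_pixel_matrix(image) else image
  h <- nrow(px); w <- ncol(px)
  stopifnot(x >= 1, x <= w, y >= 1, y <= h)
  vapply(1:8, function(b) {
    ny <- min(max(y + lbp_offsets[b, 1], 1), h)
    nx <- min(max(x + lbp_offsets[b, 2], 1), w)
    as.integer(px[y, x] > px[ny, nx])
  }, integer(1))
}

#' LBP bit histogram of a set of codes
#'
#' The texture statistic keeps the 8 LBP bits as a vector (rather than
#' collapsing them to a 0--255 integer): the cell histogram is the
#' componentwise sum of the per-pixel bit vectors.
#'
#' @param cell_codes Matrix with 8 columns (one row per pixel) or a list of
#'   8-bit vectors.
#' @return Integer vector of length 8.
#' @export
lbp_histogram <- function(cell_codes) {
  if (is.list(cell_codes)) cell_codes <- do.call(rbind, cell_codes)
  stopifnot(ncol(cell_codes) == 8)
  as.integer(colSums(cell_codes))
}

#' Sobel edge map with orientation
#'
#' Computes Sobel gradient magnitude and unsigned orientation (degrees in
#' `[0, 180)`) per pixel, and a binary edge support from an Otsu threshold
#' on the magnitude. Constant images yield empty support.
#'
#' @param image A `vein_image` or numeric matrix.
#' @return List with matrices `magnitude`, `orientation` and logical
#'   `support`.
#' @export
edge_map <- function(image) {
  px <- if (inherits(image, "vein_image")) as_pixel_matrix(image) else image
  g <- sobel_gradients(px)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ori <- (atan2(g$gy, g$gx) * 180 / pi) %% 180
  support <- if (max(mag) == 0) {
    matrix(FALSE, nrow(px), ncol(px))
  } else {
    mag > otsu_threshold(mag)
  }
  list(magnitude = mag, orientation = ori, support = support)
}

#' Histogram of oriented gradients for one cell
#'
#' Magnitude-weighted hard votes of the cell's edge-support pixels into
#' `k_orient` equal orientation bins over `[0, 180)` degrees (edges at
#' `180/K` multiples). Cells without edge pixels give a zero vector.
#'
#' @param magnitude,orientation,support Matrices for the cell, as produced
#'   by [edge_map()] (subset to the cell).
#' @param k_orient Number of orientation bins.
#' @return Numeric vector of length `k_orient`.
#' @export
hog_histogram <- function(magnitude, orientation, support, k_orient = 4L) {
  idx <- which(support)
  out <- numeric(k_orient)
  if (length(idx) == 0) return(out)
  bin <- pmin(floor(orientation[idx] / (180 / k_orient)) + 1, k_orient)
  for (b in seq_len(k_orient)) out[b] <- sum(magnitude[idx][bin == b])
  out
}

# Fast pyramid accumulator: V is an (h*w) x K matrix of per-pixel bin
# contributions in column-major pixel order; returns the concatenation over
# levels 0..L of per-cell column sums, cells row-major, bins fastest.
accumulate_pyramid <- function(V, h, w, l_max, level_weights = NULL) {
  blocks <- vector("list", l_max + 1)
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  for (l in 0:l_max) {
    g <- 2^l
    if (h < g || w < g) {
      stop(sprintf("image %d x %d too small for level %d", w, h, l), call. = FALSE)
    }
    cx <- findInterval(xs - 1, grid_breaks(w, l), rightmost.closed = TRUE)
    cy <- findInterval(ys - 1, grid_breaks(h, l), rightmost.closed = TRUE)
    cell <- (cy - 1) * g + cx                       # row-major cell id
    m <- rowsum(V, cell)                            # sorted by cell id
    wt <- if (is.null(level_weights)) 1 else level_weights[l + 1]
    blocks[[l + 1]] <- as.numeric(t(m)) * wt
  }
  unlist(blocks)
}

descriptor_layout <- function(descriptor, k, l_max) {
  purrr::map_dfr(0:l_max, function(l) {
    g <- 2^l
    tidyr::expand_grid(level = l, cell_row = seq_len(g), cell_col = seq_len(g),
                       bin = seq_len(k))
  }) |>
    dplyr::mutate(descriptor = descriptor, .before = 1)
}

#' Extract one spatial-pyramid descriptor from an image
#'
#' Computes the chosen per-pixel statistic once on the full image, bins it
#' into the cells of every pyramid level `0..L` (cells in row-major order,
#' bins fastest), concatenates the per-cell histograms and, under the
#' default `"sum"` normalization, scales the whole block to sum to unity
#' (blocks that are identically zero are left at zero).
#'
#' @param image A preprocessed `vein_image` or numeric matrix (0--255).
#' @param statistic `"gray"` (PHG), `"texture"` (PHT, LBP bits) or
#'   `"orientation"` (PHOG).
#' @param k Bins per cell.
#' @param l_max Maximum pyramid level.
#' @param normalize Scale the block to sum to unity (default `TRUE`).
#' @param level_weights Optional per-level weights (orientation block).
#' @return Numeric vector of length `k * sum(4^(0:l_max))` with a `layout`
#'   attribute (tibble: descriptor, level, cell_row, cell_col, bin).
#' @export
pyramid_descriptor <- function(image,
                               statistic = c("gray", "texture", "orientation"),
                               k, l_max, normalize = TRUE,
                               level_weights = NULL) {
  statistic <- match.arg(statistic)
  px <- if (inherits(image, "vein_image")) as_pixel_matrix(image) else image
  h <- nrow(px); w <- ncol(px)
  V <- switch(statistic,
    gray = {
      bin <- gray_bin(as.numeric(px), k)
      V <- matrix(0, h * w, k)
      V[cbind(seq_len(h * w), bin)] <- 1
      V
    },
    texture = {
      stopifnot(k == 8L)
      matrix(lbp_planes(px), nrow = h * w, ncol = 8)
    },
    orientation = {
      em <- edge_map(px)
      bin <- pmin(floor(as.numeric(em$orientation) / (180 / k)) + 1, k)
      V <- matrix(0, h * w, k)
      idx <- which(as.logical(em$support))
      if (length(idx)) {
        V[cbind(idx, bin[idx])] <- as.numeric(em$magnitude)[idx]
      }
      V
    })
  v <- accumulate_pyramid(V, h, w, l_max, level_weights)
  if (normalize && sum(v) > 0) v <- v / sum(v)
  attr(v, "layout") <- descriptor_layout(
    c(gray = "phg", texture = "pht", orientation = "phog")[[statistic]], k, l_max)
  v
}

#' The PHGTOG descriptor of one image
#'
#' Concatenates the gray (PHG), texture (PHT) and oriented-gradient (PHOG)
#' pyramid blocks; with the default configuration the result has length
#' 84 + 168 + 340 = 592. Under `"sum"` normalization each block sums to
#' unity independently.
#'
#' @param image A preprocessed 96 x 64 `vein_image` (any size >= the finest
#'   grid is accepted).
#' @param config A [pyramid_config()].
#' @return Numeric feature vector with a `layout` attribute.
#' @export
phgtog <- function(image, config = pyramid_config()) {
  norm <- config$norm == "sum"
  phg <- pyramid_descriptor(image, "gray", config$k_gray, config$l_gray,
                            normalize = norm)
  pht <- pyramid_descriptor(image, "texture", config$k_tex, config$l_tex,
                            normalize = norm)
  phog <- pyramid_descriptor(image, "orientation", config$k_orient,
                             config$l_orient, normalize = norm,
                             level_weights = config$phog_level_weights)
  v <- c(phg, pht, phog)
  attr(v, "layout") <- dplyr::bind_rows(attr(phg, "layout"),
                                        attr(pht, "layout"),
                                        attr(phog, "layout")) |>
    dplyr::mutate(index = dplyr::row_number())
  v
}

#' Extract PHGTOG features for a whole dataset
#'
#' @param dataset Preprocessed manifest tibble with an `image` list column.
#' @param config A [pyramid_config()]. With `norm = "minmax"`, per-image
#'   block normalization is skipped and each feature column is instead
#'   rescaled to `[0, 1]` by its min/max across this table (columns with
#'   zero range are left at 0).
#' @return A feature tibble: `subject_id`, `sample_id`, `session`, then
#'   feature columns `f_0 ... f_{p-1}`; the block layout and config ride
#'   along as attributes `layout` and `config`.
#' @export
extract_features <- function(dataset, config = pyramid_config()) {
  feats <- purrr::map(dataset$image, phgtog, config = config)
  layout <- attr(feats[[1]], "layout")
  X <- do.call(rbind, feats)
  if (config$norm == "minmax") {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- 1
    X <- sweep(sweep(X, 2, lo), 2, rng, `/`)
  }
  colnames(X) <- paste0("f_", seq_len(ncol(X)) - 1)
  out <- dplyr::bind_cols(
    dataset[intersect(c("subject_id", "sample_id", "session"), names(dataset))],
    tibble::as_tibble(X))
  attr(out, "layout") <- layout
  attr(out, "config") <- config
  out
}

#' Feature matrix and labels of a feature table
#' @param features Tibble from [extract_features()].
#' @return `feature_matrix()`: numeric matrix (one row per image);
#'   `feature_labels()`: integer vector of subject ids.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[grep("^f_", names(features))])
}

#' @rdname feature_matrix
#' @export
feature_labels <- function(features) features$subject_id

#' Persist / reload a feature table
#'
#' The table goes to CSV (one row per image: ids then `f_0...`), the
#' pyramid configuration and block layout to a JSON sidecar
#' `<path>.layout.json`; the round-trip is bit-exact for the values
#' serialized at full precision.
#'
#' @param features Feature tibble.
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  fcols <- grep("^f_", names(df))
  for (j in fcols) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(config = unclass(attr(features, "config")),
               layout = attr(features, "layout"))
  jsonlite::write_json(side, paste0(path, ".layout.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fcols <- grep("^f_", names(df))
  for (j in fcols) df[[j]] <- as.numeric(df[[j]])
  out <- tibble::as_tibble(df)
  side <- jsonlite::read_json(paste0(path, ".layout.json"), simplifyVector = TRUE)
  cfg <- side$config
  attr(out, "config") <- pyramid_config(cfg$k_gray, cfg$k_tex, cfg$k_orient,
                                        cfg$l_gray, cfg$l_tex, cfg$l_orient,
                                        norm = cfg$norm)
  attr(out, "layout") <- tibble::as_tibble(side$layout)
  out
}
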