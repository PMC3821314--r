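#' Raster image carrier for the recognition pipeline
#'
#' A `vein_image` is a numeric matrix of intensities on the 0--255 scale
#' (rows are image rows, columns are image columns) plus a `stage` tag
#' recording where in the preprocessing chain the image sits. Stages move
#' only forward along `raw -> gray -> roi -> size_norm -> gray_norm`.
#'
#' @param pixels Numeric matrix (gray) or height x width x 3 array (color).
#' @param stage One of `"raw"`, `"gray"`, `"roi"`, `"size_norm"`, `"gray_norm"`.
#' @return A `vein_image` object.
#' @export
vein_image <- function(pixels, stage = "raw") {
  stage <- match.arg(stage, .vein_stages)
  if (is.matrix(pixels)) {
    px <- pixels
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    px <- pixels
  } else {
    stop("`pixels` must be a matrix or a 3-d array", call. = FALSE)
  }
  if (any(dim(px)[1:2] < 1L)) stop("image dimensions must be >= 1", call. = FALSE)
  rng <- range(px)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    stop("intensities must be finite and in [0, 255]", call. = FALSE)
  }
  structure(px, stage = stage, class = c("vein_image", class(px)))
}

.vein_stages <- c("raw", "gray", "roi", "size_norm", "gray_norm")

#' @export
print.vein_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vein_image> %d x %d px, stage '%s', intensity [%.1f, %.1f]\n",
              d[2], d[1], image_stage(x), min(x), max(x)))
  invisible(x)
}

#' Query the preprocessing stage of an image
#' @param image A `vein_image` (a bare matrix counts as stage `"raw"`).
#' @return Stage string.
#' @export
image_stage <- function(image) attr(image, "stage") %||% "raw"

# stamp a new stage, enforcing forward-only transitions
set_stage <- function(image, stage) {
  from <- match(image_stage(image), .vein_stages)
  to <- match(stage, .vein_stages)
  if (to < from) {
    stop(sprintf("stage may not move backwards ('%s' -> '%s')",
                 .vein_stages[from], stage), call. = FALSE)
  }
  vein_image(unclass_image(image), stage = stage)
}

unclass_image <- function(image) {
  attr(image, "stage") <- NULL
  class(image) <- setdiff(class(image), "vein_image")
  image
}

as_pixel_matrix <- function(image) {
  px <- unclass_image(image)
  if (!is.matrix(px)) stop("expected a single-channel image", call. = FALSE)
  px
}

#' Read an image file into a `vein_image`
#'
#' PNG files are read natively; intensities are rescaled from `[0, 1]` to the
#' 0--255 working scale. Gray, gray+alpha, RGB and RGBA layouts are accepted
#' (alpha is dropped).
#'
#' @param path Path to a PNG file.
#' @return A `vein_image` at stage `"raw"` (3-channel) or `"gray"` (1-channel).
#' @export
read_vein_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] %in% c(2L, 4L)) {
    px <- px[, , seq_len(dim(px)[3] - 1L), drop = FALSE]
  }
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  px <- px * 255
  vein_image(px, stage = if (is.matrix(px)) "gray" else "raw")
}

#' Write a `vein_image` to a PNG file
#' @param image A `vein_image` or numeric matrix on the 0--255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vein_image <- function(image, path) {
  px <- unclass_image(image) / 255
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
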