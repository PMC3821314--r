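#' Specification of a synthetic finger-vein dataset
#'
#' Bundles the knobs of the synthetic generator: how many subjects, how many
#' samples each, image geometry, within-class jitter (a single global rigid
#' transform per sample, emulating small finger shifts and rotations between
#' captures), additive sensor noise, and the RNG seed. An identical spec
#' (including seed) always yields a bit-identical dataset.
#'
#' @param n_subjects Number of distinct fingers (classes), >= 1.
#' @param samples_per_subject Images per subject, >= 1.
#' @param image_size `c(width, height)` in pixels. The default 96 x 64 matches
#'   the size the preprocessing chain normalizes to, so synthetic images can
#'   bypass ROI extraction.
#' @param jitter_px Maximum absolute translation per sample, pixels, >= 0.
#' @param jitter_deg Maximum absolute rotation per sample, degrees, >= 0.
#' @param noise_sigma Standard deviation of additive Gaussian intensity noise
#'   (0--255 scale), >= 0.
#' @param seed Integer RNG seed.
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_subjects, samples_per_subject,
                         image_size = c(96, 64),
                         jitter_px = 3, jitter_deg = 3, noise_sigma = 10,
                         seed = 1L) {
  if (n_subjects < 1 || samples_per_subject < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (length(image_size) != 2L || any(image_size < 8)) {
    stop("`image_size` must be c(width, height) with both >= 8", call. = FALSE)
  }
  if (jitter_px < 0 || jitter_deg < 0 || noise_sigma < 0) {
    stop("jitter and noise parameters must be >= 0", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         samples_per_subject = as.integer(samples_per_subject),
         image_size = as.integer(image_size),
         jitter_px = jitter_px, jitter_deg = jitter_deg,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "dataset_spec")
}

# Deterministic substream mixing: keeps every intermediate below 2^53 so the
# arithmetic is exact in doubles, and the result below 2^31 for set.seed().
mix_seed <- function(...) {
  s <- 0
  for (x in c(...)) s <- (s * 69069 + as.numeric(x) + 1) %% 2147483647
  as.integer(s)
}

#' Generate a per-subject vein template
#'
#' Each subject is a fixed set of 3--6 random quadratic Bezier curves (the
#' "veins"), stroked at render time with a Gaussian cross-profile. Templates
#' are drawn from a substream keyed by `(seed, subject_id)`, so adding
#' subjects never perturbs existing ones and distinct subjects get distinct
#' curve sets with overwhelming probability.
#'
#' @param subject_id Integer subject label.
#' @param seed Integer dataset seed.
#' @param image_size `c(width, height)` in pixels.
#' @return A `vein_template` with fields `subject_id`, `ridge_set` (list of
#'   3 x 2 control-point matrices, columns x and y, 0-based image
#'   coordinates), `ridge_width` (Gaussian profile sigma, px), `ridge_depth`
#'   (intensity drop below background) and `image_size`.
#' @export
make_template <- function(subject_id, seed, image_size = c(96, 64)) {
  w <- image_size[1]; h <- image_size[2]
  withr::local_seed(mix_seed(seed, subject_id))
  n_ridges <- sample(3:6, 1)
  ridge_set <- lapply(seq_len(n_ridges), function(i) {
    # veins run roughly along the finger axis (x), spread across rows
    y0 <- stats::runif(1, 0.1 * h, 0.9 * h)
    p0 <- c(stats::runif(1, 0, 0.15 * w), y0)
    p2 <- c(stats::runif(1, 0.85 * w, w - 1), y0 + stats::rnorm(1, 0, 0.15 * h))
    p1 <- (p0 + p2) / 2 + c(stats::rnorm(1, 0, 0.1 * w), stats::rnorm(1, 0, 0.25 * h))
    cp <- rbind(p0, p1, p2)
    cp[, 1] <- pmin(pmax(cp[, 1], 0), w - 1)
    cp[, 2] <- pmin(pmax(cp[, 2], 0), h - 1)
    dimnames(cp) <- list(c("p0", "p1", "p2"), c("x", "y"))
    cp
  })
  structure(
    list(subject_id = as.integer(subject_id),
         ridge_set = ridge_set,
         ridge_width = stats::runif(1, 1.5, 3),
         ridge_depth = stats::runif(1, 70, 130),
         image_size = as.integer(image_size)),
    class = "vein_template")
}

bezier_points <- function(cp, n = 64L) {
  t <- seq(0, 1, length.out = n)
  b <- cbind((1 - t)^2, 2 * t * (1 - t), t^2)
  b %*% cp
}

#' Render one sample image from a template
#'
#' Draws the template's ridges as dark curvilinear strokes (background minus
#' `ridge_depth`, Gaussian cross-profile of sigma `ridge_width`) on a bright
#' background, after applying a single global rigid transform (rotation about
#' the image center, then translation) sampled uniformly within the jitter
#' bounds, then adds Gaussian intensity noise and clips to \[0, 255\]. The
#' rigid transform is applied to the ridge control points in continuous
#' coordinates, which is equivalent to rigidly warping the rendered image but
#' avoids a second resampling pass. With zero jitter and zero noise, renders
#' are pixel-identical across calls.
#'
#' @param template A `vein_template`.
#' @param jitter_px,jitter_deg Maximum absolute translation (px) / rotation
#'   (degrees) sampled per call.
#' @param noise_sigma Additive Gaussian noise sd (0--255 scale).
#' @param seed Integer seed for the per-sample jitter/noise stream.
#' @param background Background intensity (default 200).
#' @return A `vein_image` at stage `"gray"`.
#' @export
render_sample <- function(template, jitter_px = 0, jitter_deg = 0,
                          noise_sigma = 0, seed = 1L, background = 200) {
  w <- template$image_size[1]; h <- template$image_size[2]
  withr::local_seed(mix_seed(seed, template$subject_id))
  dx <- stats::runif(1, -jitter_px, jitter_px)
  dy <- stats::runif(1, -jitter_px, jitter_px)
  th <- stats::runif(1, -jitter_deg, jitter_deg) * pi / 180
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- do.call(rbind, lapply(template$ridge_set, bezier_points))
  pts <- sweep(pts, 2, ctr) %*% t(rot)
  pts <- sweep(pts, 2, ctr + c(dx, dy), `+`)

  xs <- rep(0:(w - 1), each = h)   # column-major pixel order
  ys <- rep(0:(h - 1), times = w)
  d2 <- rep(Inf, w * h)
  for (k in seq_len(nrow(pts))) {
    dk <- (xs - pts[k, 1])^2 + (ys - pts[k, 2])^2
    d2 <- pmin(d2, dk)
  }
  depth <- template$ridge_depth * exp(-d2 / (2 * template$ridge_width^2))
  px <- background - depth
  if (noise_sigma > 0) px <- px + stats::rnorm(w * h, 0, noise_sigma)
  px <- matrix(pmin(pmax(px, 0), 255), nrow = h, ncol = w)
  vein_image(px, stage = "gray")
}

#' Generate a labelled synthetic dataset
#'
#' Renders `n_subjects * samples_per_subject` images with per-sample jitter
#' and noise drawn from substreams keyed by `(seed, subject_id, sample_id)`,
#' so the dataset is bit-identical under the same spec and individual
#' subjects are reproducible in isolation.
#'
#' @param spec A [dataset_spec()].
#' @return A tibble manifest with columns `subject_id`, `sample_id`,
#'   `session` (earlier two-thirds of samples are session 1, the rest
#'   session 2) and `image` (list column of `vein_image`).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "dataset_spec")) stop("`spec` must be a dataset_spec", call. = FALSE)
  m <- spec$samples_per_subject
  session_split <- ceiling(2 * m / 3)
  grid <- tidyr::expand_grid(subject_id = seq_len(spec$n_subjects),
                             sample_id = seq_len(m))
  grid$session <- ifelse(grid$sample_id <= session_split, 1L, 2L)
  grid$image <- purrr::map2(grid$subject_id, grid$sample_id, function(sid, k) {
    tpl <- make_template(sid, spec$seed, spec$image_size)
    render_sample(tpl,
                  jitter_px = spec$jitter_px, jitter_deg = spec$jitter_deg,
                  noise_sigma = spec$noise_sigma,
                  seed = mix_seed(spec$seed, 1000 + k))
  })
  tibble::new_tibble(grid, spec = spec, class = "vein_dataset")
}

#' Write a dataset to disk as a PNG tree plus manifest
#'
#' Images land in `<root>/<subject_id>/<sample_id>.png`; a `manifest.csv`
#' with columns `path,subject_id,session` indexes them. This layout is the
#' pipeline's canonical on-disk input.
#'
#' @param dataset A manifest tibble from [generate_dataset()].
#' @param root Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    d <- file.path(root, dataset$subject_id[i])
    dir.create(d, showWarnings = FALSE)
    paths[i] <- file.path(d, sprintf("%03d.png", dataset$sample_id[i]))
    write_vein_image(dataset$image[[i]], paths[i])
  }
  manifest <- data.frame(path = paths,
                         subject_id = dataset$subject_id,
                         session = dataset$session)
  mpath <- file.path(root, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a dataset written by [write_dataset()]
#' @param root Directory containing `manifest.csv`.
#' @return A manifest tibble with an `image` list column.
#' @export
read_dataset <- function(root) {
  manifest <- utils::read.csv(file.path(root, "manifest.csv"))
  tibble::tibble(
    subject_id = as.integer(manifest$subject_id),
    sample_id = seq_along(manifest$path) -
      match(manifest$subject_id, manifest$subject_id) + 1L,
    session = as.integer(manifest$session),
    image = purrr::map(manifest$path, read_vein_image))
}
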