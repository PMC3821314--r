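test_that("grid partition follows the doubling rule with rounded boundaries", {
  img <- matrix(0, 64, 96)
  expect_length(grid_partition(img, 0), 1)
  expect_equal(dim(grid_partition(img, 0)[[1]]), c(64, 96))

  cells2 <- grid_partition(img, 2)
  expect_length(cells2, 16)
  expect_true(all(vapply(cells2, function(c) all(dim(c) == c(16, 24)), logical(1))))

  # non-divisible 97 x 65: widths {49, 48}, heights {33, 32}
  odd <- matrix(0, 65, 97)
  cells1 <- grid_partition(odd, 1)
  expect_equal(vapply(cells1, ncol, integer(1)), c(49, 48, 49, 48))
  expect_equal(vapply(cells1, nrow, integer(1)), c(33, 33, 32, 32))
  # cells tile the image exactly once
  expect_equal(sum(vapply(cells1, length, integer(1))), 65 * 97)

  expect_error(grid_partition(matrix(0, 2, 2), 2), "too small")
})

test_that("gray histograms bin on equal widths over [0, 255] and conserve mass", {
  expect_equal(gray_histogram(matrix(0, 10, 10), 4), c(100, 0, 0, 0))
  # bin-edge rule: one pixel at 0, 64, 128, 255 -> one per bin
  expect_equal(gray_histogram(c(0, 64, 128, 255), 4), c(1, 1, 1, 1))
  set.seed(2)
  cell <- matrix(runif(35 * 7, 0, 255), 35, 7)
  expect_equal(sum(gray_histogram(cell, 4)), length(cell))
  expect_equal(sum(gray_histogram(cell, 7)), length(cell))
})

test_that("LBP codes compare center > neighbor, clockwise from top-left", {
  # a center brighter than all 8 neighbors codes as all ones
  m <- matrix(90, 3, 3); m[2, 2] <- 100
  expect_equal(lbp_code(m, 2, 2), rep(1L, 8))
  m2 <- matrix(20, 3, 3); m2[2, 2] <- 50
  expect_equal(lbp_code(m2, 2, 2), rep(1L, 8))
  # constant image: strict inequality gives the all-zero code
  expect_equal(lbp_code(matrix(7, 3, 3), 2, 2), rep(0L, 8))
  # border pixels use replicate padding (no error, valid code)
  expect_length(lbp_code(m, 1, 1), 8)
})

test_that("LBP histograms sum bit vectors componentwise", {
  codes <- rbind(c(0, 1, 1, 1, 0, 1, 0, 0),
                 c(1, 1, 0, 1, 0, 1, 0, 1),
                 c(0, 1, 1, 1, 0, 1, 0, 1),
                 c(0, 1, 0, 1, 1, 1, 0, 0))
  expect_equal(lbp_histogram(codes), c(1, 4, 2, 4, 1, 4, 0, 2))
  expect_equal(lbp_histogram(matrix(0, 5, 8)), rep(0L, 8))
  one <- c(0, 1, 1, 0, 1, 0, 0, 1)
  expect_equal(lbp_histogram(matrix(one, 1, 8)), one)
})

test_that("edge maps respond to steps with the right orientation", {
  em0 <- edge_map(matrix(5, 10, 10))
  expect_false(any(em0$support))

  em <- edge_map(step_image())
  cols <- which(apply(em$support, 2, any))
  expect_true(all(abs(cols - 8.5) <= 1.5))       # support hugs the step
  # gradient along x: unsigned orientation ~ 0 degrees
  expect_true(all(em$orientation[em$support] %in% c(0, 180) |
                    em$orientation[em$support] < 1e-9))

  # a single dark horizontal ridge gives two parallel flanking responses
  ridge <- matrix(200, 20, 20); ridge[10, ] <- 60
  emr <- edge_map(ridge)
  rows <- sort(unique(which(emr$support, arr.ind = TRUE)[, 1]))
  expect_true(all(rows %in% c(9, 10, 11)))
  expect_true(all(c(9, 11) %in% rows))
})

test_that("HOG histograms vote magnitude into the right orientation bin", {
  em <- edge_map(step_image())
  h <- hog_histogram(em$magnitude, em$orientation, em$support, 4)
  expect_gt(h[1], 0)                              # 0-degree bin
  expect_equal(h[2:4], rep(0, 3))

  # 45-degree gradient (smooth diagonal ramp: a hard staircase step would
  # alias the Sobel angle) -> mass lands in the bin containing 45 degrees
  diag_img <- outer(1:20, 1:20, function(y, x)
    40 + 160 * pmin(pmax((x + y - 14) / 12, 0), 1))
  emd <- edge_map(diag_img)
  hd <- hog_histogram(emd$magnitude, emd$orientation, emd$support, 4)
  expect_equal(which.max(hd), 2)                  # bin [45, 90) contains 45
  expect_gt(hd[2], 0.9 * sum(hd))

  expect_equal(hog_histogram(em$magnitude, em$orientation,
                             em$support & FALSE, 4), rep(0, 4))
})

test_that("pyramid descriptors obey the dimension law K * sum(4^l)", {
  img <- matrix(runif(96 * 64, 0, 255), 64, 96)
  expect_length(pyramid_descriptor(img, "gray", 4, 2), 84)
  expect_length(pyramid_descriptor(img, "texture", 8, 2), 168)
  expect_length(pyramid_descriptor(img, "orientation", 4, 3), 340)
  # property over random K, L
  set.seed(3)
  for (i in 1:6) {
    k <- sample(1:9, 1); l <- sample(0:3, 1)
    v <- pyramid_descriptor(img, "gray", k, l)
    expect_length(v, k * sum(4^(0:l)))
  }
})

test_that("each level conserves the level-0 statistic before normalization", {
  set.seed(4)
  img <- matrix(runif(96 * 64, 0, 255), 64, 96)
  for (stat in c("gray", "texture")) {
    k <- if (stat == "gray") 4L else 8L
    v <- pyramid_descriptor(img, stat, k, 2, normalize = FALSE)
    lvl0 <- v[1:k]
    lvl1 <- matrix(v[k + 1:(4 * k)], nrow = k)
    lvl2 <- matrix(v[5 * k + 1:(16 * k)], nrow = k)
    expect_equal(rowSums(lvl1), lvl0)
    expect_equal(rowSums(lvl2), lvl0)
  }
  # PHOG conserves too: the edge support is computed once on the full image
  v <- pyramid_descriptor(img, "orientation", 4, 3, normalize = FALSE)
  lvl0 <- v[1:4]
  for (l in 1:3) {
    off <- 4 * sum(4^(0:(l - 1)))
    expect_equal(rowSums(matrix(v[off + 1:(4 * 4^l)], nrow = 4)), lvl0)
  }
  # and level-0 blocks match the standalone cell statistics
  expect_equal(pyramid_descriptor(img, "gray", 4, 0, normalize = FALSE)[1:4],
               as.numeric(gray_histogram(img, 4)))
})

test_that("swapping quadrants changes fine levels but not level 0", {
  set.seed(5)
  img <- matrix(runif(64 * 96, 0, 255), 64, 96)
  swapped <- img
  swapped[1:32, 1:48] <- img[33:64, 49:96]
  swapped[33:64, 49:96] <- img[1:32, 1:48]
  for (stat in c("gray")) {
    a <- pyramid_descriptor(img, stat, 4, 2, normalize = FALSE)
    b <- pyramid_descriptor(swapped, stat, 4, 2, normalize = FALSE)
    expect_equal(a[1:4], b[1:4])                   # global histogram unchanged
    expect_false(isTRUE(all.equal(a[5:84], b[5:84])))
  }
})

test_that("phgtog concatenates 84 + 168 + 340 = 592 with unit block sums", {
  img <- matrix(runif(96 * 64, 0, 255), 64, 96)
  v <- phgtog(img)
  expect_length(v, 592)
  layout <- attr(v, "layout")
  expect_equal(nrow(layout), 592)
  expect_equal(as.numeric(table(layout$descriptor)[c("phg", "pht", "phog")]),
               c(84, 168, 340))
  for (d in c("phg", "pht", "phog")) {
    expect_equal(sum(v[layout$descriptor == d]), 1, tolerance = 1e-9)
  }

  # constant image: PHG mass in one bin per cell, PHT and PHOG zero blocks
  vc <- phgtog(matrix(100, 64, 96))
  expect_equal(sum(vc[layout$descriptor == "phg"]), 1, tolerance = 1e-9)
  expect_equal(sum(vc[layout$descriptor == "pht"]), 0)
  expect_equal(sum(vc[layout$descriptor == "phog"]), 0)
  phg_cells <- vc[layout$descriptor == "phg"]
  expect_equal(sum(phg_cells > 0), 21)             # one active bin per cell

  # determinism across identical renders
  tpl <- make_template(1, seed = 2)
  expect_identical(phgtog(render_sample(tpl, seed = 1)),
                   phgtog(render_sample(tpl, seed = 9)))
})

test_that("feature tables carry layout/config and round-trip bit-exactly", {
  ds <- preprocess_dataset(generate_dataset(dataset_spec(2, 2, seed = 3)),
                           skip_roi = TRUE)
  feats <- extract_features(ds)
  expect_equal(nrow(feats), 4)
  expect_length(grep("^f_", names(feats)), 592)

  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path)
  back <- read_features(path)
  expect_identical(feature_matrix(back), feature_matrix(feats))
  expect_equal(attr(back, "config")$k_gray, 4L)
  expect_equal(nrow(attr(back, "layout")), 592)

  # minmax ablation: features rescaled into [0, 1] across the table
  mm <- extract_features(ds, pyramid_config(norm = "minmax"))
  M <- feature_matrix(mm)
  expect_true(all(M >= 0 & M <= 1))
})
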