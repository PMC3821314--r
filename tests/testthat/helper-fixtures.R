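# Shared fixtures, all generated in code.

# gradient image: value = x + 2*y on a small grid, scaled into [0, 255]
gradient_image <- function(w = 12, h = 8) {
  outer(seq_len(h) - 1, seq_len(w) - 1, function(y, x) x + 2 * y)
}

# vertical step edge at column `at` (dark left, bright right)
step_image <- function(w = 16, h = 12, at = 8, lo = 40, hi = 200) {
  m <- matrix(lo, h, w)
  m[, (at + 1):w] <- hi
  m
}

# independent bilinear interpolation at one fractional (x, y), 1-based,
# used as the oracle for normalize_size()
bilinear_oracle <- function(px, x, y) {
  x <- min(max(x, 1), ncol(px)); y <- min(max(y, 1), nrow(px))
  x0 <- min(floor(x), ncol(px) - 1); y0 <- min(floor(y), nrow(px) - 1)
  fx <- x - x0; fy <- y - y0
  (1 - fy) * ((1 - fx) * px[y0, x0] + fx * px[y0, x0 + 1]) +
    fy * ((1 - fx) * px[y0 + 1, x0] + fx * px[y0 + 1, x0 + 1])
}

# brute-force cyclical coordinate-descent LASSO oracle for
# 0.5 * ||y - X w||^2 + lambda * ||w||_1 (independent of glmnet)
lasso_cd_oracle <- function(X, y, lambda, iters = 20000) {
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  w <- numeric(ncol(X))
  for (it in seq_len(iters)) {
    w_old <- w
    for (j in seq_len(ncol(X))) {
      r <- y - X[, -j, drop = FALSE] %*% w[-j]
      w[j] <- soft(sum(X[, j] * r), lambda) / sum(X[, j]^2)
    }
    if (max(abs(w - w_old)) < 1e-12) break
  }
  w
}

lasso_objective <- function(X, y, w, lambda) {
  0.5 * sum((y - X %*% w)^2) + lambda * sum(abs(w))
}

# small deterministic multi-subject feature benchmark where subject 1
# differs from everyone else only in a known block of coordinates
blocky_features <- function(n_subjects = 4, m = 8, p = 30, block = 1:5,
                            shift = 1, noise = 0.1, seed = 42) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n_subjects * m * p, sd = noise), n_subjects * m, p)
  labels <- rep(seq_len(n_subjects), each = m)
  X[labels == 1, block] <- X[labels == 1, block] + shift
  list(X = X, labels = labels, block = block)
}
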