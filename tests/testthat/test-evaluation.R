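# independent enumeration oracle: sweep every observed score as a threshold
# (accept iff distance <= t), return the full (t, FAR, FRR) table
enumerate_rates <- function(genuine, imposter) {
  thr <- c(-Inf, sort(unique(c(genuine, imposter))), Inf)
  data.frame(
    threshold = thr,
    far = vapply(thr, function(t) mean(imposter <= t), numeric(1)),
    frr = vapply(thr, function(t) mean(genuine > t), numeric(1)))
}

test_that("pair construction hits the protocol's count law", {
  # the canonical 136/10/2 protocol: 1,360 genuine and 36,720 imposters
  labels <- rep(1:136, each = 10)
  pairs <- build_pairs(protocol(136, 10, 10, 2), labels)
  expect_equal(sum(pairs$kind == "genuine"), 1360)
  expect_equal(sum(pairs$kind == "imposter"), 36720)

  # small case: N=2, test=3, ipp=1 -> 6 genuine, 2 imposters
  p2 <- build_pairs(protocol(2, 3, 3, 1), rep(1:2, each = 3))
  expect_equal(sum(p2$kind == "genuine"), 6)
  expect_equal(sum(p2$kind == "imposter"), 2)

  # property: counts follow N * test and N * (N-1) * ipp
  set.seed(30)
  for (i in 1:5) {
    n <- sample(2:8, 1); tpc <- sample(2:5, 1); ipp <- sample(seq_len(tpc), 1)
    pp <- build_pairs(protocol(n, tpc, tpc, ipp), rep(seq_len(n), each = tpc))
    expect_equal(sum(pp$kind == "genuine"), n * tpc)
    expect_equal(sum(pp$kind == "imposter"), n * (n - 1) * ipp)
  }

  expect_error(build_pairs(protocol(2, 3, 3, 3), rep(1:2, each = 2)), "fewer")
  expect_error(build_pairs(protocol(2, 2, 2, 3), rep(1:2, each = 3)), "exceeds")
})

test_that("imposter probes are the first ipp test samples of each class", {
  pairs <- build_pairs(protocol(3, 2, 2, 1), rep(1:3, each = 2))
  imp <- pairs[pairs$kind == "imposter", ]
  expect_true(all(imp$probe_row %in% c(1, 3, 5)))    # first sample per class
})

test_that("ROC matches the enumeration oracle and is monotone", {
  set.seed(31)
  genuine <- rexp(50); imposter <- rexp(80) + 1
  roc <- roc_curve(genuine, imposter)
  orc <- enumerate_rates(genuine, imposter)
  expect_equal(roc$far, orc$far)
  expect_equal(roc$frr, orc$frr)
  expect_true(all(diff(roc$far) >= 0))
  expect_true(all(diff(roc$frr) <= 0))
  expect_true(all(roc$far >= 0 & roc$far <= 1 & roc$frr >= 0 & roc$frr <= 1))

  expect_error(roc_curve(numeric(0), imposter), "non-empty")
})

test_that("EER follows the crossing rule on hand-enumerable cases", {
  # separable: all genuine below all imposters -> EER 0
  expect_equal(eer(roc_curve(c(1, 2), c(3, 4))), 0)

  # interleaved {1,3} vs {2,4}: at t=2 the sweep reaches FAR = FRR = 0.5
  # exactly (verified by the enumeration oracle), so the crossing value is 0.5
  orc <- enumerate_rates(c(1, 3), c(2, 4))
  k <- which(orc$far == orc$frr)[1]
  expect_equal(orc$far[k], 0.5)
  expect_equal(eer(roc_curve(c(1, 3), c(2, 4))), 0.5)

  # identical large samples -> EER near 0.5
  set.seed(32)
  s <- rnorm(2000)
  expect_equal(eer(roc_curve(s, s)), 0.5, tolerance = 1e-9)

  # EER is always within [0, 1] and below FAR-at-zero-FRR
  for (i in 1:10) {
    g <- rnorm(30); im <- rnorm(40, mean = runif(1, 0, 2))
    roc <- roc_curve(g, im)
    e <- eer(roc)
    op <- operating_points(roc)
    expect_gte(e, 0); expect_lte(e, 1)
    expect_gte(op$far_at_zero_frr + 1e-12, e)
  }
})

test_that("extreme operating points follow their definitions", {
  # separable -> both zero
  roc <- roc_curve(c(1, 2), c(3, 4))
  op <- operating_points(roc)
  expect_equal(op$far_at_zero_frr, 0)
  expect_equal(op$frr_at_zero_far, 0)

  # fully overlapping singletons: accepting the genuine accepts the imposter
  op2 <- operating_points(roc_curve(1, 1))
  expect_equal(op2$far_at_zero_frr, 1)

  # oracle check on a random instance
  set.seed(33)
  g <- runif(25); im <- runif(35)
  roc3 <- roc_curve(g, im)
  op3 <- operating_points(roc3)
  expect_equal(op3$far_at_zero_frr, mean(im <= max(g)))
  expect_equal(op3$frr_at_zero_far, mean(g > max(c(-Inf, g, im)[c(-Inf, g, im) < min(im)])))
})

test_that("recognition rate is the exact-match fraction", {
  expect_equal(recognition_rate(1:4, 1:4), 1)
  expect_equal(recognition_rate(1:4, 5:8), 0)
  expect_equal(recognition_rate(c(1, 2, 3, 9), 1:4), 0.75)
  expect_error(recognition_rate(1:3, 1:4), "length")
})

test_that("evaluate_scores assembles a coherent report with tidy methods", {
  scored <- tibble::tibble(
    kind = rep(c("genuine", "imposter"), c(20, 30)),
    distance = c(runif(20, 0, 1), runif(30, 0.5, 2)))
  identified <- tibble::tibble(true_subject = rep(1:5, 4),
                               predicted_subject = c(rep(1:5, 3), rep(1, 5)))
  rep <- evaluate_scores(scored, identified)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$recognition_rate, 16 / 20)
  expect_equal(nrow(glance(rep)), 1)
  expect_equal(tidy(rep), rep$roc)
  plt <- autoplot(rep)
  expect_s3_class(plt, "ggplot")
})
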