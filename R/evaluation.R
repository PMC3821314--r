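#' Verification protocol description
#'
#' With `N` classes, `test_per_class` test samples each and
#' `imposters_per_class_pair` imposter probes per ordered class pair, the
#' protocol produces `N * test_per_class` genuine pairs and
#' `N * (N - 1) * imposters_per_class_pair` imposter pairs (the canonical
#' 136/10/2 setup gives 1,360 and 36,720).
#'
#' @param n_classes,enroll_per_class,test_per_class,imposters_per_class_pair
#'   Protocol counts, all >= 1.
#' @return A `protocol` list.
#' @export
protocol <- function(n_classes, enroll_per_class, test_per_class,
                     imposters_per_class_pair = 2L) {
  stopifnot(n_classes >= 1, enroll_per_class >= 1, test_per_class >= 1,
            imposters_per_class_pair >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 enroll_per_class = as.integer(enroll_per_class),
                 test_per_class = as.integer(test_per_class),
                 imposters_per_class_pair = as.integer(imposters_per_class_pair)),
            class = "protocol")
}

#' Construct genuine and imposter probe/claim pairs
#'
#' Every test sample is matched against its own class center (genuine).
#' For imposters, the first `imposters_per_class_pair` test samples of each
#' class (by sample order — a deterministic choice) are matched against
#' every other class's center.
#'
#' @param proto A [protocol()].
#' @param labels Subject label of each test row, in table order.
#' @return Tibble with `probe_row`, `claimed_subject`, `kind`
#'   (`"genuine"`/`"imposter"`).
#' @export
build_pairs <- function(proto, labels) {
  ids <- sort(unique(labels))
  if (length(ids) != proto$n_classes) {
    stop(sprintf("expected %d classes, found %d", proto$n_classes, length(ids)),
         call. = FALSE)
  }
  per_class <- split(seq_along(labels), labels)[as.character(ids)]
  sizes <- lengths(per_class)
  if (any(sizes < proto$test_per_class)) {
    stop("some class has fewer test samples than the protocol requires", call. = FALSE)
  }
  if (proto$imposters_per_class_pair > proto$test_per_class) {
    stop("imposters_per_class_pair exceeds test_per_class", call. = FALSE)
  }
  genuine <- purrr::map_dfr(seq_along(ids), function(i) {
    rows <- per_class[[i]][seq_len(proto$test_per_class)]
    tibble::tibble(probe_row = rows, claimed_subject = ids[i], kind = "genuine")
  })
  imposter <- purrr::map_dfr(seq_along(ids), function(i) {
    rows <- per_class[[i]][seq_len(proto$imposters_per_class_pair)]
    others <- ids[ids != ids[i]]
    tidyr::expand_grid(probe_row = rows, claimed_subject = others) |>
      dplyr::mutate(kind = "imposter")
  })
  dplyr::bind_rows(genuine, imposter)
}

#' ROC over distance scores
#'
#' Scores are distances (smaller = more similar); a probe is accepted when
#' its distance is `<=` the threshold. Thresholds sweep the union of all
#' observed scores plus `-Inf` and `+Inf`, so the curve runs from
#' (FAR 0, FRR 1) to (FAR 1, FRR 0). `FAR(t)` is the fraction of imposter
#' distances `<= t`; `FRR(t)` the fraction of genuine distances `> t`.
#'
#' @param genuine,imposter Numeric score vectors, both non-empty.
#' @return Tibble `threshold`, `far`, `frr`, sorted by threshold.
#' @export
roc_curve <- function(genuine, imposter) {
  if (length(genuine) == 0 || length(imposter) == 0) {
    stop("genuine and imposter score sets must be non-empty", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(c(genuine, imposter))), Inf)
  gs <- sort(genuine); is <- sort(imposter)
  far <- findInterval(thr, is) / length(is)            # P(imposter <= t)
  frr <- 1 - findInterval(thr, gs) / length(gs)        # P(genuine  >  t)
  tibble::tibble(threshold = thr, far = far, frr = frr)
}

#' Equal error rate of a ROC
#'
#' The error rate at the threshold where FAR equals FRR. When a swept
#' threshold achieves FAR = FRR exactly, that common value is returned;
#' otherwise the crossing is linearly interpolated between the adjacent
#' thresholds that bracket it.
#'
#' @param roc Tibble from [roc_curve()].
#' @return EER in \[0, 1\].
#' @export
eer <- function(roc) {
  d <- roc$far - roc$frr                     # -1 at -Inf, +1 at +Inf
  k <- which(d >= 0)[1]
  if (d[k] == 0) return(roc$far[k])
  # interpolate between k-1 (d < 0) and k (d > 0)
  a <- d[k - 1]; b <- d[k]
  t <- -a / (b - a)
  far_x <- roc$far[k - 1] + t * (roc$far[k] - roc$far[k - 1])
  frr_x <- roc$frr[k - 1] + t * (roc$frr[k] - roc$frr[k - 1])
  (far_x + frr_x) / 2
}

#' Extreme operating points of a ROC
#'
#' `far_at_zero_frr` is the FAR at the smallest swept threshold with
#' FRR = 0 (the convenience end); `frr_at_zero_far` is the FRR at the
#' largest swept threshold with FAR = 0 (the high-security end).
#'
#' @param roc Tibble from [roc_curve()].
#' @return Named list `far_at_zero_frr`, `frr_at_zero_far`.
#' @export
operating_points <- function(roc) {
  list(far_at_zero_frr = roc$far[which(roc$frr == 0)[1]],
       frr_at_zero_far = roc$frr[max(which(roc$far == 0))])
}

#' Closed-set recognition rate
#'
#' @param predictions,truth Equal-length label vectors.
#' @return Fraction of exact matches.
#' @export
recognition_rate <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length", call. = FALSE)
  }
  mean(predictions == truth)
}

#' Full biometric evaluation of a scored pair table
#'
#' @param scored Tibble from [score_pairs()] (columns `kind`, `distance`).
#' @param identified Optional tibble from [identify_all()]; adds the
#'   recognition rate.
#' @return An `eval_report`: score sets, ROC tibble, `eer`,
#'   `far_at_zero_frr`, `frr_at_zero_far`, `recognition_rate` (NA when no
#'   identification table is given).
#' @export
evaluate_scores <- function(scored, identified = NULL) {
  genuine <- scored$distance[scored$kind == "genuine"]
  imposter <- scored$distance[scored$kind == "imposter"]
  roc <- roc_curve(genuine, imposter)
  op <- operating_points(roc)
  rr <- if (is.null(identified)) NA_real_ else {
    recognition_rate(identified$predicted_subject, identified$true_subject)
  }
  structure(list(genuine = genuine, imposter = imposter, roc = roc,
                 eer = eer(roc),
                 far_at_zero_frr = op$far_at_zero_frr,
                 frr_at_zero_far = op$frr_at_zero_far,
                 recognition_rate = rr),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<eval_report> %d genuine / %d imposter scores\n",
    "  EER %.4f | FAR@zeroFRR %.4f | FRR@zeroFAR %.4f | recognition rate %s\n"),
    length(x$genuine), length(x$imposter), x$eer, x$far_at_zero_frr,
    x$frr_at_zero_far,
    if (is.na(x$recognition_rate)) "-" else sprintf("%.4f", x$recognition_rate)))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return `tidy()`: the ROC tibble (threshold, far, frr); `glance()`: a
#'   one-row tibble of the summary metrics.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$roc

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(eer = x$eer,
                 far_at_zero_frr = x$far_at_zero_frr,
                 frr_at_zero_far = x$frr_at_zero_far,
                 recognition_rate = x$recognition_rate,
                 n_genuine = length(x$genuine),
                 n_imposter = length(x$imposter))
}

#' ROC plot of an evaluation report
#'
#' FRR against FAR on log-x, with the EER marked.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  roc <- object$roc
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$far, y = .data$frr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = object$eer, y = object$eer, shape = 4) +
    ggplot2::labs(x = "False acceptance rate",
                  y = "False rejection rate",
                  title = sprintf("ROC (EER = %.4f)", object$eer)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
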