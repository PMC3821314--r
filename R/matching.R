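#' Build a subject's class center
#'
#' The class center is the componentwise mean of the subject's enrollment
#' feature vectors; when a personalized mask is supplied the samples are
#' projected onto it first (masking and averaging commute, so the order is
#' immaterial — projection first keeps the stored template small).
#'
#' @param samples Numeric matrix (one enrollment sample per row) or a single
#'   vector.
#' @param subject_id Label stored with the center.
#' @param mask Optional sorted feature indices (personalized space).
#' @return A `class_center`: `subject_id`, `center`, `space` (`"full"` or
#'   `"masked"`), `mask`, `m` (samples averaged).
#' @export
build_center <- function(samples, subject_id = NA_integer_, mask = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (nrow(samples) < 1) stop("need >= 1 sample", call. = FALSE)
  if (!is.null(mask)) {
    samples <- samples[, sort(mask), drop = FALSE]
  }
  structure(list(subject_id = subject_id,
                 center = colMeans(samples),
                 space = if (is.null(mask)) "full" else "masked",
                 mask = if (is.null(mask)) NULL else sort(mask),
                 m = nrow(samples)),
            class = "class_center")
}

#' Build class centers for every subject
#'
#' @param features Training feature tibble ([extract_features()]).
#' @param models Optional `pfs_models`; when supplied each subject's center
#'   lives in its own masked space (PFS mode), otherwise all centers share
#'   the full PHGTOG space.
#' @return Named list of `class_center` objects (class `center_set`).
#' @export
build_centers <- function(features, models = NULL) {
  X <- feature_matrix(features)
  labels <- feature_labels(features)
  ids <- sort(unique(labels))
  centers <- lapply(ids, function(sid) {
    mask <- if (is.null(models)) NULL else models$models[[as.character(sid)]]$mask
    build_center(X[labels == sid, , drop = FALSE], subject_id = sid, mask = mask)
  })
  names(centers) <- ids
  structure(centers, class = "center_set")
}

#' @export
print.center_set <- function(x, ...) {
  dims <- vapply(x, function(ce) length(ce$center), integer(1))
  cat(sprintf("<center_set> %d subjects, space '%s', template length %d-%d\n",
              length(x), x[[1]]$space, min(dims), max(dims)))
  invisible(x)
}

#' Euclidean match score of a probe against one class center
#'
#' The probe is projected into the center's space (its mask) first; the
#' score is the Euclidean distance `||f - T||_2`, so 0 means an exact match
#' in that space.
#'
#' @param probe Full-length feature vector.
#' @param center A `class_center`.
#' @return Non-negative distance.
#' @export
score <- function(probe, center) {
  f <- if (is.null(center$mask)) probe else apply_mask(probe, center$mask)
  if (length(f) != length(center$center)) {
    stop("probe/center space mismatch (wrong mask or layout)", call. = FALSE)
  }
  sqrt(sum((f - center$center)^2))
}

#' Verify a claimed identity
#'
#' Accepts when the distance to the claimed subject's center is less than or
#' equal to the threshold (the boundary is inclusive).
#'
#' @param probe Full-length feature vector.
#' @param claimed_subject Subject id to verify against.
#' @param centers A `center_set`.
#' @param threshold Decision threshold on the distance.
#' @return List with `accept` (logical) and `distance`.
#' @export
verify <- function(probe, claimed_subject, centers, threshold) {
  ce <- centers[[as.character(claimed_subject)]]
  if (is.null(ce)) stop(sprintf("unknown subject '%s'", claimed_subject), call. = FALSE)
  d <- score(probe, ce)
  list(accept = d <= threshold, distance = d)
}

#' Identify a probe against all class centers
#'
#' Closed-set identification: the probe is scored against every center (in
#' PFS mode each candidate's distance is computed in that candidate's own
#' masked space; raw distances are compared across spaces unless
#' `dim_normalize` rescales them) and the nearest subject wins. Ties break
#' to the smallest subject id, with a message.
#'
#' @param probe Full-length feature vector.
#' @param centers A `center_set`.
#' @param dim_normalize Divide each distance by `sqrt(template length)` to
#'   offset differing mask sizes (default `FALSE`).
#' @return The predicted subject id.
#' @export
identify <- function(probe, centers, dim_normalize = FALSE) {
  ids <- unname(vapply(centers, function(ce) ce$subject_id, numeric(1)))
  d <- vapply(centers, function(ce) {
    s <- score(probe, ce)
    if (dim_normalize) s / sqrt(length(ce$center)) else s
  }, numeric(1))
  hits <- which(d == min(d))
  if (length(hits) > 1) {
    hits <- hits[order(ids[hits])]
    message(sprintf("identification tie among subjects {%s}; taking %s",
                    paste(ids[hits], collapse = ", "), ids[hits[1]]))
  }
  ids[hits[1]]
}

#' Score a table of (probe, claimed subject) pairs
#'
#' @param pairs Tibble with columns `probe_row` (row index into `features`)
#'   and `claimed_subject` (from [build_pairs()]).
#' @param features Test feature tibble.
#' @param centers A `center_set`.
#' @param dim_normalize See [identify()].
#' @return `pairs` with columns `true_subject` and `distance` added.
#' @export
score_pairs <- function(pairs, features, centers, dim_normalize = FALSE) {
  X <- feature_matrix(features)
  labels <- feature_labels(features)
  pairs$true_subject <- labels[pairs$probe_row]
  pairs$distance <- vapply(seq_len(nrow(pairs)), function(i) {
    ce <- centers[[as.character(pairs$claimed_subject[i])]]
    s <- score(X[pairs$probe_row[i], ], ce)
    if (dim_normalize) s / sqrt(length(ce$center)) else s
  }, numeric(1))
  pairs
}

#' Identify every probe of a test set
#'
#' @param features Test feature tibble.
#' @param centers A `center_set`.
#' @param dim_normalize See [identify()].
#' @return Tibble with `true_subject` and `predicted_subject` per probe.
#' @export
identify_all <- function(features, centers, dim_normalize = FALSE) {
  X <- feature_matrix(features)
  preds <- vapply(seq_len(nrow(X)), function(i) {
    identify(X[i, ], centers, dim_normalize = dim_normalize)
  }, numeric(1))
  tibble::tibble(true_subject = feature_labels(features),
                 predicted_subject = preds)
}
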