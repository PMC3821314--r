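#' One-vs-rest labels for a subject
#'
#' @param labels Vector of subject labels, one per training sample.
#' @param subject_id The positive class; must occur in `labels`, and at
#'   least one other label must be present.
#' @return Numeric vector in `{+1, -1}`.
#' @export
one_vs_rest_labels <- function(labels, subject_id) {
  if (!subject_id %in% labels) {
    stop(sprintf("subject '%s' not present in labels", subject_id), call. = FALSE)
  }
  y <- ifelse(labels == subject_id, 1, -1)
  if (all(y == 1)) {
    stop("no negative class: training set contains only this subject", call. = FALSE)
  }
  y
}

#' Smallest penalty that zeroes every coefficient
#'
#' For the objective `0.5 * sum((y - X w)^2) + lambda * sum(|w|)` the whole
#' coefficient vector is zero exactly when `lambda >= max(|X^T y|)`.
#'
#' @param X Feature matrix (samples x features).
#' @param y Label vector in `{+1, -1}`.
#' @return The critical penalty `lambda_max`.
#' @export
lambda_max <- function(X, y) max(abs(crossprod(X, y)))

# support of w at the fixed tolerance used throughout the package
mask_of <- function(w, eps = 1e-8) which(abs(w) > eps)

#' Train a per-subject sparse weight vector
#'
#' Solves the L1-regularized least-squares problem
#' `min_w 0.5 * sum_i (y_i - w' x_i)^2 + lambda * sum_j |w_j|`
#' with no intercept and no feature standardization (the features are used
#' exactly as the extractor normalized them, so the L1 penalty is not
#' silently reweighted). The support of `w` (|w_j| > 1e-8) is the subject's
#' personalized feature mask.
#'
#' @param X Feature matrix (samples x features), all finite.
#' @param y One-vs-rest labels in `{+1, -1}`.
#' @param lambda Penalty strength, > 0 (absolute scale of the objective
#'   above).
#' @param subject_id Label stored with the result.
#' @param thresh Solver convergence threshold (glmnet `thresh`); the
#'   default is tight enough that small instances match a brute-force
#'   coordinate-descent solution to well below 1e-6 in objective value.
#' @return A `subject_weights` list: `subject_id`, `w`, `lambda`, `mask`
#'   (sorted indices of the support).
#' @export
train_weights <- function(X, y, lambda, subject_id = NA_integer_,
                          thresh = 1e-10) {
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  stopifnot(lambda > 0)
  m <- nrow(X)
  lam_top <- lambda_max(X, y)
  if (lambda >= lam_top) {
    w <- numeric(ncol(X))
  } else {
    # glmnet minimizes (1/(2m)) RSS + lambda_g * |w|_1, so lambda_g = lambda/m;
    # a short descending path down to the target stabilizes the solution.
    path <- exp(seq(log(lam_top), log(lambda), length.out = 30)) / m
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = path, intercept = FALSE,
                          standardize = FALSE, thresh = thresh, maxit = 1e6)
    w <- as.numeric(fit$beta[, ncol(fit$beta)])
  }
  structure(list(subject_id = subject_id, w = w, lambda = lambda,
                 mask = mask_of(w)),
            class = "subject_weights")
}

#' @export
print.subject_weights <- function(x, ...) {
  cat(sprintf("<subject_weights> subject %s: %d of %d features selected (lambda = %.4g)\n",
              format(x$subject_id), length(x$mask), length(x$w), x$lambda))
  invisible(x)
}

#' Train personalized weight vectors for every subject
#'
#' One LASSO fit per subject under its own one-vs-rest relabeling, all at
#' penalty `lambda_rel * lambda_max(subject)`. The default penalty is light
#' (1e-5 of each subject's critical penalty): it keeps roughly half of the
#' 592 features, the selection regime in which personalized masks retain
#' enough information to match on. Subjects whose fit returns an
#' empty support fall back to the full feature set with a warning (an empty
#' mask would leave nothing to match on).
#'
#' @param features Feature tibble from [extract_features()] (training rows
#'   only), or a numeric matrix with `labels` supplied.
#' @param lambda_rel Penalty relative to each subject's `lambda_max`,
#'   default 1e-5.
#' @param labels Subject labels (required when `features` is a matrix).
#' @param thresh Solver convergence threshold; looser than the
#'   [train_weights()] default because a full benchmark trains hundreds of
#'   fits whose masks and centers are insensitive to the last digits.
#' @return A `pfs_models` object: named list of `subject_weights` plus the
#'   feature-table attributes.
#' @export
train_subjects <- function(features, lambda_rel = 1e-5, labels = NULL,
                           thresh = 1e-7) {
  if (is.matrix(features)) {
    X <- features
    stopifnot(!is.null(labels))
  } else {
    X <- feature_matrix(features)
    labels <- feature_labels(features)
  }
  if (length(unique(labels)) < 2) stop("need >= 2 subjects", call. = FALSE)
  ids <- sort(unique(labels))
  models <- lapply(ids, function(sid) {
    y <- one_vs_rest_labels(labels, sid)
    sw <- train_weights(X, y, lambda = lambda_rel * lambda_max(X, y),
                        subject_id = sid, thresh = thresh)
    if (length(sw$mask) == 0) {
      warning(sprintf("subject %s: empty mask, falling back to full feature set", sid),
              call. = FALSE)
      sw$mask <- seq_len(ncol(X))
    }
    sw
  })
  names(models) <- ids
  structure(list(models = models, lambda_rel = lambda_rel, p = ncol(X)),
            class = "pfs_models")
}

#' @export
print.pfs_models <- function(x, ...) {
  sizes <- vapply(x$models, function(m) length(m$mask), integer(1))
  cat(sprintf("<pfs_models> %d subjects, p = %d, mask size %d-%d (mean %.1f), lambda_rel = %g\n",
              length(x$models), x$p, min(sizes), max(sizes), mean(sizes),
              x$lambda_rel))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-subject summary of trained personalized masks
#'
#' @param x A `pfs_models` object.
#' @param ... Unused.
#' @return `tidy()`: tibble with one row per subject (`subject_id`,
#'   `lambda`, `mask_size`, `p`); `glance()`: one-row tibble with mask-size
#'   summary statistics.
#' @method tidy pfs_models
#' @export
tidy.pfs_models <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(subject_id = m$subject_id, lambda = m$lambda,
                   mask_size = length(m$mask), p = length(m$w))
  })
}

#' @rdname tidy.pfs_models
#' @method glance pfs_models
#' @export
glance.pfs_models <- function(x, ...) {
  sizes <- vapply(x$models, function(m) length(m$mask), integer(1))
  tibble::tibble(n_subjects = length(x$models), p = x$p,
                 lambda_rel = x$lambda_rel,
                 min_mask = min(sizes), mean_mask = mean(sizes),
                 max_mask = max(sizes))
}

#' Project a feature vector onto a subject's mask
#'
#' @param feature_vector Numeric vector of length `p`.
#' @param mask Sorted integer indices, all in `1..p`.
#' @return The masked values, in ascending index order.
#' @export
apply_mask <- function(feature_vector, mask) {
  if (length(mask) && (max(mask) > length(feature_vector) || min(mask) < 1)) {
    stop("mask index out of range for this feature layout", call. = FALSE)
  }
  feature_vector[sort(mask)]
}

#' Save / load trained models as one JSON document per subject
#'
#' Each file records the subject id, penalty, the sparse weights as
#' (index, value) pairs, and the mask.
#'
#' @param models A `pfs_models` object.
#' @param dir Output directory.
#' @return `dir` (write) or a `pfs_models` (read).
#' @export
write_models <- function(models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in models$models) {
    nz <- mask_of(m$w)
    doc <- list(subject_id = m$subject_id, lambda = m$lambda, p = length(m$w),
                w_index = nz, w_value = m$w[nz], mask = m$mask)
    jsonlite::write_json(doc, file.path(dir, sprintf("subject_%s.json", m$subject_id)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_models
#' @param lambda_rel Relative penalty to record on the reloaded object.
#' @export
read_models <- function(dir, lambda_rel = NA_real_) {
  files <- sort(list.files(dir, pattern = "^subject_.*\\.json$", full.names = TRUE))
  models <- lapply(files, function(f) {
    doc <- jsonlite::read_json(f, simplifyVector = TRUE)
    w <- numeric(doc$p)
    w[doc$w_index] <- doc$w_value
    structure(list(subject_id = doc$subject_id, w = w, lambda = doc$lambda,
                   mask = as.integer(doc$mask)),
              class = "subject_weights")
  })
  ids <- vapply(models, function(m) m$subject_id, numeric(1))
  ord <- order(ids)
  models <- models[ord]
  names(models) <- ids[ord]
  structure(list(models = models, lambda_rel = lambda_rel,
                 p = length(models[[1]]$w)),
            class = "pfs_models")
}
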