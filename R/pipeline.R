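#' Configuration of one end-to-end recognition run
#'
#' Bundles the dataset specification (or an input directory written by
#' [write_dataset()]), the pyramid configuration, the LASSO penalty, the
#' evaluation protocol and the matching mode into a single serializable
#' document. A short hash of the config is stamped on every artifact the
#' run produces, so artifacts from different configs cannot be mixed
#' silently.
#'
#' @param dataset A [dataset_spec()], or a directory path containing a
#'   dataset manifest.
#' @param config A [pyramid_config()].
#' @param lambda_rel LASSO penalty relative to each subject's lambda_max
#'   (PFS mode), default 1e-5 (keeps roughly half the features).
#' @param enroll_per_class,test_per_class Train/test split per subject, by
#'   sample order; defaults 20 and 10 with 2 imposter probes per class pair.
#' @param imposters_per_class_pair Imposter probes per ordered class pair.
#' @param mode `"phgtog"` (full descriptor) or `"pfs"` (personalized
#'   selection).
#' @param skip_roi Bypass ROI extraction during preprocessing (default
#'   `TRUE`, the right choice for synthetic images with no finger
#'   silhouette).
#' @param dim_normalize See [identify()].
#' @param seed Seed recorded for the run (the dataset spec carries its own).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(dataset, config = pyramid_config(),
                            lambda_rel = 1e-5,
                            enroll_per_class = 20L, test_per_class = 10L,
                            imposters_per_class_pair = 2L,
                            mode = c("phgtog", "pfs"),
                            skip_roi = TRUE, dim_normalize = FALSE,
                            seed = 1L) {
  structure(list(dataset = dataset, config = config,
                 lambda_rel = lambda_rel,
                 enroll_per_class = as.integer(enroll_per_class),
                 test_per_class = as.integer(test_per_class),
                 imposters_per_class_pair = as.integer(imposters_per_class_pair),
                 mode = match.arg(mode), skip_roi = skip_roi,
                 dim_normalize = dim_normalize, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("cfg%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2^31)
}

#' Split a feature table into enrollment and test partitions
#'
#' The first `enroll_per_class` samples of each subject (by sample order)
#' enroll; the next `test_per_class` are the test set.
#'
#' @param features Feature tibble.
#' @param enroll_per_class,test_per_class Per-subject counts.
#' @return List with tibbles `enroll` and `test`.
#' @export
split_enroll_test <- function(features, enroll_per_class, test_per_class) {
  ranked <- features |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup()
  if (max(ranked$.rank) < enroll_per_class + test_per_class) {
    stop("not enough samples per subject for the requested split", call. = FALSE)
  }
  keep_attrs <- function(tb) {
    attr(tb, "layout") <- attr(features, "layout")
    attr(tb, "config") <- attr(features, "config")
    tb
  }
  list(enroll = keep_attrs(dplyr::filter(ranked, .data$.rank <= enroll_per_class) |>
                             dplyr::select(-".rank")),
       test = keep_attrs(dplyr::filter(ranked,
                                       .data$.rank > enroll_per_class,
                                       .data$.rank <= enroll_per_class + test_per_class) |>
                           dplyr::select(-".rank")))
}

#' Run the full recognition pipeline
#'
#' Generates (or reads) the dataset, preprocesses every image, extracts
#' PHGTOG, optionally trains per-subject personalized masks, builds class
#' centers from the enrollment partition, scores the verification protocol
#' and the closed-set identification task on the test partition, and
#' returns the evaluation report. With `out_dir` set, every intermediate
#' (features, models, scores, report) is persisted, each stamped with the
#' config hash.
#'
#' @param run A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @return An `eval_report`, with attributes `models` (PFS mode),
#'   `config_hash` and `mask_sizes`.
#' @export
run_pipeline <- function(run, out_dir = NULL) {
  stopifnot(inherits(run, "run_config"))
  hash <- config_hash(run)

  dataset <- if (inherits(run$dataset, "dataset_spec")) {
    generate_dataset(run$dataset)
  } else {
    read_dataset(run$dataset)
  }
  dataset <- preprocess_dataset(dataset, skip_roi = run$skip_roi)
  features <- extract_features(dataset, run$config)
  parts <- split_enroll_test(features, run$enroll_per_class, run$test_per_class)

  models <- NULL
  if (run$mode == "pfs") {
    models <- train_subjects(parts$enroll, lambda_rel = run$lambda_rel)
  }
  centers <- build_centers(parts$enroll, models)

  proto <- protocol(n_classes = length(unique(features$subject_id)),
                    enroll_per_class = run$enroll_per_class,
                    test_per_class = run$test_per_class,
                    imposters_per_class_pair = run$imposters_per_class_pair)
  pairs <- build_pairs(proto, feature_labels(parts$test))
  scored <- score_pairs(pairs, parts$test, centers,
                        dim_normalize = run$dim_normalize)
  identified <- identify_all(parts$test, centers,
                             dim_normalize = run$dim_normalize)
  report <- evaluate_scores(scored, identified)
  attr(report, "config_hash") <- hash
  attr(report, "models") <- models
  attr(report, "mask_sizes") <- if (is.null(models)) {
    rep(ncol(feature_matrix(features)), length(centers))
  } else {
    vapply(models$models, function(m) length(m$mask), integer(1))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(features, file.path(out_dir, "features.csv"))
    if (!is.null(models)) write_models(models, file.path(out_dir, "models"))
    scored$config_hash <- hash
    utils::write.csv(scored, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(glance(report), list(config_hash = hash)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
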