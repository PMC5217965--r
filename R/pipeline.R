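#' Per-voxel temporal features of a DCE series
#'
#' Convenience wrapper: time matrix, temporal PCA, and min-max normalized
#' score volumes in one step.
#'
#' @param series A [dce_series()].
#' @param n_components Number of principal components kept.
#' @return A list with `basis` (the [fit_pca()] result) and `scores`
#'   (the [score_volumes()]).
#' @export
dce_features <- function(series, n_components = 4L) {
  tm <- build_time_matrix(series)
  basis <- fit_pca(tm)
  list(basis = basis, scores = score_volumes(basis, n_components))
}

.reference_index <- function(series, reference_time_s) {
  post <- setdiff(seq_along(series$volumes), series$pre_contrast_index)
  i <- post[which.min(abs(series$times_s[post] - reference_time_s))]
  i
}

#' Run the full segmentation pipeline on a DCE series
#'
#' Executes every stage in order: temporal PCA features, SLIC supervoxels,
#' supervoxel classification (training the classifier from `truth` unless a
#' fitted `model` is supplied), probability broadcasting and Gaussian
#' smoothing, per-voxel argmax labeling restricted to the body mask,
#' morphological organ extraction, threshold-based bone segmentation, and
#' priority integration. Deterministic given the config seed.
#'
#' @param series A [dce_series()].
#' @param config A [pipeline_config()].
#' @param truth Ground-truth label volume used to build the training set
#'   (required when `model` is `NULL`).
#' @param model Optional fitted [train_svm()] / [train_rf()] classifier;
#'   skips training.
#' @param training_set Optional prebuilt [build_training_set()] result;
#'   overrides `truth` for training.
#' @param keep_intermediates Keep score volumes and probability maps in the
#'   returned object (they are large).
#' @return An object of class `dce_segmentation`: the `result`
#'   ([integrate_masks()] output), `model`, `svmap`, `training_set`,
#'   `config`, and optionally `scores` and `prob_maps`.
#' @export
dce_segment <- function(series, config = pipeline_config(), truth = NULL,
                        model = NULL, training_set = NULL,
                        keep_intermediates = FALSE) {
  stopifnot(inherits(series, "dce_series"),
            inherits(config, "pipeline_config"))
  feats <- dce_features(series, config$n_components)
  svmap <- slic_supervoxels(feats$scores, S = config$S, m = config$m)
  if (is.null(model)) {
    if (is.null(training_set)) {
      if (is.null(truth)) {
        stop("either a fitted model, a training set, or truth labels ",
             "must be supplied")
      }
      pool <- build_training_set(svmap, truth, purity = config$purity,
                                 per_category_n = NULL, seed = config$seed)
      training_set <- sample_training_fraction(pool, config$training_fraction,
                                               seed = config$seed)
    }
    model <- if (config$classifier == "svm") {
      train_svm(training_set, seed = config$seed,
                log2C = config$svm_log2C, log2gamma = config$svm_log2gamma)
    } else {
      train_rf(training_set, n_trees = config$rf_n_trees,
               features_per_node = config$rf_features_per_node,
               seed = config$seed)
    }
  }
  proba <- predict_proba(model, svmap$features)
  maps <- broadcast_probabilities(svmap, proba)
  maps <- smooth_probability_maps(maps, config$smooth_size,
                                  config$smooth_sigma)
  labels <- argmax_labels(maps)
  pre_vol <- series$volumes[[series$pre_contrast_index]]
  body <- body_mask(pre_vol)
  labels[!body] <- 0L
  soft_organs <- setdiff(config$priority, "bone")
  masks <- lapply(soft_organs, function(o) {
    extract_organ(labels, o, opening_radius = config$opening_radius)
  })
  names(masks) <- soft_organs
  ref_vol <- series$volumes[[.reference_index(series,
                                              config$reference_time_s)]]
  if ("bone" %in% config$priority) {
    masks$bone <- segment_bone(pre_vol, ref_vol,
                               dilation_radius = config$bone_dilation_radius)
  }
  result <- integrate_masks(masks, priority = config$priority)
  out <- list(result = result, model = model, svmap = svmap,
              training_set = training_set, config = config,
              explained_ratio = feats$basis$explained_ratio)
  if (keep_intermediates) {
    out$scores <- feats$scores
    out$prob_maps <- maps
  }
  structure(out, class = "dce_segmentation")
}

#' @export
print.dce_segmentation <- function(x, ...) {
  cat("dceseg pipeline run (", x$config$classifier, " classifier, ",
      x$svmap$k, " supervoxels)\n", sep = "")
  print(x$result)
  invisible(x)
}
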