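#' Reference per-category training-pool sizes
#'
#' Per-category supervoxel counts used as the default size of the "total
#' data set" from which training subsets are drawn, reflecting the relative
#' abundance of the ten tissue categories in a whole-body mouse acquisition
#' (large context classes such as intestine and fat/muscle contribute more
#' supervoxels than small organs like the spleen).
#'
#' @return Named integer vector over [dce_categories()].
#' @export
reference_category_counts <- function() {
  c(heart = 36L, liver = 54L, spleen = 19L, lung = 40L, kidney = 36L,
    bone = 34L, intestinal_wall = 60L, intestinal_cavity = 60L,
    fat_muscle = 76L, skin_adherent = 36L)
}

.sv_category_fractions <- function(sv_labels, truth, k) {
  n_cat <- length(dce_categories())
  idx <- as.vector(sv_labels) + k * as.vector(truth) # truth 0..n_cat
  counts <- tabulate(idx, nbins = k * (n_cat + 1L))
  counts <- matrix(counts, nrow = k)[, -1L, drop = FALSE] # drop background
  size <- tabulate(as.vector(sv_labels), nbins = k)
  list(counts = counts, size = size)
}

#' Build a labeled training set from supervoxels and ground truth
#'
#' A supervoxel enters the training pool of category c if at least `purity`
#' of its voxels carry ground-truth label c; purity > 0.5 guarantees each
#' supervoxel is eligible for at most one category. From each category's
#' pool, up to `per_category_n[c]` supervoxels are sampled without
#' replacement (seeded). This emulates selecting training supervoxels from
#' different parts of each (possibly heterogeneous) organ.
#'
#' @param svmap A [slic_supervoxels()] result.
#' @param truth Integer ground-truth label volume on the same grid
#'   (category ids per [dce_categories()], 0 = background).
#' @param purity Minimum pure-voxel fraction, in (0.5, 1].
#' @param per_category_n Named vector of pool sizes per category (defaults
#'   to [reference_category_counts()], capped at the number of eligible
#'   supervoxels); `NULL` entries or `Inf` take every eligible supervoxel.
#' @param seed Integer seed for the sampling.
#' @return An object of class `training_set`: a data.frame with columns
#'   `id` (supervoxel label), `b1..bn` (mean features) and `category`
#'   (factor), plus attributes `eligible` (per-category eligible counts).
#' @export
build_training_set <- function(svmap, truth, purity = 0.8,
                               per_category_n = reference_category_counts(),
                               seed = 1L) {
  stopifnot(inherits(svmap, "supervoxel_map"),
            identical(dim(truth), dim(svmap$labels)),
            purity > 0.5, purity <= 1)
  storage.mode(truth) <- "integer"
  cats <- dce_categories()
  fr <- .sv_category_fractions(svmap$labels, truth, svmap$k)
  frac <- fr$counts / fr$size
  present <- cats[sort(unique(as.vector(truth[truth > 0L])))]
  eligible <- lapply(seq_along(cats), function(ci) which(frac[, ci] >= purity))
  names(eligible) <- cats
  none <- present[vapply(eligible[present], length, 1L) == 0L]
  if (length(none) > 0) {
    stop("no eligible supervoxels at purity ", purity, " for: ",
         paste(none, collapse = ", "))
  }
  if (is.null(per_category_n)) {
    per_category_n <- stats::setNames(rep(Inf, length(cats)), cats)
  }
  set.seed(seed)
  rows <- list()
  for (cat in present) {
    pool <- eligible[[cat]]
    n_want <- per_category_n[[cat]]
    if (is.null(n_want) || !is.finite(n_want)) n_want <- length(pool)
    n_take <- min(length(pool), n_want)
    take <- sort(pool[sample.int(length(pool), n_take)])
    rows[[cat]] <- take
  }
  ids <- unlist(rows, use.names = FALSE)
  labs <- rep(names(rows), vapply(rows, length, 1L))
  fm <- svmap$features[ids, , drop = FALSE]
  colnames(fm) <- paste0("b", seq_len(ncol(fm)))
  ts <- data.frame(id = ids, fm,
                   category = factor(labs, levels = intersect(cats, present)))
  attr(ts, "eligible") <- vapply(eligible[present], length, 1L)
  class(ts) <- c("training_set", "data.frame")
  ts
}

#' Subsample a training set per category
#'
#' Draws `fraction` of each category's rows without replacement (seeded, at
#' least one row per category), as in training-size experiments that train
#' on 10--90\% of a fixed total data set.
#'
#' @param ts A [build_training_set()] result.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return A `training_set` with the sampled rows.
#' @export
sample_training_fraction <- function(ts, fraction, seed = 1L) {
  stopifnot(inherits(ts, "training_set"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(ts)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(ts)), ts$category), function(ix) {
    n_take <- max(1L, round(fraction * length(ix)))
    sort(ix[sample.int(length(ix), n_take)])
  }), use.names = FALSE)
  out <- ts[sort(keep), , drop = FALSE]
  class(out) <- c("training_set", "data.frame")
  out
}

.feature_cols <- function(ts) {
  grep("^b[0-9]+$", colnames(ts), value = TRUE)
}

.stratified_folds <- function(y, ids, k, seed) {
  # fold membership depends only on (seed, ids, classes), not on row order
  folds <- integer(length(y))
  set.seed(seed)
  for (lev in levels(y)) {
    ix <- which(y == lev)
    ix <- ix[order(ids[ix])]
    folds[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
  }
  folds
}

#' Train an RBF-kernel SVM with grid-searched hyperparameters
#'
#' The cost C and kernel shape gamma are selected by exhaustive search over
#' integer powers of two (defaults: 21 C-values 2^-5..2^15 and 31
#' gamma-values 2^-15..2^15, i.e. 651 pairs), scoring each pair by the
#' pooled misclassification fraction of a stratified 5-fold cross-validation
#' with seeded fold assignment. Ties prefer the smaller C, then the smaller
#' gamma (the smoother model). The winning pair is refit on the full
#' training set.
#'
#' Probability estimates are derived from the decision function of the
#' one-vs-one multiclass scheme: with `probability = "votes"` (default) the
#' per-category probability is its fraction of the pairwise decision votes
#' — the direct analog of the random forest's averaged tree votes, and
#' insensitive to per-category training-set size. `probability = "platt"`
#' instead uses pairwise-coupled sigmoid-calibrated probabilities (the
#' calibration's internal cross-validation is seeded); note that with very
#' unbalanced training sets Platt calibration systematically assigns small
#' categories lower confidence, which biases the downstream smoothed argmax
#' against them.
#'
#' @param ts A [build_training_set()] result with at least two categories.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed (fold assignment and probability calibration).
#' @param log2C,log2gamma Integer exponents defining the search grid.
#' @param probability Probability-estimate method, `"margin"` or `"platt"`.
#' @param sigmoid_slope Slope of the fixed sigmoid mapping decision values
#'   to pairwise probabilities; the default 4 maps a unit functional margin
#'   (the distance of the canonical SVM margin) to ~0.98 confidence.
#' @return An object of class `dce_classifier` (kind `"svm"`) with the
#'   fitted model, chosen `C`, `gamma`, the CV error surface and the
#'   category levels.
#' @export
train_svm <- function(ts, folds = 5L, seed = 1L,
                      log2C = -5:15, log2gamma = -15:15,
                      probability = c("margin", "platt"),
                      sigmoid_slope = 4) {
  probability <- match.arg(probability)
  stopifnot(inherits(ts, "training_set"))
  y <- droplevels(ts$category)
  if (nlevels(y) < 2L) stop("SVM training needs at least two categories")
  small <- table(y) < folds
  if (any(small)) {
    warning("fewer than ", folds, " samples for: ",
            paste(names(small)[small], collapse = ", "))
  }
  X <- as.matrix(ts[, .feature_cols(ts), drop = FALSE])
  ord <- order(ts$id)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  fold <- .stratified_folds(y, ts$id[ord], folds, seed)
  grid <- expand.grid(log2gamma = log2gamma, log2C = log2C)
  cv_err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    C <- 2^grid$log2C[g]
    gamma <- 2^grid$log2gamma[g]
    wrong <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (all(tr) || !any(tr)) next
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = gamma, scale = FALSE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      wrong <- wrong + sum(pred != y[!tr])
    }
    cv_err[g] <- wrong / length(y)
  }
  # smallest CV error; ties -> smaller C, then smaller gamma
  best <- order(cv_err, grid$log2C, grid$log2gamma)[1]
  C <- 2^grid$log2C[best]
  gamma <- 2^grid$log2gamma[best]
  set.seed(seed)
  model <- e1071::svm(X, y, kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE, probability = probability == "platt")
  structure(list(kind = "svm", model = model, C = C, gamma = gamma,
                 probability = probability, sigmoid_slope = sigmoid_slope,
                 log2C = grid$log2C[best], log2gamma = grid$log2gamma[best],
                 cv_error = cv_err[best],
                 cv_surface = cbind(grid, error = cv_err),
                 categories = levels(y), n_features = ncol(X), seed = seed),
            class = "dce_classifier")
}

#' Train a random-forest classifier
#'
#' An ensemble of `n_trees` decision trees with `features_per_node`
#' candidate features per split; the per-category probability of a sample is
#' the fraction of trees voting for that category.
#'
#' @param ts A [build_training_set()] result.
#' @param n_trees Number of trees.
#' @param features_per_node Candidate features per split; must be smaller
#'   than the number of features.
#' @param seed Integer seed (bagging and split sampling).
#' @return A `dce_classifier` (kind `"rf"`, or `"constant"` for the
#'   degenerate single-category training set).
#' @export
train_rf <- function(ts, n_trees = 500L, features_per_node = 2L, seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  X <- as.matrix(ts[, .feature_cols(ts), drop = FALSE])
  if (features_per_node >= ncol(X)) {
    stop("features_per_node (", features_per_node,
         ") must be smaller than the number of features (", ncol(X), ")")
  }
  y <- droplevels(ts$category)
  if (nlevels(y) < 2L) {
    return(structure(list(kind = "constant", categories = levels(y),
                          n_features = ncol(X), seed = seed),
                     class = "dce_classifier"))
  }
  ord <- order(ts$id)
  set.seed(seed)
  model <- randomForest::randomForest(X[ord, , drop = FALSE], y[ord],
                                      ntree = n_trees,
                                      mtry = features_per_node)
  structure(list(kind = "rf", model = model, n_trees = n_trees,
                 features_per_node = features_per_node,
                 categories = levels(y), n_features = ncol(X), seed = seed),
            class = "dce_classifier")
}

#' @export
print.dce_classifier <- function(x, ...) {
  cat("dceseg classifier:", x$kind, "\n")
  if (x$kind == "svm") {
    cat(sprintf("  C = 2^%d, gamma = 2^%d, CV error = %.4f\n",
                x$log2C, x$log2gamma, x$cv_error))
  } else if (x$kind == "rf") {
    cat("  trees:", x$n_trees, " features/node:", x$features_per_node, "\n")
  }
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Per-category probabilities for supervoxel feature vectors
#'
#' @param model A [train_svm()] / [train_rf()] classifier.
#' @param features Numeric matrix (rows = supervoxels, columns = the n
#'   features the model was trained on) or a `training_set`.
#' @return Matrix of probabilities, one row per input row summing to 1,
#'   columns named by `model$categories` in fixed order.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "dce_classifier"))
  if (inherits(features, "training_set") || is.data.frame(features)) {
    features <- as.matrix(features[, .feature_cols(features), drop = FALSE])
  }
  if (ncol(features) != model$n_features) {
    stop("feature dimension ", ncol(features), " does not match model (",
         model$n_features, ")")
  }
  cats <- model$categories
  if (model$kind == "constant") {
    p <- matrix(1, nrow = nrow(features), ncol = 1L,
                dimnames = list(NULL, cats))
    return(p)
  }
  colnames(features) <- paste0("b", seq_len(ncol(features)))
  if (model$kind == "svm") {
    if (identical(model$probability, "platt")) {
      pred <- stats::predict(model$model, features, probability = TRUE)
      p <- attr(pred, "probabilities")
    } else {
      pred <- stats::predict(model$model, features, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # pairwise coupling of sigmoid-mapped decision values with a fixed
      # slope (no per-pair calibration, so the confidence of a category
      # does not depend on its training-set size):
      #   p_i  proportional to  1 / (sum_j 1/r_ij - (k - 2)),
      # r_ij the sigmoid of the (i vs j) decision value
      K <- length(cats)
      inv_sum <- matrix(0, nrow(features), K, dimnames = list(NULL, cats))
      pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
      eps <- 1e-6
      a <- if (is.null(model$sigmoid_slope)) 4 else model$sigmoid_slope
      for (j in seq_along(pairs)) {
        # libsvm convention: a positive "A/B" decision value favors A
        r <- pmin(pmax(stats::plogis(a * dv[, j]), eps), 1 - eps)
        inv_sum[, pairs[[j]][1]] <- inv_sum[, pairs[[j]][1]] + 1 / r
        inv_sum[, pairs[[j]][2]] <- inv_sum[, pairs[[j]][2]] + 1 / (1 - r)
      }
      p <- 1 / (inv_sum - (K - 2))
      p <- p / rowSums(p)
    }
    p <- p[, cats, drop = FALSE]
  } else {
    p <- stats::predict(model$model, features, type = "prob")
    p <- p[, cats, drop = FALSE]
  }
  rownames(p) <- NULL
  p
}
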