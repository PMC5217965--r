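#' Build the voxel-by-time intensity matrix
#'
#' Reshapes each 3D volume of the series to a column and stacks the columns
#' into a V x T matrix whose rows are the individual signal-versus-time
#' curves (V voxels, T time points, columns in acquisition order).
#'
#' @param series A [dce_series()].
#' @return An object of class `time_matrix` with fields `values` (V x T
#'   matrix) and `shape` (the original 3D grid, for the inverse reshape).
#' @export
build_time_matrix <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  shape <- dim(series$volumes[[1]])
  values <- vapply(series$volumes, as.vector, numeric(prod(shape)))
  structure(list(values = values, shape = shape), class = "time_matrix")
}

#' Reshape one time-matrix column back to a 3D volume
#'
#' @param tm A [build_time_matrix()] result.
#' @param t Time-point (column) index.
#' @return 3D array of the original grid shape.
#' @export
time_matrix_volume <- function(tm, t) {
  stopifnot(inherits(tm, "time_matrix"))
  array(tm$values[, t], dim = tm$shape)
}

#' Principal component analysis of the temporal curves
#'
#' Column (per-time-point) means are subtracted, then the centered matrix is
#' decomposed by singular value decomposition. The temporal components are
#' orthonormal T-vectors ordered by decreasing explained variance; the
#' scores are the weights of each component in each voxel's curve. To make
#' the (intrinsically sign-ambiguous) decomposition deterministic, each
#' component is flipped so its largest-magnitude coefficient is positive.
#'
#' @param tm A [build_time_matrix()] result, with at least as many voxels as
#'   time points.
#' @return An object of class `pca_basis` with fields `components` (T x T,
#'   columns = temporal patterns), `explained_ratio` (fractions of total
#'   variance, nonincreasing, summing to 1), `scores` (V x T), `center`
#'   (column means) and `shape`.
#' @export
fit_pca <- function(tm) {
  stopifnot(inherits(tm, "time_matrix"))
  X <- tm$values
  if (nrow(X) < ncol(X)) stop("need at least as many voxels as time points")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = 0)
  comp <- sv$v
  # deterministic sign: largest-|coefficient| entry of each component > 0
  for (k in seq_len(ncol(comp))) {
    j <- which.max(abs(comp[, k]))
    if (comp[j, k] < 0) comp[, k] <- -comp[, k]
  }
  tot <- sum(sv$d^2)
  if (tot <= .Machine$double.eps * nrow(X)) {
    warning("input has no temporal variance; all explained ratios set to 0")
    ratio <- rep(0, ncol(X))
  } else {
    ratio <- sv$d^2 / tot
  }
  scores <- Xc %*% comp
  structure(list(components = comp, explained_ratio = ratio,
                 scores = scores, center = center, shape = tm$shape),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("Temporal PCA basis:", ncol(x$components), "components\n")
  cat("  explained variance:",
      paste(sprintf("%.4f", x$explained_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Min-max normalized principal-component score volumes
#'
#' Takes the first `n` score columns, min-max normalizes each over the whole
#' volume to [0, 1], and reshapes them to the 3D grid. These are the per-voxel
#' features used for supervoxel generation and classification. A constant
#' score column cannot be normalized and is set to all zeros with a warning.
#'
#' @param basis A [fit_pca()] result.
#' @param n Number of components to keep (1..T). If `NULL`, the smallest n
#'   whose cumulative explained variance reaches `cum_var` is used.
#' @param cum_var Cumulative-variance threshold for automatic n selection.
#' @return An object of class `score_volumes`: a list with `channels` (list
#'   of n 3D arrays in [0,1]) and `n`.
#' @export
score_volumes <- function(basis, n = 4L, cum_var = 0.99) {
  stopifnot(inherits(basis, "pca_basis"))
  Tn <- ncol(basis$scores)
  if (is.null(n)) {
    n <- which(cumsum(basis$explained_ratio) >= cum_var)[1]
    if (is.na(n)) n <- Tn
  }
  n <- as.integer(n)
  stopifnot(n >= 1L, n <= Tn)
  channels <- vector("list", n)
  for (k in seq_len(n)) {
    s <- basis$scores[, k]
    rng <- range(s)
    if (diff(rng) <= 0) {
      warning("score column ", k, " is constant; channel set to all zeros")
      s <- rep(0, length(s))
    } else {
      s <- (s - rng[1]) / (rng[2] - rng[1])
    }
    channels[[k]] <- array(s, dim = basis$shape)
  }
  structure(list(channels = channels, n = n), class = "score_volumes")
}

#' Stack score channels into one 4D array
#'
#' @param scores A [score_volumes()] result.
#' @return 4D array with the channel as the fourth dimension.
#' @export
score_array <- function(scores) {
  stopifnot(inherits(scores, "score_volumes"))
  d <- dim(scores$channels[[1]])
  arr <- array(0, dim = c(d, scores$n))
  for (k in seq_len(scores$n)) arr[, , , k] <- scores$channels[[k]]
  arr
}

#' Relative signal enhancement of a region
#'
#' Computes R_t = (T_t - T_0) / T_0 for each post-contrast time point, where
#' T_0 and T_t are the mean intensities of the region on the pre-contrast and
#' post-contrast volumes. Averaging over a region (rather than a single
#' voxel) suppresses noise.
#'
#' @param series A [dce_series()].
#' @param region Voxels defining the region: a logical array of the grid
#'   shape, or an integer matrix of (x, y, z) rows, or a vector of linear
#'   indices. Must be nonempty.
#' @return Named numeric vector of R_t values, one per post-contrast time
#'   point (names = acquisition times in seconds).
#' @export
relative_enhancement <- function(series, region) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$volumes[[1]])
  if (is.logical(region)) {
    stopifnot(identical(dim(region), d))
    idx <- which(region)
  } else if (is.matrix(region)) {
    stopifnot(ncol(region) == 3L,
              all(region >= 1L), all(region <= rep(d, each = nrow(region))))
    idx <- region[, 1] + d[1] * (region[, 2] - 1L) +
      d[1] * d[2] * (region[, 3] - 1L)
  } else {
    idx <- as.integer(region)
    stopifnot(all(idx >= 1L), all(idx <= prod(d)))
  }
  if (length(idx) == 0L) stop("region is empty")
  pre <- series$pre_contrast_index
  t0 <- mean(series$volumes[[pre]][idx])
  if (t0 == 0) stop("mean pre-contrast intensity is zero; R_t undefined")
  post <- setdiff(seq_along(series$volumes), pre)
  rt <- vapply(post, function(t) {
    (mean(series$volumes[[t]][idx]) - t0) / t0
  }, numeric(1))
  names(rt) <- series$times_s[post]
  rt
}
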