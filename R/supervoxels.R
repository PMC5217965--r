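#' Additive feature + spatial SLIC distance
#'
#' The clustering distance combines a feature term (root-mean-square
#' difference over the n score channels, normalized by the compactness m)
#' and a spatial term (Euclidean voxel distance normalized by the seed
#' interval S):
#' \deqn{D = \sqrt{\tfrac{1}{n}\sum_k (b_{jk}-b_{ik})^2}/m +
#'       \sqrt{\sum_k (x_{jk}-x_{ik})^2}/S}
#' Both terms are dimensionless, so m directly trades boundary adherence
#' against spatial compactness. An alternative quadrature combination
#' \eqn{\sqrt{(f/m)^2 + (s/S)^2}} (the original SLIC form) is available via
#' `combine = "quadrature"`.
#'
#' @param feat_i,feat_j Feature vectors (length n).
#' @param pos_i,pos_j Spatial positions (length 3, voxels).
#' @param m Compactness (> 0).
#' @param S Seed interval (> 0, voxels).
#' @param combine `"additive"` (default) or `"quadrature"`.
#' @return Nonnegative scalar distance; zero iff features and positions are
#'   identical.
#' @export
slic_distance <- function(feat_i, pos_i, feat_j, pos_j, m, S,
                          combine = c("additive", "quadrature")) {
  combine <- match.arg(combine)
  if (length(feat_i) != length(feat_j)) {
    stop("feature vectors differ in length")
  }
  if (length(pos_i) != 3L || length(pos_j) != 3L) {
    stop("positions must have length 3")
  }
  stopifnot(m > 0, S > 0)
  fd <- sqrt(mean((feat_j - feat_i)^2))
  sd_ <- sqrt(sum((pos_j - pos_i)^2))
  if (combine == "additive") fd / m + sd_ / S
  else sqrt((fd / m)^2 + (sd_ / S)^2)
}

#' Initialize SLIC cluster centers
#'
#' Centers start on a regular lattice of spacing `S` voxels and are then
#' moved to the position with the lowest feature-gradient magnitude within
#' their 3x3x3 neighborhood, so that no seed sits on an edge. The gradient
#' is the sum over channels of the squared central intensity differences
#' along the three axes. Ties keep the original lattice position.
#'
#' @param scores A [score_volumes()] result (or a 4D feature array).
#' @param S Seed interval in voxels.
#' @return Matrix with one row per center: columns `x`, `y`, `z` (1-based
#'   voxel coordinates) followed by the feature vector at that position.
#' @export
init_centers <- function(scores, S) {
  arr <- if (inherits(scores, "score_volumes")) score_array(scores) else scores
  stopifnot(length(dim(arr)) == 4L, S >= 1L)
  cen <- cpp_seed_centers(arr, as.integer(S))
  cen[, 1:3] <- cen[, 1:3] + 1  # 0-based C++ -> 1-based R coordinates
  colnames(cen) <- c("x", "y", "z",
                     paste0("b", seq_len(ncol(cen) - 3L)))
  cen
}

#' Generate supervoxels by n-feature 3D SLIC
#'
#' Localized k-means over the joint (feature, position) space: centers are
#' seeded on an S-lattice ([init_centers()]), each center competes only for
#' voxels within its 2S x 2S x 2S window under the [slic_distance()], and
#' centers are updated to member means each iteration. After convergence (no
#' assignment changes) or `max_iter` iterations, connectivity of every
#' supervoxel is enforced ([enforce_connectivity()]): fragments smaller than
#' `min_size` are absorbed by their largest neighbor. The algorithm is fully
#' deterministic.
#'
#' @param scores A [score_volumes()] result (or 4D feature array with
#'   channels in [0,1]).
#' @param S Seed interval, voxels (>= 2); supervoxels have roughly S^3
#'   voxels.
#' @param m Compactness (see [slic_distance()]).
#' @param max_iter Maximum clustering iterations.
#' @param min_size Minimum supervoxel size retained by connectivity
#'   enforcement; defaults to `ceiling(S^3 / 4)`.
#' @return An object of class `supervoxel_map`: fields `labels` (3D integer
#'   array, values 1..k), `size`, `center` (k x 3 mean positions), `features`
#'   (k x n mean score vectors), `k`, `N` and `params`.
#' @export
slic_supervoxels <- function(scores, S = 8L, m = 0.02, max_iter = 10L,
                             min_size = NULL) {
  arr <- if (inherits(scores, "score_volumes")) score_array(scores) else scores
  stopifnot(length(dim(arr)) == 4L, S >= 2L, m > 0, max_iter >= 1L)
  if (is.null(min_size)) min_size <- ceiling(S^3 / 4)
  cen <- cpp_seed_centers(arr, as.integer(S))
  res <- cpp_slic_iterate(arr, cen, as.integer(S), m, as.integer(max_iter))
  labels <- cpp_enforce_connectivity(res$labels, as.integer(min_size))
  stats <- cpp_label_stats(labels, arr)
  structure(list(labels = labels, size = as.integer(stats$size),
                 center = stats$center, features = stats$features,
                 k = nrow(stats$center), N = length(labels),
                 params = list(S = as.integer(S), m = m,
                               n = dim(arr)[4], max_iter = max_iter,
                               min_size = min_size,
                               iterations = res$iterations)),
            class = "supervoxel_map")
}

#' @export
print.supervoxel_map <- function(x, ...) {
  cat("Supervoxel map:", x$k, "supervoxels over", x$N, "voxels",
      sprintf("(S=%d, m=%g, n=%d)\n", x$params$S, x$params$m, x$params$n))
  cat("  sizes: min", min(x$size), "median", stats::median(x$size),
      "max", max(x$size), "\n")
  invisible(x)
}

#' Enforce 26-connectivity of a supervoxel label map
#'
#' Splits every label into its 26-connected components; each label's largest
#' component keeps the label, fragments of at least `min_size` voxels become
#' supervoxels of their own, and smaller fragments are merged into their
#' largest 26-adjacent neighbor. Every voxel stays labeled and output labels
#' are contiguous 1..k.
#'
#' @param labels 3D positive-integer array.
#' @param min_size Minimum fragment size kept as an independent supervoxel.
#' @return Relabeled 3D integer array in which every label is 26-connected.
#' @export
enforce_connectivity <- function(labels, min_size) {
  stopifnot(length(dim(labels)) == 3L, min_size >= 1)
  storage.mode(labels) <- "integer"
  cpp_enforce_connectivity(labels, as.integer(min_size))
}

#' Per-supervoxel mean feature vectors
#'
#' The classifier operates on one feature vector per supervoxel: the mean of
#' the n score channels over the supervoxel's voxels.
#'
#' @param svmap A [slic_supervoxels()] result (or a bare 3D label array).
#' @param scores A [score_volumes()] result (or 4D feature array) on the
#'   same grid.
#' @return Numeric matrix (k x n) of mean features; row i belongs to label i.
#' @export
mean_features <- function(svmap, scores) {
  labels <- if (inherits(svmap, "supervoxel_map")) svmap$labels else svmap
  arr <- if (inherits(scores, "score_volumes")) score_array(scores) else scores
  stopifnot(identical(dim(labels), dim(arr)[1:3]))
  storage.mode(labels) <- "integer"
  st <- cpp_label_stats(labels, arr)
  fm <- st$features
  colnames(fm) <- paste0("b", seq_len(ncol(fm)))
  fm
}

#' Supervoxel feature table
#'
#' @param svmap A [slic_supervoxels()] result.
#' @return data.frame with columns label, b1..bn, size, x, y, z — the CSV
#'   layout used by the CLI.
#' @export
supervoxel_table <- function(svmap) {
  stopifnot(inherits(svmap, "supervoxel_map"))
  fm <- svmap$features
  colnames(fm) <- paste0("b", seq_len(ncol(fm)))
  data.frame(label = seq_len(svmap$k), fm, size = svmap$size,
             x = svmap$center[, 1], y = svmap$center[, 2],
             z = svmap$center[, 3])
}
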