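#' Broadcast supervoxel probabilities to voxels
#'
#' Every voxel receives the probability row of the supervoxel it belongs
#' to, producing one 3D probability volume per category.
#'
#' @param svmap A [slic_supervoxels()] result (or a 3D label array).
#' @param proba Probability matrix from [predict_proba()]: one row per
#'   supervoxel label (row i = label i), columns named by category.
#' @return An object of class `probability_maps`: a list with `array` (4D,
#'   category as 4th dimension) and `categories`.
#' @export
broadcast_probabilities <- function(svmap, proba) {
  labels <- if (inherits(svmap, "supervoxel_map")) svmap$labels else svmap
  stopifnot(length(dim(labels)) == 3L, is.matrix(proba))
  if (max(labels) > nrow(proba)) {
    stop("probability rows missing for labels ", nrow(proba) + 1L, "..",
         max(labels))
  }
  if (is.null(colnames(proba))) stop("probability columns must be named")
  d <- dim(labels)
  n_cat <- ncol(proba)
  arr <- array(0, dim = c(d, n_cat))
  idx <- as.vector(labels)
  for (k in seq_len(n_cat)) {
    arr[, , , k] <- proba[idx, k]
  }
  structure(list(array = arr, categories = colnames(proba)),
            class = "probability_maps")
}

.gaussian_kernel1d <- function(size, sigma) {
  r <- (size - 1L) / 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian smoothing of probability maps
#'
#' Convolves each category's probability volume with a normalized, sampled,
#' truncated Gaussian (size^3 kernel, standard deviation `sigma`), with
#' mirror reflection at the volume faces. Because one normalized kernel is
#' shared by all categories, the per-voxel probability sum stays 1.
#'
#' @param maps A [broadcast_probabilities()] result.
#' @param size Odd kernel size in voxels.
#' @param sigma Gaussian standard deviation in voxels.
#' @return Smoothed `probability_maps`.
#' @export
smooth_probability_maps <- function(maps, size = 9L, sigma = 3) {
  stopifnot(inherits(maps, "probability_maps"), sigma > 0)
  if (size %% 2L == 0L) stop("kernel size must be odd")
  k1 <- .gaussian_kernel1d(size, sigma)
  arr <- maps$array
  for (k in seq_len(dim(arr)[4])) {
    arr[, , , k] <- cpp_sep_conv3(arr[, , , k], k1)
  }
  structure(list(array = arr, categories = maps$categories),
            class = "probability_maps")
}

#' The separable Gaussian kernel as a full 3D array
#'
#' @param size Odd kernel size; @param sigma standard deviation (voxels).
#' @return size^3 array summing to 1.
#' @export
gaussian_kernel3d <- function(size = 9L, sigma = 3) {
  k1 <- .gaussian_kernel1d(size, sigma)
  outer(outer(k1, k1), k1)
}

#' Label each voxel with its most probable category
#'
#' @param maps A `probability_maps` object.
#' @return 3D integer array of category ids (per [dce_categories()]); exact
#'   ties go to the category earliest in the maps' column order.
#' @export
argmax_labels <- function(maps) {
  stopifnot(inherits(maps, "probability_maps"))
  d <- dim(maps$array)
  P <- matrix(maps$array, nrow = prod(d[1:3]), ncol = d[4])
  loc <- max.col(P, ties.method = "first")
  ids <- category_id(maps$categories)
  array(ids[loc], dim = d[1:3])
}

.disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, ]
  cbind(as.integer(g$dx), as.integer(g$dy), 0L)
}

.ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ]
  cbind(as.integer(g$dx), as.integer(g$dy), as.integer(g$dz))
}

.as_mask <- function(x) {
  m <- array(as.integer(x != 0), dim = dim(x))
  m
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the same structuring element: a
#' radius-`radius` disk applied slice-wise in the axial (fixed-z) plane by
#' default, or a full 3D ball with `element = "ball"`.
#'
#' @param mask 3D logical/0-1 array.
#' @param radius Element radius in voxels.
#' @param element `"disk"` (2D, per axial slice) or `"ball"` (3D).
#' @return Opened 0/1 integer array.
#' @export
binary_opening <- function(mask, radius = 2L, element = c("disk", "ball")) {
  element <- match.arg(element)
  off <- if (element == "disk") .disk_offsets(radius) else
    .ball_offsets(radius)
  m <- .as_mask(mask)
  cpp_binary_morph(cpp_binary_morph(m, off, TRUE), off, FALSE)
}

#' Dilate a binary mask with a 3D ball
#'
#' @param mask 3D logical/0-1 array; @param radius ball radius in voxels.
#' @return Dilated 0/1 integer array.
#' @export
binary_dilation <- function(mask, radius = 3L) {
  cpp_binary_morph(.as_mask(mask), .ball_offsets(radius), FALSE)
}

#' Fill enclosed cavities of a binary mask
#'
#' Background voxels with no 6-connected path to the volume boundary are
#' turned on.
#'
#' @param mask 3D logical/0-1 array.
#' @return 0/1 integer array with holes filled.
#' @export
fill_holes <- function(mask) {
  cpp_fill_holes(.as_mask(mask))
}

#' Connected components of a mask or label volume
#'
#' Voxels are connected when they are neighbors (under the chosen
#' connectivity) and carry the same nonzero value, so a binary mask yields
#' its foreground components and an integer label volume yields the
#' components of every label.
#'
#' @param mask 3D logical/integer array; 0/FALSE is background.
#' @param connectivity 26 (default) or 6.
#' @return 3D integer array of component ids (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  m <- array(as.integer(mask), dim = dim(mask))
  cpp_label_components(m, as.integer(connectivity))
}

#' Extract one organ mask from a hard label volume
#'
#' The category's voxels are binarized, cleaned by a morphological opening
#' (radius-`opening_radius` disk per axial slice), reduced to their dominant
#' connected components, and hole-filled. Component analysis keeps the
#' largest component plus every component of at least half its size, so
#' paired organs (the two kidneys, the two lung lobes) survive while small
#' spurious islands are dropped.
#'
#' @param labels 3D integer label volume (category ids).
#' @param category Category name (see [dce_categories()]).
#' @param opening_radius Disk radius for the opening, voxels.
#' @param element Structuring element passed to [binary_opening()].
#' @param connectivity Component connectivity (26 or 6).
#' @param keep_ratio Keep every component whose size is at least
#'   `keep_ratio` times the largest one.
#' @return 3D logical organ mask.
#' @export
extract_organ <- function(labels, category, opening_radius = 2L,
                          element = "disk", connectivity = 26L,
                          keep_ratio = 0.5) {
  id <- category_id(category)
  mask <- .as_mask(labels == id)
  if (!any(mask == 1L)) {
    warning("category '", category, "' absent from labels; empty mask")
    return(array(FALSE, dim = dim(labels)))
  }
  opened <- binary_opening(mask, opening_radius, element)
  if (!any(opened == 1L)) {
    warning("mask for '", category, "' vanished under opening; empty mask")
    return(array(FALSE, dim = dim(labels)))
  }
  comp <- cpp_label_components(opened, as.integer(connectivity))
  sizes <- tabulate(comp[comp > 0L])
  keep <- which(sizes >= keep_ratio * max(sizes))
  kept <- array(as.integer(comp %in% keep & comp > 0L), dim = dim(labels))
  filled <- cpp_fill_holes(kept)
  array(filled == 1L, dim = dim(labels))
}

#' Histogram threshold between soft tissue and bone
#'
#' Two-stage histogram analysis of an intensity volume: first Otsu's
#' criterion separates air from tissue; the mode of the tissue intensities
#' is taken as the soft-tissue peak; Otsu applied to the intensities above
#' that peak then yields the soft-tissue/bone threshold.
#'
#' @param vol 3D intensity volume.
#' @param bins Number of histogram bins per Otsu stage.
#' @return Scalar threshold (intensity units).
#' @export
bone_threshold <- function(vol, bins = 256L) {
  v <- as.vector(vol)
  thr_air <- .otsu(v, bins)
  tissue <- v[v > thr_air]
  if (length(tissue) == 0L) stop("no voxels above the air threshold")
  h <- graphics::hist(tissue, breaks = bins, plot = FALSE)
  mode_val <- h$mids[which.max(h$counts)]
  upper <- v[v > mode_val]
  if (length(upper) < 2L) stop("no intensities above the soft-tissue mode")
  .otsu(upper, bins)
}

.otsu <- function(values, bins = 256L) {
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # all bins across an empty histogram gap tie for the maximum; take the
  # middle of the tied region (threshold = upper edge of that bin)
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  mean(h$breaks[best + 1L])
}

#' Threshold-based bone segmentation
#'
#' Bone is brighter than every (even contrast-enhanced) soft tissue on the
#' pre-contrast scan, so a histogram threshold recovers it there. On
#' post-contrast scans strongly enhancing organs may cross the same
#' threshold; thresholding is therefore restricted to a region of interest
#' obtained by dilating the pre-contrast bone, which tolerates small rigid
#' displacements between scans while excluding enhanced organs elsewhere.
#'
#' @param pre_volume Pre-contrast 3D intensity volume.
#' @param post_volume Post-contrast volume at the reference time point
#'   (aligned grid).
#' @param threshold Intensity threshold; `NULL` derives it from the
#'   pre-contrast histogram via [bone_threshold()].
#' @param dilation_radius Ball radius (voxels) for the ROI dilation.
#' @return 3D logical bone mask on the post-contrast reference volume.
#' @export
segment_bone <- function(pre_volume, post_volume, threshold = NULL,
                         dilation_radius = 3L) {
  stopifnot(identical(dim(pre_volume), dim(post_volume)))
  if (is.null(threshold)) {
    threshold <- bone_threshold(pre_volume)
  } else {
    h <- graphics::hist(pre_volume[pre_volume > 0], breaks = 256L,
                        plot = FALSE)
    if (threshold < h$mids[which.max(h$counts)]) {
      warning("bone threshold ", threshold,
              " lies below the soft-tissue mode; the mask will leak")
    }
  }
  pre_bone <- .as_mask(pre_volume > threshold)
  if (!any(pre_bone == 1L)) {
    warning("no pre-contrast voxels above the bone threshold; empty mask")
    return(array(FALSE, dim = dim(pre_volume)))
  }
  roi <- binary_dilation(pre_bone, dilation_radius)
  array(post_volume > threshold & roi == 1L, dim = dim(pre_volume))
}

#' Integrate per-organ masks under a priority order
#'
#' Voxels claimed by several organ masks are assigned to the claimant with
#' the highest priority (earliest in `priority`); voxels claimed once keep
#' their organ.
#'
#' @param masks Named list of 3D logical organ masks on one grid.
#' @param priority Character vector containing (at least) every name in
#'   `masks`, highest priority first.
#' @return An object of class `segmentation_result`: `labels` (3D integer
#'   array of category ids, 0 = unclaimed), `masks` (the priority-resolved
#'   per-organ masks, each equal to the labels' support for that organ) and
#'   `priority`.
#' @export
integrate_masks <- function(masks, priority = dce_organs()) {
  stopifnot(is.list(masks), length(masks) > 0L, !is.null(names(masks)))
  missing <- setdiff(names(masks), priority)
  if (length(missing) > 0) {
    stop("priority order is missing organs: ",
         paste(missing, collapse = ", "))
  }
  d <- dim(masks[[1]])
  labels <- array(0L, dim = d)
  for (organ in rev(intersect(priority, names(masks)))) {
    stopifnot(identical(dim(masks[[organ]]), d))
    labels[masks[[organ]]] <- category_id(organ)
  }
  out_masks <- lapply(names(masks), function(o) {
    array(labels == category_id(o), dim = d)
  })
  names(out_masks) <- names(masks)
  structure(list(labels = labels, masks = out_masks,
                 priority = intersect(priority, names(masks))),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation result (priority:",
      paste(x$priority, collapse = " > "), ")\n")
  for (o in names(x$masks)) {
    cat("  ", format(o, width = 8L), sum(x$masks[[o]]), "voxels\n")
  }
  invisible(x)
}

#' Body mask from a pre-contrast volume
#'
#' Separates the animal from surrounding air: Otsu air/tissue threshold,
#' largest 26-connected component, enclosed cavities (for example the
#' air-filled lung) filled. Classification context classes are meaningful
#' only inside the body, so the pipeline restricts the hard label volume to
#' this mask before organ extraction.
#'
#' @param pre_volume Pre-contrast 3D intensity volume.
#' @return 3D logical body mask.
#' @export
body_mask <- function(pre_volume) {
  thr <- .otsu(as.vector(pre_volume))
  m <- .as_mask(pre_volume > thr)
  comp <- cpp_label_components(m, 26L)
  sizes <- tabulate(comp[comp > 0L])
  if (length(sizes) == 0L) stop("no voxels above the air threshold")
  largest <- array(as.integer(comp == which.max(sizes)), dim = dim(m))
  array(cpp_fill_holes(largest) == 1L, dim = dim(m))
}
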