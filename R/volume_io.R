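#' Dynamic contrast-enhanced series container
#'
#' Holds the ordered 3D intensity volumes of one DCE acquisition on a common
#' grid, with their acquisition times and isotropic voxel spacing. The first
#' volume (by default) is the pre-contrast scan.
#'
#' @param volumes List of 3D numeric arrays sharing one shape.
#' @param times_s Strictly increasing acquisition times (seconds), one per
#'   volume; at least 2.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param pre_contrast_index Index of the pre-contrast volume (default 1).
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(volumes, times_s, voxel_size_mm = 1,
                       pre_contrast_index = 1L) {
  stopifnot(is.list(volumes), length(volumes) >= 2L,
            length(volumes) == length(times_s))
  if (any(diff(times_s) <= 0)) {
    stop("times_s must be strictly increasing")
  }
  d <- dim(volumes[[1]])
  if (length(d) != 3L) stop("volumes must be 3D arrays")
  for (i in seq_along(volumes)) {
    if (!identical(dim(volumes[[i]]), d)) {
      stop("volume ", i, " has shape ", paste(dim(volumes[[i]]), collapse = "x"),
           ", expected ", paste(d, collapse = "x"))
    }
  }
  stopifnot(voxel_size_mm > 0,
            pre_contrast_index >= 1L, pre_contrast_index <= length(volumes))
  structure(list(volumes = volumes, times_s = as.numeric(times_s),
                 voxel_size_mm = voxel_size_mm,
                 pre_contrast_index = as.integer(pre_contrast_index)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat("DCE series:", length(x$volumes), "time points,",
      paste(d, collapse = " x "), "grid,",
      x$voxel_size_mm, "mm voxels\n")
  cat("  times (s):", paste(x$times_s, collapse = ", "),
      " [pre-contrast index ", x$pre_contrast_index, "]\n", sep = "")
  invisible(x)
}

#' Read a DCE series from per-time-point NIfTI files
#'
#' @param paths Character vector of NIfTI file paths, in acquisition order.
#' @param times_s Acquisition times matching `paths`.
#' @param pre_contrast_index Index of the pre-contrast volume.
#' @return A [dce_series()]. Voxel spacing is taken from the first file's
#'   header (first pixdim).
#' @export
read_series <- function(paths, times_s, pre_contrast_index = 1L) {
  stopifnot(length(paths) == length(times_s))
  vols <- vector("list", length(paths))
  d <- NULL
  vox <- 1
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    a <- array(as.numeric(img), dim = dim(img))
    if (is.null(d)) {
      d <- dim(a)
      vox <- RNifti::pixdim(img)[1]
    } else if (!identical(dim(a), d)) {
      stop("volume shape mismatch in '", paths[i], "': ",
           paste(dim(a), collapse = "x"), " vs ", paste(d, collapse = "x"))
    }
    vols[[i]] <- a
  }
  dce_series(vols, times_s, voxel_size_mm = vox,
             pre_contrast_index = pre_contrast_index)
}

#' Write a DCE series as per-time-point NIfTI files
#'
#' @param series A [dce_series()].
#' @param paths Output paths (.nii or .nii.gz), one per time point.
#' @return Invisibly, `paths`.
#' @export
write_series <- function(series, paths) {
  stopifnot(inherits(series, "dce_series"),
            length(paths) == length(series$volumes))
  for (i in seq_along(paths)) {
    write_volume(series$volumes[[i]], paths[i],
                 voxel_size_mm = series$voxel_size_mm)
  }
  invisible(paths)
}

#' Read / write a single volume (intensity or integer labels) as NIfTI
#'
#' @param path NIfTI file path.
#' @return `read_volume`: a 3D array (numeric, or integer if the file stores
#'   an integer datatype).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))
  attr(a, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  a
}

#' @rdname read_volume
#' @param vol 3D array to write.
#' @param voxel_size_mm Isotropic spacing stored in the header.
#' @export
write_volume <- function(vol, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Scanner cone-beam geometry
#'
#' @param sdd_mm Source-to-detector distance (mm).
#' @param sod_mm Source-to-object distance (mm); must satisfy
#'   `sdd_mm > sod_mm > 0`.
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(sdd_mm, sod_mm) {
  if (!(sod_mm > 0) || !(sdd_mm > sod_mm)) {
    stop("geometry requires sdd_mm > sod_mm > 0")
  }
  structure(list(sdd_mm = sdd_mm, sod_mm = sod_mm), class = "ct_geometry")
}

#' Cone-beam magnification factor
#'
#' The geometric magnification of a cone-beam scanner is the ratio of the
#' source-to-detector and source-to-object distances.
#'
#' @param geometry A [ct_geometry()].
#' @return Dimensionless scalar `sdd_mm / sod_mm`.
#' @export
magnification <- function(geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  geometry$sdd_mm / geometry$sod_mm
}

#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their defaults.
#'
#' @param n_components Number of principal components kept as voxel features.
#' @param S SLIC seed-grid interval in voxels (controls supervoxel size).
#' @param m SLIC compactness: weight of feature similarity relative to
#'   spatial proximity (smaller = tighter boundary adherence).
#' @param smooth_size,smooth_sigma Gaussian probability-map smoothing: kernel
#'   size (voxels, odd) and standard deviation (voxels).
#' @param opening_radius Radius (voxels) of the disk structuring element used
#'   for the per-slice morphological opening of organ masks.
#' @param bone_dilation_radius Radius (voxels) of the 3D ball dilating the
#'   pre-contrast bone into the region of interest used on post-contrast
#'   volumes.
#' @param classifier `"svm"` or `"rf"`.
#' @param svm_log2C,svm_log2gamma Integer exponent grids for the SVM search:
#'   cost C = 2^svm_log2C, kernel shape gamma = 2^svm_log2gamma.
#' @param rf_n_trees,rf_features_per_node Random-forest size and number of
#'   candidate features per split.
#' @param purity Minimum fraction of a supervoxel's voxels that must share
#'   one ground-truth label for it to enter the training pool.
#' @param training_fraction Fraction of the per-category training pool
#'   actually used for training.
#' @param priority Organ priority order (highest first) for integration.
#' @param reference_time_s Post-contrast acquisition time (seconds) of the
#'   volume used for bone thresholding.
#' @param seed Integer seed for every stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_components = 4L, S = 8L, m = 0.02,
                            smooth_size = 9L, smooth_sigma = 3,
                            opening_radius = 2L, bone_dilation_radius = 3L,
                            classifier = c("svm", "rf"),
                            svm_log2C = -5:15, svm_log2gamma = -15:15,
                            rf_n_trees = 500L, rf_features_per_node = 2L,
                            purity = 0.8, training_fraction = 0.5,
                            priority = dce_organs(),
                            reference_time_s = 100, seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(n_components >= 1L, S >= 2L, m > 0, smooth_size >= 1L,
            smooth_size %% 2L == 1L, smooth_sigma > 0, opening_radius >= 1L,
            bone_dilation_radius >= 1L, rf_n_trees >= 1L,
            rf_features_per_node >= 1L, purity > 0.5, purity <= 1,
            training_fraction > 0, training_fraction <= 1)
  if (!setequal(priority, dce_organs())) {
    stop("priority must be a permutation of: ",
         paste(dce_organs(), collapse = ", "))
  }
  structure(list(n_components = as.integer(n_components), S = as.integer(S),
                 m = m, smooth_size = as.integer(smooth_size),
                 smooth_sigma = smooth_sigma,
                 opening_radius = as.integer(opening_radius),
                 bone_dilation_radius = as.integer(bone_dilation_radius),
                 classifier = classifier,
                 svm_log2C = as.integer(svm_log2C),
                 svm_log2gamma = as.integer(svm_log2gamma),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_features_per_node = as.integer(rf_features_per_node),
                 purity = purity, training_fraction = training_fraction,
                 priority = priority, reference_time_s = reference_time_s,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Missing fields take the [pipeline_config()] defaults, so a config file
#' only needs to state what it changes.
#'
#' @param path YAML file path.
#' @return `read_config`: a `pipeline_config`.
#' @export
read_config <- function(path) {
  fields <- yaml::read_yaml(path)
  if (is.null(fields)) fields <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, fields)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("dceseg pipeline configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) > 8L) v <- c(v[1:3], "...", v[length(v)])
    cat("  ", format(nm, width = 22L), paste(v, collapse = " "), "\n")
  }
  invisible(x)
}
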