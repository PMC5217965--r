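#' Tissue specification for the synthetic phantom
#'
#' Describes one tissue: its name (one of the ten pipeline categories), its
#' geometry as a set of ellipsoid/tube primitives in voxel coordinates, a
#' pre-contrast base intensity, and a relative-enhancement curve giving the
#' fractional intensity rise R_t = (T_t - T_0)/T_0 at each post-contrast time
#' point.
#'
#' @param name Category name; must be one of [dce_categories()].
#' @param geometry List of primitives. Each is a list with `type` either
#'   `"ellipsoid"` (fields `center` = (x,y,z), `semiaxes` = (a,b,c), voxels)
#'   or `"tube"` (an axis-aligned cylinder: fields `axis` one of "x","y","z",
#'   `center` = 2 coordinates in the orthogonal plane, `radius`, and `range`
#'   = (lo, hi) along the axis). Coordinates are 1-based voxel indices.
#' @param base_intensity Pre-contrast intensity, arbitrary CT-like units (> 0).
#' @param enhancement Numeric vector of relative enhancements R_t, one per
#'   post-contrast time point (dimensionless).
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(name, geometry, base_intensity, enhancement) {
  name <- match.arg(name, dce_categories())
  stopifnot(is.numeric(base_intensity), length(base_intensity) == 1L,
            base_intensity > 0, is.numeric(enhancement))
  for (g in geometry) {
    if (!is.list(g) || is.null(g$type) ||
        !g$type %in% c("ellipsoid", "tube")) {
      stop("geometry primitives must be lists with type 'ellipsoid' or 'tube'")
    }
  }
  structure(list(name = name, geometry = geometry,
                 base_intensity = base_intensity,
                 enhancement = as.numeric(enhancement)),
            class = "tissue_spec")
}

#' Phantom specification
#'
#' Bundles everything needed to generate a synthetic 4D DCE series with
#' ground-truth labels: grid, timing, tissues, noise, and per-time-point
#' rigid jitter.
#'
#' @param grid_shape Integer vector of 3 positive extents (x, y, z).
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param times_s Acquisition times in seconds, strictly increasing; the
#'   first entry is the pre-contrast scan.
#' @param tissues List of [tissue_spec()] objects. Overlapping primitives are
#'   resolved by list order (later tissues overwrite earlier ones).
#' @param noise_sd Standard deviation of the additive zero-mean Gaussian
#'   noise, in intensity units (>= 0).
#' @param jitter_vox Maximum per-time-point rigid integer translation in
#'   voxels (0 disables jitter); each post-contrast volume is shifted by a
#'   uniform draw in \{-jitter_vox, ..., jitter_vox\}^3.
#' @param seed Integer seed making generation bit-for-bit reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm, times_s, tissues,
                         noise_sd = 0, jitter_vox = 0L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            voxel_size_mm > 0, length(times_s) >= 2L,
            noise_sd >= 0, jitter_vox >= 0)
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  n_post <- length(times_s) - 1L
  for (tis in tissues) {
    stopifnot(inherits(tis, "tissue_spec"))
    if (length(tis$enhancement) != n_post) {
      stop("tissue '", tis$name, "': enhancement must have ", n_post,
           " entries (one per post-contrast time point)")
    }
    for (g in tis$geometry) {
      if (!.primitive_inside(g, grid_shape)) {
        stop("tissue '", tis$name, "': geometry primitive extends outside ",
             "the grid")
      }
    }
  }
  peak_soft <- 0
  bone_base <- Inf
  for (tis in tissues) {
    if (tis$name == "bone") {
      bone_base <- min(bone_base, tis$base_intensity)
    } else {
      peak_soft <- max(peak_soft,
                       tis$base_intensity * (1 + max(0, tis$enhancement)))
    }
  }
  if (bone_base <= peak_soft) {
    stop("bone base_intensity (", bone_base, ") must exceed the maximum ",
         "enhanced soft-tissue intensity (", peak_soft, ")")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 times_s = as.numeric(times_s), tissues = tissues,
                 noise_sd = noise_sd, jitter_vox = as.integer(jitter_vox),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.primitive_inside <- function(g, grid_shape) {
  if (g$type == "ellipsoid") {
    all(g$center - g$semiaxes >= 1) &&
      all(g$center + g$semiaxes <= grid_shape)
  } else {
    ax <- match(g$axis, c("x", "y", "z"))
    plane <- setdiff(1:3, ax)
    all(g$range >= 1) && g$range[2] <= grid_shape[ax] &&
      all(g$center - g$radius >= 1) &&
      all(g$center + g$radius <= grid_shape[plane])
  }
}

#' Default mouse-like phantom specification
#'
#' A 100 x 100 x 180 grid with all ten tissue categories, one pre-contrast
#' plus five post-contrast time points 50 s apart, and enhancement kinetics
#' that qualitatively reproduce the contrast dynamics seen in DCE micro-CT
#' of the mouse after an iohexol bolus:
#' \itemize{
#'   \item the heart (blood pool) enhances immediately and washes out;
#'   \item the kidney enhancement rises and remains high to the last scan
#'     (renal clearance of the agent);
#'   \item the spleen's drop from peak is steeper than the liver's;
#'   \item subcutaneous fat/muscle and the intestinal cavity barely enhance
#'     (R_t <= 0.05 throughout);
#'   \item bone is a high-intensity structure above every enhanced soft
#'     tissue.
#' }
#' Default additive noise SD is 20, i.e. 5\% of the nominal soft-tissue base
#' intensity of 400.
#'
#' @param grid_shape Grid extents; the tissue geometry is scaled to the grid,
#'   so smaller grids give proportionally smaller (coarser) phantoms.
#' @param noise_sd,jitter_vox,seed Override the corresponding
#'   [phantom_spec()] fields.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(grid_shape = c(100L, 100L, 180L),
                                 noise_sd = 20, jitter_vox = 0L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  # geometry below is authored on the reference 100 x 100 x 180 grid and
  # rescaled; sx,sy,sz are the per-axis scale factors
  sc <- grid_shape / c(100, 100, 180)
  E <- function(cx, cy, cz, a, b, c3) {
    list(type = "ellipsoid",
         center = c(cx, cy, cz) * sc,
         semiaxes = pmax(c(a, b, c3) * sc, 1.5))
  }
  Tz <- function(cx, cy, r, z0, z1) {
    list(type = "tube", axis = "z",
         center = c(cx * sc[1], cy * sc[2]),
         radius = max(r * min(sc[1:2]), 1.5),
         range = c(z0, z1) * sc[3])
  }
  tissues <- list(
    tissue_spec("fat_muscle",
                list(Tz(50, 50, 38, 8, 172)),
                base_intensity = 380,
                enhancement = c(0.02, 0.02, 0.02, 0.02, 0.02)),
    tissue_spec("lung",
                list(E(32, 50, 142, 10, 13, 14), E(68, 50, 142, 10, 13, 14)),
                base_intensity = 150,
                enhancement = c(0.30, 0.25, 0.20, 0.15, 0.12)),
    tissue_spec("heart",
                list(E(50, 54, 127, 11, 11, 10)),
                base_intensity = 400,
                enhancement = c(1.60, 1.00, 0.70, 0.50, 0.40)),
    tissue_spec("liver",
                list(E(46, 48, 95, 24, 22, 17)),
                base_intensity = 420,
                enhancement = c(0.80, 0.90, 0.85, 0.75, 0.65)),
    tissue_spec("spleen",
                list(E(76, 46, 98, 9, 9, 16)),
                base_intensity = 410,
                enhancement = c(1.10, 1.00, 0.70, 0.45, 0.30)),
    tissue_spec("intestinal_wall",
                list(Tz(50, 42, 13, 22, 62)),
                base_intensity = 400,
                enhancement = c(0.25, 0.30, 0.30, 0.26, 0.22)),
    tissue_spec("intestinal_cavity",
                list(Tz(50, 42, 8, 24, 60)),
                base_intensity = 300,
                enhancement = c(0.03, 0.03, 0.03, 0.02, 0.02)),
    tissue_spec("kidney",
                list(E(30, 60, 60, 9, 9, 13), E(70, 60, 60, 9, 9, 13)),
                base_intensity = 400,
                enhancement = c(1.20, 1.50, 1.55, 1.50, 1.40)),
    tissue_spec("skin_adherent",
                list(E(50, 82, 120, 6, 6, 8), E(18, 50, 80, 6, 6, 8),
                     E(82, 50, 40, 6, 6, 8), E(50, 18, 150, 6, 6, 8)),
                base_intensity = 390,
                enhancement = c(0.15, 0.05, 0.20, 0.02, 0.10)),
    tissue_spec("bone",
                list(Tz(50, 24, 5, 10, 170)),
                base_intensity = 1400,
                enhancement = c(0, 0, 0, 0, 0))
  )
  phantom_spec(grid_shape = grid_shape, voxel_size_mm = 0.315,
               times_s = c(-50, 0, 50, 100, 150, 200), tissues = tissues,
               noise_sd = noise_sd, jitter_vox = jitter_vox, seed = seed)
}

.primitive_mask <- function(g, coords) {
  if (g$type == "ellipsoid") {
    ((coords$x - g$center[1]) / g$semiaxes[1])^2 +
      ((coords$y - g$center[2]) / g$semiaxes[2])^2 +
      ((coords$z - g$center[3]) / g$semiaxes[3])^2 <= 1
  } else {
    ax <- match(g$axis, c("x", "y", "z"))
    plane <- list(coords$x, coords$y, coords$z)[setdiff(1:3, ax)]
    along <- list(coords$x, coords$y, coords$z)[[ax]]
    (plane[[1]] - g$center[1])^2 + (plane[[2]] - g$center[2])^2 <=
      g$radius^2 & along >= g$range[1] & along <= g$range[2]
  }
}

#' Rasterize the phantom tissues into a ground-truth label volume
#'
#' @param spec A [phantom_spec()].
#' @return Integer 3D array; voxel values are category ids
#'   (see [dce_categories()]), 0 for background. Overlapping tissues are
#'   resolved by list order (later overwrites earlier) with a warning.
#' @export
phantom_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  coords <- list(
    x = array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d),
    y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d),
    z = array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d))
  labels <- array(0L, dim = d)
  overlap <- 0L
  for (tis in spec$tissues) {
    id <- category_id(tis$name)
    for (g in tis$geometry) {
      m <- .primitive_mask(g, coords)
      overlap <- overlap + sum(labels[m] != 0L & labels[m] != id)
      labels[m] <- id
    }
  }
  if (overlap > 0L) {
    warning("phantom tissues overlap on ", overlap,
            " voxels; later tissues in the list take precedence")
  }
  labels
}

#' Generate a synthetic 4D DCE series with ground truth
#'
#' Rasterizes the tissues into a label volume, then builds one intensity
#' volume per acquisition time: the pre-contrast volume carries each
#' tissue's base intensity T_0, and the post-contrast volume at time t
#' carries T_0 * (1 + R_t). Zero-mean Gaussian noise of SD `noise_sd` is
#' added independently per volume, and (optionally) each post-contrast
#' volume is rigidly shifted by an integer jitter. With `noise_sd = 0` and
#' `jitter_vox = 0` the output is exactly piecewise-constant per
#' (tissue, time).
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `series` (a [dce_series()]) and `labels`
#'   (integer ground-truth label volume; see [phantom_labels()]).
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec)
  d <- spec$grid_shape
  n_time <- length(spec$times_s)
  base <- array(0, dim = d)
  for (tis in spec$tissues) {
    base[labels == category_id(tis$name)] <- tis$base_intensity
  }
  enh <- matrix(0, nrow = length(dce_categories()), ncol = n_time - 1L)
  for (tis in spec$tissues) {
    enh[category_id(tis$name), ] <- tis$enhancement
  }
  set.seed(spec$seed)
  vols <- vector("list", n_time)
  for (t in seq_len(n_time)) {
    if (t == 1L) {
      vol <- base
    } else {
      rt <- array(0, dim = d)
      inside <- labels > 0L
      rt[inside] <- enh[labels[inside], t - 1L]
      vol <- base * (1 + rt)
    }
    if (spec$jitter_vox > 0L && t > 1L) {
      shift <- sample(seq(-spec$jitter_vox, spec$jitter_vox), 3L,
                      replace = TRUE)
      vol <- shift_volume(vol, shift)
    }
    if (spec$noise_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
    }
    vols[[t]] <- vol
  }
  series <- dce_series(vols, times_s = spec$times_s,
                       voxel_size_mm = spec$voxel_size_mm)
  list(series = series, labels = labels)
}

#' Rigidly translate a volume by an integer offset
#'
#' Voxels shifted in from outside the grid are zero-filled.
#'
#' @param vol 3D array.
#' @param shift Integer vector of 3 offsets (voxels).
#' @return Shifted 3D array of the same shape.
#' @export
shift_volume <- function(vol, shift) {
  d <- dim(vol)
  shift <- as.integer(shift)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    src[[a]] <- if (s >= 0) 1:(d[a] - s) else (1 - s):d[a]
    dst[[a]] <- if (s >= 0) (1 + s):d[a] else 1:(d[a] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Look up a tissue's relative enhancement at a post-contrast time point
#'
#' Time index 0 denotes the pre-contrast scan and returns 0 by definition of
#' relative enhancement; indices 1..P address the stored post-contrast
#' curve.
#'
#' @param tissue A [tissue_spec()].
#' @param time_index Integer in 0..(number of post-contrast points).
#' @return The relative enhancement R_t (dimensionless scalar).
#' @export
enhancement_at <- function(tissue, time_index) {
  stopifnot(inherits(tissue, "tissue_spec"))
  time_index <- as.integer(time_index)
  if (time_index < 0L || time_index > length(tissue$enhancement)) {
    stop("time_index out of range: ", time_index)
  }
  if (time_index == 0L) return(0)
  tissue$enhancement[time_index]
}
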