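# Shared fixtures. Expensive objects (the full-size phantom and its
# features/supervoxels) are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# default-size phantom under the study conditions: noise SD 20 (5% of the
# nominal soft-tissue base 400), no jitter
study_phantom <- function() {
  cached("study_phantom", suppressWarnings(
    phantom_generate(default_phantom_spec(seed = 101))))
}

study_features <- function() {
  cached("study_features", dce_features(study_phantom()$series, 4L))
}

study_svmap <- function() {
  cached("study_svmap",
         slic_supervoxels(study_features()$scores, S = 8L, m = 0.02))
}

# a small, fast phantom for unit tests (same tissue layout, coarser grid)
small_phantom <- function(noise_sd = 0, seed = 5) {
  key <- sprintf("small_phantom_%g_%d", noise_sd, seed)
  cached(key, suppressWarnings(phantom_generate(
    default_phantom_spec(grid_shape = c(50L, 50L, 90L),
                         noise_sd = noise_sd, seed = seed))))
}

# two-block score fixture: all channels differ sharply across the x = split
# plane, which a feature-driven supervoxel algorithm must never straddle
two_block_scores <- function(n_side = 64L, split = n_side / 2L,
                             n_chan = 4L, lo = 0.2, hi = 0.8) {
  d <- c(n_side, n_side, n_side)
  arr <- array(lo, dim = c(d, n_chan))
  arr[(split + 1L):n_side, , , ] <- hi
  arr
}

# independent connected-components oracle: plain R breadth-first search
bfs_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  if (connectivity == 6L) off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) == 1, ]
  comp <- array(0L, dim = d)
  nextc <- 0L
  for (s in which(mask & comp == 0L)) {
    if (comp[s] != 0L) next
    nextc <- nextc + 1L
    queue <- s
    comp[s] <- nextc
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (cur - 1L) %/% (d[1] * d[2])
      r <- (cur - 1L) %% (d[1] * d[2])
      y <- r %/% d[1]
      x <- r %% d[1]
      for (j in seq_len(nrow(off))) {
        xx <- x + off$dx[j]; yy <- y + off$dy[j]; zz <- z + off$dz[j]
        if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] ||
            zz < 0 || zz >= d[3]) next
        ni <- 1L + xx + d[1] * (yy + d[2] * zz)
        if (mask[ni] && comp[ni] == 0L) {
          comp[ni] <- nextc
          queue <- c(queue, ni)
        }
      }
    }
  }
  comp
}

# build a minimal supervoxel_map by hand for classification tests
manual_svmap <- function(labels, features) {
  labels <- array(as.integer(labels), dim = dim(labels))
  st <- dceseg:::cpp_label_stats(labels, features)
  structure(list(labels = labels, size = as.integer(st$size),
                 center = st$center, features = st$features,
                 k = nrow(st$center), N = length(labels),
                 params = list(S = NA, m = NA, n = dim(features)[4])),
            class = "supervoxel_map")
}

# well-separated Gaussian blobs in feature space, one per category name
separable_training_set <- function(categories, n_per = 20L, seed = 1L,
                                   spread = 0.01) {
  set.seed(seed)
  centers <- seq(0.1, 0.9, length.out = length(categories))
  rows <- lapply(seq_along(categories), function(i) {
    matrix(stats::rnorm(n_per * 4L, mean = centers[i], sd = spread),
           ncol = 4L)
  })
  fm <- do.call(rbind, rows)
  colnames(fm) <- paste0("b", 1:4)
  ts <- data.frame(id = seq_len(nrow(fm)), fm,
                   category = factor(rep(categories, each = n_per),
                                     levels = categories))
  class(ts) <- c("training_set", "data.frame")
  ts
}
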