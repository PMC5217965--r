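test_that("the clustering distance matches hand-evaluated cases", {
  # identical voxel and center
  expect_equal(slic_distance(rep(0.5, 4), c(1, 2, 3), rep(0.5, 4),
                             c(1, 2, 3), m = 0.02, S = 8), 0)
  # all four feature differences 0.02, same position:
  # RMS = sqrt(4 * 0.0004 / 4) = 0.02, D = 0.02 / 0.02 = 1
  expect_equal(slic_distance(rep(0.10, 4), c(5, 5, 5), rep(0.12, 4),
                             c(5, 5, 5), m = 0.02, S = 8), 1.0,
               tolerance = 1e-12)
  # equal features, spatial offset (8, 0, 0): D = 8 / 8 = 1
  expect_equal(slic_distance(rep(0.3, 4), c(1, 1, 1), rep(0.3, 4),
                             c(9, 1, 1), m = 0.02, S = 8), 1.0,
               tolerance = 1e-12)
  # symmetry and nonnegativity on random cases
  set.seed(7)
  for (i in 1:20) {
    f1 <- runif(4); f2 <- runif(4); p1 <- runif(3, 1, 32); p2 <- runif(3, 1, 32)
    d12 <- slic_distance(f1, p1, f2, p2, m = 0.02, S = 8)
    expect_equal(d12, slic_distance(f2, p2, f1, p1, m = 0.02, S = 8))
    expect_gte(d12, 0)
  }
  expect_error(slic_distance(runif(3), c(1, 1, 1), runif(4), c(1, 1, 1),
                             m = 0.02, S = 8), "length")
  # quadrature alternative combines the same two terms in quadrature
  f <- slic_distance(rep(0.1, 4), c(0, 0, 0), rep(0.12, 4), c(8, 0, 0),
                     m = 0.02, S = 8, combine = "quadrature")
  expect_equal(f, sqrt(1^2 + 1^2), tolerance = 1e-12)
})

test_that("seeding places a lattice and perturbs to low-gradient positions", {
  # uniform scores: 32^3 grid with S = 8 gives 4^3 centers on the lattice
  arr <- array(0.5, dim = c(32, 32, 32, 2))
  cen <- init_centers(arr, 8L)
  expect_equal(nrow(cen), 64L)
  lattice <- as.matrix(expand.grid(x = c(5, 13, 21, 29), y = c(5, 13, 21, 29),
                                   z = c(5, 13, 21, 29)))
  expect_equal(cen[order(cen[, 3], cen[, 2], cen[, 1]), 1:3],
               lattice[order(lattice[, 3], lattice[, 2], lattice[, 1]), ],
               ignore_attr = TRUE)
  # a seed one voxel from a sharp feature edge moves to a flat neighbor:
  # verify against brute-force gradient over the 27 neighbors
  arr2 <- array(0.2, dim = c(16, 16, 16, 1))
  arr2[1:4, , , ] <- 0.8   # edge between x = 4 and x = 5; lattice x = 5
  cen2 <- init_centers(arr2, 8L)
  grad <- function(x, y, z) {
    d <- dim(arr2)[1:3]
    cl <- function(v, n) pmin(pmax(v, 1), n)
    (arr2[cl(x + 1, d[1]), y, z, 1] - arr2[cl(x - 1, d[1]), y, z, 1])^2 +
      (arr2[x, cl(y + 1, d[2]), z, 1] - arr2[x, cl(y - 1, d[2]), z, 1])^2 +
      (arr2[x, y, cl(z + 1, d[3]), 1] - arr2[x, y, cl(z - 1, d[3]), 1])^2
  }
  for (i in seq_len(nrow(cen2))) {
    g_here <- grad(cen2[i, 1], cen2[i, 2], cen2[i, 3])
    expect_equal(g_here, 0)  # all seeds end on flat ground
  }
})

test_that("SLIC partitions a two-block volume along the block face", {
  arr <- two_block_scores(32L)
  sv <- slic_supervoxels(arr, S = 8L, m = 0.02)
  # partition: every voxel labeled, k nonempty labels summing to N
  expect_true(all(sv$labels >= 1L))
  expect_equal(sum(sv$size), sv$N)
  expect_true(all(sv$size > 0L))
  expect_equal(length(sv$size), sv$k)
  # boundary recall 1.0: no supervoxel straddles the x = 16 face
  expect_true(all(sv$labels[16, , ] != sv$labels[17, , ]))
  # almost every voxel sits in a supervoxel whose mean feature equals its
  # own (connectivity enforcement may merge a rare fragment diagonally
  # across the face, slightly mixing that supervoxel's mean)
  own <- arr[, , , 1]
  mixed <- mean(abs(sv$features[as.vector(sv$labels), 1] -
                      as.vector(own)) > 1e-9)
  expect_lt(mixed, 0.01)
})

test_that("SLIC is deterministic and respects the window locality", {
  arr <- two_block_scores(32L)
  a <- slic_supervoxels(arr, S = 8L, m = 0.02)
  b <- slic_supervoxels(arr, S = 8L, m = 0.02)
  expect_identical(a$labels, b$labels)
  # no voxel is farther than 2S from its supervoxel's center in any axis
  d <- dim(a$labels)
  coords <- cbind(
    x = rep(seq_len(d[1]), times = d[2] * d[3]),
    y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    z = rep(seq_len(d[3]), each = d[1] * d[2]))
  centers <- a$center[as.vector(a$labels), ]
  expect_lte(max(abs(coords - centers)), 2 * 8)
})

test_that("decreasing compactness does not increase feature variance", {
  # on a noise-free structured volume, a smaller m buys tighter feature
  # homogeneity (under voxel noise this need not hold: a very small m
  # chases noise, fragments, and the connectivity merge mixes features)
  ph <- small_phantom(noise_sd = 0)
  sc <- dce_features(ph$series, 4L)$scores
  arr <- score_array(sc)
  wvar <- function(m) {
    sv <- slic_supervoxels(arr, S = 8L, m = m)
    V <- matrix(arr, ncol = dim(arr)[4])
    mean(vapply(seq_len(dim(arr)[4]), function(ch) {
      mu <- sv$features[as.vector(sv$labels), ch]
      mean((V[, ch] - mu)^2)
    }, numeric(1)))
  }
  v <- vapply(c(0.005, 0.02, 0.1), wvar, numeric(1))
  expect_true(all(diff(v) >= -1e-12))
})

test_that("connectivity enforcement merges orphan fragments", {
  # already-connected map is unchanged up to relabeling
  lab <- array(1L, dim = c(8, 8, 8)); lab[5:8, , ] <- 2L
  out <- enforce_connectivity(lab, min_size = 16L)
  expect_equal(length(unique(as.vector(out))), 2L)
  expect_true(all(out[1:4, , ] == out[1, 1, 1]))
  expect_true(all(out[5:8, , ] == out[5, 1, 1]))
  # a 3-voxel orphan island of label 1 inside label 2 is absorbed
  lab2 <- array(2L, dim = c(10, 10, 10))
  lab2[1:5, , ] <- 1L
  lab2[8, 5, 5] <- 1L; lab2[9, 5, 5] <- 1L; lab2[8, 6, 5] <- 1L
  out2 <- enforce_connectivity(lab2, min_size = 16L)
  expect_equal(out2[8, 5, 5], out2[10, 10, 10])
  # postcondition: each label is one 26-connected component (independent
  # breadth-first-search oracle)
  for (l in unique(as.vector(out2))) {
    comp <- bfs_components(out2 == l)
    expect_equal(max(comp), 1L)
  }
  # large fragments survive as supervoxels of their own
  lab3 <- array(1L, dim = c(10, 10, 10))
  lab3[1:3, 1:3, 1:3] <- 2L
  lab3[8:10, 8:10, 8:10] <- 2L   # two disconnected label-2 blocks, 27 each
  out3 <- enforce_connectivity(lab3, min_size = 16L)
  expect_equal(length(unique(as.vector(out3))), 3L)
})

test_that("mean features equal a brute-force per-label accumulation", {
  set.seed(8)
  labels <- array(sample(1:7, 6 * 6 * 6, replace = TRUE), dim = c(6, 6, 6))
  arr <- array(runif(6 * 6 * 6 * 3), dim = c(6, 6, 6, 3))
  fm <- mean_features(labels, arr)
  for (l in 1:7) {
    for (ch in 1:3) {
      v <- arr[, , , ch]
      expect_equal(unname(fm[l, ch]), mean(v[labels == l]),
                   tolerance = 1e-12)
    }
  }
  # constant channel: every supervoxel mean equals the constant
  arrc <- array(0.37, dim = c(6, 6, 6, 1))
  expect_equal(max(abs(mean_features(labels, arrc) - 0.37)), 0,
               tolerance = 1e-12)
  # two-voxel supervoxel mean
  lab <- array(1L, dim = c(2, 1, 1))
  a <- array(c(0.2, 0.4), dim = c(2, 1, 1, 1))
  expect_equal(unname(mean_features(lab, a)[1, 1]), 0.3)
})
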