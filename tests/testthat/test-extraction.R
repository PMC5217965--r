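toy_maps <- function(labels, proba) {
  broadcast_probabilities(labels, proba)
}

test_that("broadcasting copies each supervoxel's row to its voxels", {
  labels <- array(c(1L, 1L, 2L, 2L), dim = c(2, 2, 1))
  proba <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  colnames(proba) <- c("heart", "liver", "spleen")
  maps <- toy_maps(labels, proba)
  # voxel lookup equals table lookup via its label
  for (v in 1:4) {
    ix <- arrayInd(v, dim(labels))
    expect_equal(maps$array[ix[1], ix[2], 1, ], proba[labels[v], ],
                 ignore_attr = TRUE)
  }
  sums <- apply(maps$array, 1:3, sum)
  expect_equal(as.vector(sums), rep(1, 4), tolerance = 1e-12)
  expect_error(broadcast_probabilities(array(3L, dim = c(1, 1, 1)), proba),
               "missing")
})

test_that("Gaussian smoothing conserves probability mass", {
  set.seed(9)
  labels <- array(sample(1:4, 12^3, replace = TRUE), dim = c(12, 12, 12))
  proba <- matrix(runif(4 * 3), 4, 3)
  proba <- proba / rowSums(proba)
  colnames(proba) <- c("heart", "liver", "spleen")
  maps <- smooth_probability_maps(toy_maps(labels, proba), 9L, 3)
  sums <- apply(maps$array, 1:3, sum)
  expect_equal(as.vector(sums), rep(1, 12^3), tolerance = 1e-6)
  expect_true(all(maps$array >= 0))
  # spatially uniform maps are a fixed point
  u <- toy_maps(array(1L, dim = c(8, 8, 8)),
                matrix(c(0.25, 0.75), 1, 2,
                       dimnames = list(NULL, c("heart", "liver"))))
  us <- smooth_probability_maps(u, 9L, 3)
  expect_equal(us$array, u$array, tolerance = 1e-12)
  expect_error(smooth_probability_maps(u, 8L, 3), "odd")
})

test_that("an impulse response reproduces the sampled 3D Gaussian kernel", {
  vol <- array(0, dim = c(19, 19, 19))
  vol[10, 10, 10] <- 1
  sm <- dceseg:::cpp_sep_conv3(vol, dceseg:::.gaussian_kernel1d(9L, 3))
  k3 <- gaussian_kernel3d(9L, 3)
  expect_equal(sm[6:14, 6:14, 6:14], k3, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(k3), 1, tolerance = 1e-12)
  # beyond the kernel radius the response is exactly zero
  expect_equal(sm[1, , ], array(0, c(19, 19)), ignore_attr = TRUE)
})

test_that("argmax labeling matches a brute-force scan with first-tie rule", {
  labels <- array(c(1L, 2L, 3L), dim = c(3, 1, 1))
  proba <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0.0), c(0.1, 0.2, 0.7))
  colnames(proba) <- c("heart", "liver", "spleen")
  out <- argmax_labels(toy_maps(labels, proba))
  expect_equal(as.vector(out),
               category_id(c("heart", "heart", "spleen")))
  # random maps against an exhaustive per-voxel scan
  set.seed(10)
  lab <- array(sample(1:6, 5^3, replace = TRUE), dim = c(5, 5, 5))
  pr <- matrix(runif(6 * 4), 6, 4)
  pr <- pr / rowSums(pr)
  colnames(pr) <- c("heart", "liver", "spleen", "kidney")
  maps <- toy_maps(lab, pr)
  out2 <- argmax_labels(maps)
  for (v in seq_len(5^3)) {
    ix <- arrayInd(v, dim(lab))
    row <- maps$array[ix[1], ix[2], ix[3], ]
    expect_equal(out2[v], category_id(colnames(pr)[which.max(row)]))
  }
})

test_that("organ extraction cleans, selects components and fills holes", {
  d <- c(40, 40, 40)
  labels <- array(0L, dim = d)
  hid <- category_id("heart")
  labels[10:29, 10:29, 10:29] <- hid          # solid 20^3 cube
  labels[15:17, 15:17, 15:17] <- 0L           # internal 3^3 cavity
  labels[35, 35, 35] <- hid                   # isolated voxel
  labels[34:36, 5:7, 30:32] <- hid            # ~30-voxel blob (27 voxels)
  mask <- extract_organ(labels, "heart")
  # cube interior retained and internal cavity filled (the disk opening
  # rounds the cube's edges, so assert away from them)
  expect_true(all(mask[12:27, 12:27, 12:27]))
  expect_true(all(mask[15:17, 15:17, 15:17]))  # the cavity, now filled
  expect_gt(sum(mask), 0.95 * 20^3)
  expect_false(mask[35, 35, 35])               # single voxel erased
  expect_false(any(mask[34:36, 5:7, 30:32]))   # small blob removed
  # anti-extensive outside the filled cavity: no voxel outside cube + blob
  outside <- mask & labels != hid
  outside[15:17, 15:17, 15:17] <- FALSE
  expect_false(any(outside))
  # paired structures of comparable size both survive
  lab2 <- array(0L, dim = d)
  kid <- category_id("kidney")
  lab2[5:14, 5:14, 5:14] <- kid
  lab2[25:34, 25:34, 25:34] <- kid
  m2 <- extract_organ(lab2, "kidney")
  expect_true(all(m2[7:12, 7:12, 7:12]))
  expect_true(all(m2[27:32, 27:32, 27:32]))
  # absent category: empty mask with a warning
  expect_warning(m3 <- extract_organ(lab2, "spleen"), "absent")
  expect_false(any(m3))
})

test_that("opening removes structures smaller than the element", {
  d <- c(20, 20, 5)
  mask <- array(0L, dim = d)
  mask[5:14, 5:14, 2:4] <- 1L    # 10x10 slab survives a radius-2 disk
  mask[18, 18, 2] <- 1L          # lone voxel does not
  op <- binary_opening(mask, 2L)
  # the slab interior survives (its corners are rounded by the disk)
  expect_true(all(op[7:12, 7:12, 2:4] == 1L))
  expect_true(all(op[5:14, 9:10, 2:4] == 1L))
  expect_equal(op[18, 18, 2], 0L)
  # opening is anti-extensive: output inside input
  expect_true(all(op <= mask))
})

test_that("bone segmentation recovers the phantom skeleton exactly", {
  ph <- small_phantom(noise_sd = 0)
  pre <- ph$series$volumes[[1]]
  post <- ph$series$volumes[[4]]   # 100 s post-contrast reference
  bone <- segment_bone(pre, post)
  expect_equal(bone, ph$labels == category_id("bone"), ignore_attr = TRUE)
  # enhanced voxels above threshold but outside the dilated ROI stay out
  thr <- bone_threshold(pre)
  hot <- post
  hot[2:4, 2:4, 2:4] <- thr + 500   # bright blob far from the skeleton
  bone2 <- segment_bone(pre, hot, threshold = thr)
  expect_false(any(bone2[2:4, 2:4, 2:4]))
  # empty pre-contrast bone: empty result with a warning
  flat <- array(100, dim = dim(pre))
  expect_warning(b3 <- segment_bone(flat, flat, threshold = 1e6), "empty")
  expect_false(any(b3))
  # a threshold below the soft-tissue mode warns about leakage
  expect_warning(segment_bone(pre, post, threshold = 10), "leak")
})

test_that("priority integration resolves overlaps and partitions voxels", {
  d <- c(10, 10, 10)
  bone <- array(FALSE, d); bone[1:5, , ] <- TRUE
  liver <- array(FALSE, d); liver[4:8, , ] <- TRUE
  res <- integrate_masks(list(bone = bone, liver = liver))
  # contested voxels go to bone (higher priority)
  expect_true(all(res$labels[4:5, , ] == category_id("bone")))
  expect_true(all(res$labels[6:8, , ] == category_id("liver")))
  expect_equal(res$masks$bone, bone, ignore_attr = TRUE)
  expect_equal(res$masks$liver & bone, array(FALSE, d), ignore_attr = TRUE)
  # disjoint masks integrate to their disjoint union
  a <- array(FALSE, d); a[1:2, , ] <- TRUE
  b <- array(FALSE, d); b[9:10, , ] <- TRUE
  res2 <- integrate_masks(list(heart = a, spleen = b))
  expect_equal(sum(res2$labels > 0), sum(a) + sum(b))
  # every voxel carries at most one label by construction; verify the
  # masks are pairwise disjoint
  overlap <- res2$masks$heart & res2$masks$spleen
  expect_false(any(overlap))
  expect_error(integrate_masks(list(pancreas = a), priority = dce_organs()),
               "missing|unknown")
})

test_that("hole filling and component labeling agree with the BFS oracle", {
  set.seed(11)
  mask <- array(runif(10^3) > 0.7, dim = c(10, 10, 10))
  comp <- label_components(mask, 26L)
  oracle <- bfs_components(mask, 26L)
  # same partition up to label naming
  expect_equal(max(comp), max(oracle))
  expect_true(all(tapply(as.vector(oracle), as.vector(comp),
                         function(v) length(unique(v))) == 1))
  # a sealed cavity is filled, an open channel is not
  box <- array(0L, dim = c(9, 9, 9))
  box[2:8, 2:8, 2:8] <- 1L
  box[4:6, 4:6, 4:6] <- 0L
  expect_true(all(fill_holes(box)[4:6, 4:6, 4:6] == 1L))
  tunnel <- box
  tunnel[5, 5, 1:5] <- 0L  # opens the cavity to the boundary
  expect_true(all(fill_holes(tunnel)[5, 5, 1:3] == 0L))
})
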