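make_two_class_svmap <- function() {
  # 8x8x8 grid, eight 4x4x4 supervoxels; features encode the truth block
  labels <- array(0L, dim = c(8, 8, 8))
  i <- 0L
  for (z in c(0L, 4L)) for (y in c(0L, 4L)) for (x in c(0L, 4L)) {
    i <- i + 1L
    labels[x + 1:4, y + 1:4, z + 1:4] <- i
  }
  feat <- array(0.2, dim = c(8, 8, 8, 4))
  feat[, , 5:8, ] <- 0.8
  list(svmap = manual_svmap(labels, feat), features = feat)
}

test_that("training-set eligibility follows the purity rule", {
  fx <- make_two_class_svmap()
  truth <- array(0L, dim = c(8, 8, 8))
  truth[, , 1:4] <- category_id("liver")
  truth[, , 5:8] <- category_id("kidney")
  ts <- build_training_set(fx$svmap, truth, purity = 0.8,
                           per_category_n = NULL, seed = 1)
  expect_equal(nrow(ts), 8L)
  expect_equal(as.vector(table(ts$category)), c(4L, 4L))
  expect_false(any(duplicated(ts$id)))
  # a 50/50 supervoxel is ineligible at purity 0.8 (and spleen has no
  # other supervoxel, so the error names it)
  truth2 <- truth
  truth2[1:2, 1:4, 1:4] <- category_id("spleen")  # half of supervoxel 1
  expect_error(build_training_set(fx$svmap, truth2, purity = 0.8,
                                  per_category_n = NULL, seed = 1),
               "spleen")
  # a 75/25 supervoxel is eligible for its majority category at purity 0.75
  truth3 <- truth
  truth3[1:4, 1, 1:4] <- category_id("spleen")     # 25% of supervoxel 1
  truth3[5:8, 1:4, 1:4] <- category_id("spleen")   # supervoxel 2, pure
  ts3 <- build_training_set(fx$svmap, truth3, purity = 0.75,
                            per_category_n = NULL, seed = 1)
  expect_true(1L %in% ts3$id[ts3$category == "liver"])
  expect_true(2L %in% ts3$id[ts3$category == "spleen"])
})

test_that("per-category pools are sampled and subsampled reproducibly", {
  ts <- separable_training_set(c("heart", "spleen"), n_per = 36L)
  ts$category <- factor(as.character(ts$category),
                        levels = c("heart", "spleen"))
  ts36 <- ts[ts$category == "heart" | seq_len(nrow(ts)) %% 4 == 0, ]
  class(ts36) <- c("training_set", "data.frame")
  # half of a 36-supervoxel category is 18; half of 19 rounds to 10
  half <- sample_training_fraction(ts, 0.5, seed = 3)
  expect_equal(sum(half$category == "heart"), 18L)
  ts19 <- separable_training_set(c("spleen"), n_per = 19L)
  expect_equal(nrow(sample_training_fraction(ts19, 0.5, seed = 3)), 10L)
  # determinism
  expect_equal(sample_training_fraction(ts, 0.5, seed = 3), half)
  expect_gt(nrow(sample_training_fraction(ts, 0.3, seed = 3)), 0)
})

test_that("the SVM grid enumerates 21 cost and 31 gamma values", {
  cfg <- pipeline_config()
  expect_equal(2^range(cfg$svm_log2C), c(2^-5, 2^15))
  expect_equal(2^range(cfg$svm_log2gamma), c(2^-15, 2^15))
  grid <- expand.grid(cfg$svm_log2gamma, cfg$svm_log2C)
  expect_equal(nrow(grid), 651L)
  # the trained model records the full search surface
  ts <- separable_training_set(c("heart", "liver"), n_per = 10L)
  m <- train_svm(ts, seed = 1, log2C = c(-1, 1), log2gamma = c(-2, 0))
  expect_equal(nrow(m$cv_surface), 4L)
})

test_that("separable categories give zero CV error and perfect recovery", {
  cats <- c("heart", "liver", "spleen", "kidney")
  ts <- separable_training_set(cats, n_per = 12L, seed = 2)
  m <- train_svm(ts, seed = 1, log2C = seq(-5, 15, 5),
                 log2gamma = seq(-15, 15, 5))
  expect_equal(m$cv_error, 0)
  p <- predict_proba(m, ts)
  expect_equal(rowSums(p), rep(1, nrow(ts)), tolerance = 1e-6)
  expect_equal(colnames(p), cats)
  acc <- mean(cats[max.col(p)] == as.character(ts$category))
  expect_gte(acc, 0.95)
})

test_that("grid search tie-breaking and order invariance are deterministic", {
  cats <- c("heart", "liver", "lung")
  ts <- separable_training_set(cats, n_per = 10L, seed = 4)
  g <- list(log2C = c(-1, 3), log2gamma = c(-3, 1))
  m1 <- train_svm(ts, seed = 9, log2C = g$log2C, log2gamma = g$log2gamma)
  # many pairs achieve zero error on a separable set; the tie rule keeps
  # the smallest C, then the smallest gamma among the winners
  winners <- m1$cv_surface[m1$cv_surface$error == min(m1$cv_surface$error), ]
  expect_equal(m1$log2C, min(winners$log2C))
  expect_equal(m1$log2gamma,
               min(winners$log2gamma[winners$log2C == m1$log2C]))
  # permuting the training rows changes nothing
  perm <- sample(nrow(ts))
  ts2 <- ts[perm, ]
  class(ts2) <- c("training_set", "data.frame")
  m2 <- train_svm(ts2, seed = 9, log2C = g$log2C, log2gamma = g$log2gamma)
  expect_equal(m2$log2C, m1$log2C)
  expect_equal(m2$log2gamma, m1$log2gamma)
  expect_equal(m2$cv_surface, m1$cv_surface)
})

test_that("single-category sets degenerate correctly", {
  ts <- separable_training_set("kidney", n_per = 8L)
  expect_error(train_svm(ts, seed = 1), "two categories")
  m <- train_rf(ts, seed = 1)
  p <- predict_proba(m, ts)
  expect_true(all(p == 1))
  expect_equal(colnames(p), "kidney")
})

test_that("random forest probabilities are seeded vote fractions", {
  cats <- c("heart", "liver", "spleen")
  ts <- separable_training_set(cats, n_per = 15L, seed = 5)
  m1 <- train_rf(ts, n_trees = 500L, features_per_node = 2L, seed = 7)
  m2 <- train_rf(ts, n_trees = 500L, features_per_node = 2L, seed = 7)
  p1 <- predict_proba(m1, ts)
  p2 <- predict_proba(m2, ts)
  expect_identical(p1, p2)
  # probabilities are averaged tree votes: multiples of 1/n_trees
  expect_equal(p1 * 500, round(p1 * 500), tolerance = 1e-9)
  expect_equal(rowSums(p1), rep(1, nrow(ts)), tolerance = 1e-6)
  expect_error(train_rf(ts, features_per_node = 4L), "smaller")
})

test_that("probability prediction is row-wise and checks dimensions", {
  cats <- c("heart", "liver")
  ts <- separable_training_set(cats, n_per = 10L, seed = 6)
  m <- train_svm(ts, seed = 1, log2C = 1, log2gamma = 0)
  X <- as.matrix(ts[, paste0("b", 1:4)])
  p <- predict_proba(m, X)
  perm <- sample(nrow(X))
  expect_equal(predict_proba(m, X[perm, ]), p[perm, ], tolerance = 1e-12)
  expect_error(predict_proba(m, X[, 1:3]), "dimension")
})

test_that("reference pool sizes carry the expected category structure", {
  counts <- reference_category_counts()
  expect_setequal(names(counts), dce_categories())
  expect_equal(sum(counts), 451L)
  expect_equal(unname(counts["spleen"]), 19L)
  expect_equal(unname(counts["fat_muscle"]), 76L)
})
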