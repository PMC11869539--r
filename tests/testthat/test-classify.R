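test_that("nodule measurement does exact equivalent-diameter arithmetic", {
  # 100-pixel component at 0.5 mm spacing: area 25 mm^2, d = 2 sqrt(25/pi)
  m <- matrix(0L, 32, 32); m[11:20, 11:20] <- 1L
  meas <- measure_nodule(segmentation_mask(m, 0.5))
  expect_equal(meas$area_mm2, 25)
  expect_equal(meas$equivalent_diameter_mm, 2 * sqrt(25 / pi), tolerance = 1e-12)

  # empty mask -> empty result, not an error
  expect_equal(nrow(measure_nodule(segmentation_mask(matrix(0L, 8, 8)))), 0)

  # two components ordered by area, largest first
  m2 <- matrix(0L, 32, 32); m2[2:4, 2:4] <- 1L; m2[10:20, 10:20] <- 1L
  meas2 <- measure_nodule(segmentation_mask(m2, 1))
  expect_equal(nrow(meas2), 2)
  expect_true(meas2$area_mm2[1] > meas2$area_mm2[2])

  # phantom nodule of specified size measures back within a voxel
  ph <- generate_phantom(simple_spec(diameter_mm = 5, spacing = 0.5))
  got <- measure_nodule(ph$mask)
  expect_lt(abs(got$equivalent_diameter_mm[1] - 5), 0.5)
})

test_that("3-D components measure on their largest axial slice", {
  v <- array(0L, c(4, 16, 16))
  v[2, 4:9, 4:9] <- 1L     # 36 px
  v[3, 4:7, 4:7] <- 1L     # same component (overlaps), smaller slice
  meas <- measure_nodule(segmentation_mask(v, c(1, 0.5, 0.5)))
  expect_equal(nrow(meas), 1)
  expect_equal(meas$area_mm2, 36 * 0.25)
})

test_that("the 3 mm size rule is inclusive and monotone", {
  expect_identical(size_rule_classify(3.0), "malignant")
  expect_identical(size_rule_classify(2.9), "benign")
  expect_identical(size_rule_classify(0), "benign")
  d <- sort(runif(50, 0, 10))
  lab <- size_rule_classify(d)
  expect_true(all(diff(lab == "malignant") >= 0))  # once malignant, stays
})

test_that("the RBF kernel matches its closed form and is a valid kernel", {
  a <- c(1, 2, 3)
  expect_equal(rbf_kernel(a, a, s = 2), 1.0)
  b <- a + c(2, 0, 0)  # ||a-b||^2 = 4 = s^2
  expect_equal(rbf_kernel(a, b, s = 2), exp(-1))
  expect_equal(rbf_kernel(a, b, 1.3), rbf_kernel(b, a, 1.3))
  expect_error(rbf_kernel(a, b, -1), "> 0")
  expect_error(rbf_kernel(a, c(1, 2), 1), "unequal")

  # Gram matrices are symmetric positive semi-definite
  set.seed(8)
  X <- matrix(rnorm(20 * 4), 20, 4)
  G <- outer(1:20, 1:20, Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], s = 2)))
  expect_equal(G, t(G))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
})

test_that("SVM separates well-separated clusters and round-trips exactly", {
  cl <- gaussian_clusters(n_per_class = 100, separation = 4, seed = 13)
  idx <- rep(rep(c(TRUE, FALSE), c(3, 1)), 50)  # 75/25 holdout per class
  model <- train_svm(cl$X[idx, ], cl$y[idx])
  pred <- svm_classify(model, cl$X[!idx, ])
  expect_gte(mean(pred == cl$y[!idx]), 0.95)

  # save/load reproduces decision values bit-for-bit
  f <- withr::local_tempfile(fileext = ".rds")
  save_svm(model, f)
  m2 <- load_svm(f)
  d1 <- attr(svm_classify(model, cl$X, decision_values = TRUE), "decision_values")
  d2 <- attr(svm_classify(m2, cl$X, decision_values = TRUE), "decision_values")
  expect_identical(d1, d2)

  # contradictory duplicated labels train without crashing
  Xc <- rbind(cl$X[1:10, ], cl$X[1:10, ])
  yc <- c(rep("benign", 10), rep("malignant", 10))
  mc <- train_svm(Xc, yc)
  acc <- mean(svm_classify(mc, Xc) == yc)
  expect_gte(acc, 0.3); expect_lte(acc, 0.7)

  expect_error(train_svm(cl$X[1:5, ], rep("benign", 5)), "both classes")
  expect_error(svm_classify(model, cl$X[, 1:3]), "dimensionality")
})

test_that("SVM on extracted features recovers the size rule away from 3 mm", {
  tmpl <- phantom_spec(c(64, 64), 0.5, noise_sigma = 0.1)
  ds <- generate_dataset(60, tmpl, seed = 17, diameter_range_mm = c(2, 12),
                         fractions = c(train = 0.667, val = 0.166, test = 0.167))
  feats <- function(items) {
    do.call(rbind, lapply(items, function(it) extract_features(it$image, it$mask)))
  }
  lab <- function(items) vapply(items, function(it) it$labels[1], character(1))
  diam <- function(items) vapply(items, function(it) it$diameters_mm[1], numeric(1))
  Xtr <- feats(ds$train); Xte <- feats(c(ds$val, ds$test))
  model <- train_svm(Xtr, lab(ds$train))
  pred <- svm_classify(model, Xte)
  truth <- lab(c(ds$val, ds$test))
  far <- abs(diam(c(ds$val, ds$test)) - 3) >= 1
  expect_gte(mean(pred[far] == truth[far]), 0.95)
})

test_that("classify_nodules ties measurement and backends together", {
  ph <- generate_phantom(simple_spec(diameter_mm = 6))
  res <- classify_nodules(ph$mask, backend = "rule")
  expect_equal(res$label, "malignant")
  expect_error(classify_nodules(ph$mask, backend = "svm"), "svm_model")
})
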