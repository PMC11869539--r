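test_that("GLCM construction matches hand-enumerated pairs", {
  # [[0,1],[0,1]] with offset (0,1), asymmetric: both pairs are 0 -> 1
  w <- matrix(c(0, 0, 1, 1), 2, 2)
  g <- compute_glcm(w, config = glcm_config(levels = 2,
                                            offsets = rbind(c(0, 1)),
                                            symmetric = FALSE))
  expect_equal(g[1, 2], 1.0)
  expect_equal(sum(g), 1.0)

  # constant ROI: one diagonal entry
  gc <- compute_glcm(matrix(7, 4, 4))
  expect_equal(gc[1, 1], 1.0)
  expect_equal(glcm_entropy(gc), 0)
  expect_equal(glcm_homogeneity(gc), 1.0)

  # normalization holds for arbitrary input
  set.seed(2)
  g2 <- compute_glcm(matrix(runif(64), 8, 8))
  expect_lt(abs(sum(g2) - 1), 1e-12)
  expect_true(all(g2 >= 0))
})

test_that("GLCM features match the brute-force oracle on random images", {
  set.seed(10)
  for (i in 1:20) {
    w <- matrix(runif(64), 8, 8)
    cfg <- glcm_config(levels = sample(4:8, 1))
    g <- compute_glcm(w, config = cfg)
    ref <- brute_glcm(w, config = cfg)
    expect_lt(max(abs(g - ref)), 1e-12)
    st <- brute_glcm_stats(g)
    expect_lt(abs(glcm_contrast(g) - st$contrast), 1e-12)
    expect_lt(abs(glcm_homogeneity(g) - st$homogeneity), 1e-12)
    expect_lt(abs(glcm_entropy(g) - st$entropy), 1e-12)
    expect_lt(abs(glcm_correlation(g) - st$correlation), 1e-12)
  }
})

test_that("checkerboard texture has the closed-form GLCM statistics", {
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  axial <- glcm_config(levels = 2, offsets = rbind(c(0, 1), c(1, 0)))
  g <- compute_glcm(cb, config = axial)
  expect_equal(glcm_contrast(g), 1.0)        # every axial pair differs by 1
  expect_equal(glcm_homogeneity(g), 0.5)     # all mass at |x - y| = 1
  expect_equal(glcm_correlation(g), -1.0)    # perfect anti-correlation

  # monotone gradient aligned with the offset: correlation ~ 1
  gr <- matrix(rep(1:8, each = 8), 8, 8)
  gg <- compute_glcm(gr, config = glcm_config(levels = 8, offsets = rbind(c(1, 0)),
                                              symmetric = TRUE))
  expect_gt(glcm_correlation(gg), 0.9)
})

test_that("contrast and homogeneity move oppositely with texture frequency", {
  freqs <- c(8, 4, 2, 1)  # block sizes: coarser -> finer checkerboards
  cfg <- glcm_config(levels = 2, offsets = rbind(c(0, 1), c(1, 0)))
  stats <- sapply(freqs, function(bs) {
    m <- outer(1:16, 1:16, function(i, j) ((i - 1) %/% bs + (j - 1) %/% bs) %% 2)
    g <- compute_glcm(m, config = cfg)
    c(glcm_contrast(g), glcm_homogeneity(g))
  })
  expect_true(all(diff(stats[1, ]) > 0))   # contrast rises
  expect_true(all(diff(stats[2, ]) < 0))   # homogeneity falls
})

test_that("degenerate GLCM correlation errors; empty masks error", {
  gc <- compute_glcm(matrix(1, 4, 4))
  expect_error(glcm_correlation(gc), "zero variance")
  expect_error(compute_glcm(matrix(1, 3, 3), mask = matrix(0L, 3, 3)), "mask")
})

test_that("shape features recover analytic disk and ellipse geometry", {
  mk <- function(r, ab = c(1, 1)) {
    n <- 2 * ceiling(r * max(ab)) + 9; cx <- (n + 1) / 2
    outer(1:n, 1:n, function(i, j) (((i - cx) / ab[1])^2 + ((j - cx) / ab[2])^2) <= r^2) * 1
  }
  s <- shape_features(segmentation_mask(mk(20), 1))
  expect_gt(s$roundness, 0.9); expect_lt(s$roundness, 1.1)
  expect_gt(s$circularity, 0.9); expect_lt(s$circularity, 1.1)
  expect_gte(s$aspect_rate, 1.0); expect_lt(s$aspect_rate, 1.1)
  expect_lt(abs(s$area_mm2 - pi * 400) / (pi * 400), 0.05)
  expect_lt(abs(s$perimeter_mm - 2 * pi * 20) / (2 * pi * 20), 0.10)

  e <- shape_features(segmentation_mask(mk(20, c(2, 1)), 1))
  expect_lt(abs(e$aspect_rate - 2) / 2, 0.05)

  # area arithmetic: 10 pixels at 0.5 mm -> 2.5 mm^2
  m10 <- matrix(0L, 8, 8); m10[3:4, 2:6] <- 1L
  expect_equal(shape_features(segmentation_mask(m10, 0.5))$area_mm2, 2.5)

  expect_error(shape_features(segmentation_mask(matrix(0L, 4, 4))), "empty")
})

test_that("3-D shape features use the largest axial slice", {
  v <- array(0L, c(5, 32, 32))
  v[2, 10:20, 10:20] <- 1L   # 11x11 on slice 2
  v[4, 14:16, 14:16] <- 1L   # smaller blob elsewhere
  s <- shape_features(segmentation_mask(v, c(1, 0.5, 0.5)))
  expect_equal(s$area_mm2, 121 * 0.25)
})

test_that("histogram features match closed forms", {
  # delta distribution
  h <- histogram_features(rep(3.3, 10), rep(1, 10))
  expect_equal(h$uniformity, 1)
  expect_equal(h$standard_variance, 0)
  expect_equal(h$skewness, 0)
  expect_equal(h$smoothness, 0)

  # symmetric two-point distribution at +-1
  h2 <- histogram_features(c(rep(-1, 50), rep(1, 50)), rep(1, 100))
  expect_equal(h2$mean, 0, tolerance = 1e-12)
  expect_equal(h2$skewness, 0, tolerance = 1e-12)
  expect_equal(h2$standard_variance, 1, tolerance = 0.02)  # bin-center offset

  # uniform over l levels: uniformity = 1/l
  l <- 32L
  vals <- rep(seq(0, 1, length.out = l), times = 4)
  h3 <- histogram_features(vals, rep(1, length(vals)), levels = l)
  expect_equal(h3$uniformity, 1 / l, tolerance = 1e-12)

  expect_error(histogram_features(1, 1), ">= 2")
})

test_that("the combined feature vector honors its invariant bounds", {
  ph <- generate_phantom(simple_spec(diameter_mm = 8, noise_sigma = 0.15, seed = 4))
  fv <- extract_features(ph$image, ph$mask)
  expect_identical(names(fv), feature_names())
  expect_gt(fv$homogeneity, 0); expect_lte(fv$homogeneity, 1)
  expect_gt(fv$uniformity, 0); expect_lte(fv$uniformity, 1)
  expect_gte(fv$entropy, 0)
  expect_gte(fv$area_mm2, 0)
  expect_gte(fv$perimeter_mm, 0)
  expect_gte(fv$aspect_rate, 1)
})

test_that("shape depends only on the mask; texture only on intensities", {
  a <- generate_phantom(simple_spec(diameter_mm = 8, noise_sigma = 0.15, seed = 1))
  b <- generate_phantom(simple_spec(diameter_mm = 8, noise_sigma = 0.15, seed = 2))
  fa <- extract_features(a$image, a$mask)
  fb <- extract_features(b$image, b$mask)
  shape_cols <- c("area_mm2", "aspect_rate", "roundness", "perimeter_mm", "circularity")
  expect_equal(fa[, shape_cols], fb[, shape_cols])
  expect_false(isTRUE(all.equal(fa$entropy, fb$entropy)))

  # translating image+mask together leaves texture features unchanged
  sp_shift <- phantom_spec(c(64, 64), 0.5,
                           nodules = list(list(center = c(25, 40), diameter_mm = 8,
                                               intensity = 1)),
                           noise_sigma = 0, seed = 1)
  ph0 <- generate_phantom(simple_spec(diameter_mm = 8, noise_sigma = 0, seed = 1))
  ph1 <- generate_phantom(sp_shift)
  f0 <- extract_features(ph0$image, ph0$mask)
  f1 <- extract_features(ph1$image, ph1$mask)
  tex <- c("contrast", "homogeneity", "entropy", "uniformity", "mean",
           "standard_variance", "kurtosis", "skewness", "smoothness")
  expect_equal(f0[, tex], f1[, tex], tolerance = 1e-10)
})
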