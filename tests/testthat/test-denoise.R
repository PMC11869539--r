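test_that("z-score normalization centers and scales exactly", {
  v <- image_volume(matrix(c(0, 2, 0, 2), 2, 2))
  z <- zscore_normalize(v)
  expect_equal(sort(unique(as.vector(z$voxels))), c(-1, 1))

  set.seed(1)
  w <- image_volume(matrix(rnorm(100, 5, 3), 10, 10))
  z1 <- zscore_normalize(w)
  expect_lt(abs(mean(z1$voxels)), 1e-9)
  expect_lt(abs(sqrt(mean(z1$voxels^2)) - 1), 1e-9)
  # idempotent up to the affine identity
  z2 <- zscore_normalize(z1)
  expect_equal(z2$voxels, z1$voxels, tolerance = 1e-9)

  expect_error(zscore_normalize(image_volume(matrix(3, 4, 4))), "constant")
})

test_that("decomposition produces the named sub-bands with consistent shapes", {
  v2 <- image_volume(matrix(rnorm(256), 16, 16))
  sb2 <- decompose(v2, denoise_params())
  expect_setequal(names(sb2$levels[[1]]), c("LL", "LH", "HL", "HH"))

  v3 <- image_volume(array(rnorm(16^3), c(16, 16, 16)))
  sb3 <- decompose(v3, denoise_params())
  expect_setequal(names(sb3$levels[[1]]),
                  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_true(all(dim(sb3$levels[[1]]$HHH) == 9))  # (16 + 4 - 1) %/% 2

  # constant input -> detail bands vanish
  sbc <- decompose(image_volume(matrix(5, 16, 16)), denoise_params())
  expect_lt(max(abs(sbc$levels[[1]]$HH)), 1e-12)
  expect_lt(max(abs(sbc$levels[[1]]$LH)), 1e-12)

  expect_error(decompose(image_volume(matrix(0, 2, 16)), denoise_params()),
               "too short")
})

test_that("perfect reconstruction holds across shapes, wavelets and levels", {
  set.seed(7)
  cases <- list(list(c(16, 16), "haar", 1L), list(c(17, 23), "db2", 1L),
                list(c(30, 30), "db2", 2L), list(c(33, 19), "db4", 1L),
                list(c(12, 14, 10), "db2", 1L), list(c(16, 16, 16), "haar", 2L))
  for (cs in cases) {
    v <- image_volume(array(rnorm(prod(cs[[1]])), cs[[1]]))
    p <- denoise_params(wavelet_name = cs[[2]], levels = cs[[3]])
    r <- reconstruct(decompose(v, p))
    expect_lt(max(abs(r$voxels - v$voxels)), 1e-8)
  }
})

test_that("MAD noise estimator behaves on known inputs", {
  v <- image_volume(matrix(rnorm(64), 8, 8))
  sb <- decompose(v, denoise_params())
  sb$levels[[1]]$HH[] <- 0.6745
  expect_equal(estimate_noise_sigma(sb), 1.0)
  sb$levels[[1]]$HH[] <- 0
  expect_equal(estimate_noise_sigma(sb), 0)

  # Monte-Carlo: the MAD of N(0,1) coefficients estimates sigma = 1
  set.seed(11)
  sb$levels[[1]]$HH <- matrix(rnorm(1e4), 100, 100)
  expect_lt(abs(estimate_noise_sigma(sb) - 1), 0.05)
})

test_that("sub-band sigma and Bayesian threshold follow the shrinkage rule", {
  # sigma_b^2 = 5, sigma_N^2 = 1 -> sigma_sn = 2
  band <- sqrt(5)  # single coefficient with second moment 5
  expect_equal(estimate_subband_sigma(band, 1), 2)
  expect_equal(estimate_subband_sigma(c(1, -1), 5), 0)  # clamp
  expect_equal(estimate_subband_sigma(c(0, 0), 0), 0)

  expect_equal(bayes_threshold(1, 2), 0.5)
  expect_equal(bayes_threshold(2, 4), 1.0)
  expect_identical(bayes_threshold(1, 0), Inf)
  expect_identical(bayes_threshold(0, 0), 0)
})

test_that("gamma factor evaluates the cubic and rejects non-positive gains", {
  expect_equal(gamma_factor(123), 1)
  expect_equal(gamma_factor(2, c(0, 0, 1, 0)), 2)
  expect_equal(gamma_factor(2, c(1, 1, 1, 1)), 8 + 4 + 2 + 1)
  expect_error(gamma_factor(1, c(0, 0, 0, -1)), "positive")
})

test_that("soft and hard thresholding act per the rules", {
  expect_equal(apply_threshold(c(5, -5, 1, -1), 2, "soft"), c(3, -3, 0, 0))
  expect_equal(apply_threshold(c(5, -5, 1), 2, "hard"), c(5, -5, 0))
  # Inf threshold kills the band
  expect_equal(apply_threshold(c(5, -5), Inf, "soft"), c(0, 0))
  # soft thresholding is a contraction
  set.seed(3)
  x <- rnorm(100)
  expect_true(all(abs(apply_threshold(x, 0.4, "soft")) <= abs(x)))
})

test_that("denoising reduces noise and never changes geometry", {
  sp <- simple_spec(diameter_mm = 8, noise_sigma = 0, seed = 1)
  clean <- generate_phantom(sp)$image

  # noise-free input passes through almost unchanged
  dn0 <- denoise_volume(clean)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(dn0$volume$voxels - clean$voxels) / max(rms(clean$voxels), 1), 0.01)

  # noisy inputs: RMSE against the clean image drops, across seeds
  improved <- vapply(1:5, function(s) {
    spn <- simple_spec(diameter_mm = 8, noise_sigma = 0.25, seed = s)
    noisy <- generate_phantom(spn)$image
    dn <- denoise_volume(noisy)
    expect_identical(dim(dn$volume$voxels), dim(noisy$voxels))
    expect_identical(dn$volume$spacing_mm, noisy$spacing_mm)
    rms(dn$volume$voxels - clean$voxels) < rms(noisy$voxels - clean$voxels)
  }, logical(1))
  expect_true(all(improved))
})

test_that("denoising a pure-noise image shrinks the finest-band MAD", {
  set.seed(21)
  v <- image_volume(matrix(rnorm(64 * 64), 64, 64))
  dn <- denoise_volume(v)
  mad_in <- estimate_noise_sigma(decompose(v, denoise_params()))
  mad_out <- estimate_noise_sigma(decompose(dn$volume, denoise_params()))
  expect_lte(mad_out, mad_in)
})
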