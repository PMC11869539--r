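test_that("dice loss matches its closed forms and is symmetric", {
  t <- array(rbinom(64, 1, 0.4), c(8, 8))
  expect_lt(dice_loss(t, t), 1e-5)                  # perfect match
  expect_gt(dice_loss(1 - t, t), 0.999)             # disjoint
  # prediction covering exactly half the truth: 1 - 2k/(3k) = 1/3
  tr <- array(0, c(4, 4)); tr[1:2, ] <- 1
  pr <- array(0, c(4, 4)); pr[1, ] <- 1
  expect_equal(dice_loss(pr, tr), 1 / 3, tolerance = 1e-5)

  set.seed(1)
  a <- array(rbinom(64, 1, 0.5), c(8, 8))
  b <- array(rbinom(64, 1, 0.5), c(8, 8))
  expect_equal(dice_loss(a, b), dice_loss(b, a))
  expect_error(dice_loss(array(0.5, c(2, 2)), array(0, c(3, 3))), "shapes")
  expect_error(dice_loss(array(2, c(2, 2)), array(1, c(2, 2))), "probabilities")
})

test_that("the built network has the promised structure", {
  m <- build_network(network_config(), seed = 1)
  expect_lt(count_params(m), 2e6)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2, 1))
  fw <- ctnodule:::net_forward(m, x, train = TRUE)
  expect_equal(dim(fw$out), c(64L, 64L, 2L, 1L))
  expect_true(all(fw$out > 0 & fw$out < 1))
  # deterministic forward given fixed weights
  fw2 <- ctnodule:::net_forward(m, x, train = TRUE)
  expect_identical(fw$out, fw2$out)
  # encoder depth incompatible with input size is rejected
  expect_error(network_config(input_size = 60L), "divisible")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(5)
  m <- build_network(network_config(input_size = 8L, encoder_depth = 2L,
                                    width_multiplier = 0.2), seed = 5)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2, 1))
  fw <- ctnodule:::net_forward(m, x, TRUE)
  gp <- ctnodule:::net_backward(m, fw, ctnodule:::dice_loss_grad(fw$out, y))
  h <- 1e-5
  for (nm in sample(names(gp), 10)) {
    p <- m$params[[nm]]
    ii <- sample(length(p), 1)
    mp <- m
    mp$params[[nm]][ii] <- p[ii] + h
    lp <- dice_loss(ctnodule:::net_forward(mp, x, TRUE)$out, y)
    mp$params[[nm]][ii] <- p[ii] - h
    lm <- dice_loss(ctnodule:::net_forward(mp, x, TRUE)$out, y)
    num <- (lp - lm) / (2 * h)
    expect_lt(abs(num - gp[[nm]][ii]),
              1e-4 * max(1, abs(num) + abs(gp[[nm]][ii])))
  }
})

test_that("plateau rule drops the LR exactly once per plateau and stops at 10", {
  # flat validation losses: drop at epoch 5 (4 non-improving epochs)
  sch <- ctnodule:::lr_schedule_from_losses(rep(0.5, 12), lr0 = 0.1, factor = 0.01)
  expect_equal(sch$lrs[1:5], rep(0.1, 5))
  expect_equal(sch$lrs[6:9], rep(0.001, 4))
  expect_equal(sch$lrs[10], 0.00001)      # second plateau, second drop
  expect_equal(sch$stop_at, 11L)          # 10 epochs without improvement
  # three flat epochs then an improvement: counters reset, no drop at all
  sch2 <- ctnodule:::lr_schedule_from_losses(c(0.5, 0.4, 0.4, 0.4, 0.4, 0.3, 0.3),
                                             lr0 = 0.1, factor = 0.01)
  expect_equal(sch2$lrs, rep(0.1, 7))
  expect_true(is.na(sch2$stop_at))
})

test_that("a short training run learns, reproduces, and round-trips", {
  tmpl <- phantom_spec(c(32, 32), 0.5, noise_sigma = 0.1)
  ds <- generate_dataset(24, tmpl, seed = 3, diameter_range_mm = c(3, 10))
  tr <- as_patches(ds$train, 32, seed = 1)
  va <- as_patches(ds$val, 32, seed = 2)
  cfg <- network_config(input_size = 32L, encoder_depth = 3L, max_epochs = 4L)
  m <- build_network(cfg, seed = 2)
  r1 <- train_network(m, tr, va, cfg, seed = 9)
  expect_lt(r1$state$best_val_loss, dice_loss(array(0.5, c(32, 32)), tr[[1]]$y))
  expect_true(all(r1$state$history$val_loss >= 0 & r1$state$history$val_loss <= 1))
  expect_true(all(diff(r1$state$history$lr) <= 0))  # LR never increases

  # fixed seeds reproduce the whole loss trajectory
  r2 <- train_network(build_network(cfg, seed = 2), tr, va, cfg, seed = 9)
  expect_equal(r1$state$history$train_loss, r2$state$history$train_loss,
               tolerance = 1e-6)
  expect_equal(r1$state$history$val_loss, r2$state$history$val_loss,
               tolerance = 1e-6)

  # checkpoint round trip preserves predictions exactly
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_network(r1$model, f)
  m2 <- load_network(f)
  img <- image_volume(tr[[1]]$x, 0.5)
  expect_identical(predict_mask(r1$model, img)$voxels,
                   predict_mask(m2, img)$voxels)

  # training on all-zero masks degenerates gracefully
  tr0 <- lapply(tr[1:4], function(p) { p$y[] <- 0; p })
  r0 <- train_network(build_network(cfg, seed = 2), tr0, tr0[1],
                      network_config(input_size = 32L, encoder_depth = 3L,
                                     max_epochs = 2L), seed = 1)
  expect_true(all(is.finite(r0$state$history$train_loss)))
})

test_that("predict_mask thresholds correctly and preserves geometry", {
  cfg <- network_config(input_size = 32L, encoder_depth = 3L)
  m <- build_network(cfg, seed = 3)
  expect_error(predict_mask(m, image_volume(matrix(0, 32, 32))), "train")
  m$trained <- TRUE
  v <- image_volume(matrix(rnorm(48 * 40), 48, 40), c(0.7, 0.6))
  pm <- predict_mask(m, v, threshold = 1)   # nothing exceeds prob 1
  expect_identical(dim(pm$voxels), dim(v$voxels))
  expect_identical(pm$spacing_mm, v$spacing_mm)
  expect_equal(sum(pm$voxels), 0)
  pm0 <- predict_mask(m, v, threshold = 0)  # everything passes
  expect_equal(sum(pm0$voxels), length(v$voxels))
})
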