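#' Segmentation network configuration
#'
#' A MobileNetV2-style encoder (stem convolution followed by one
#' inverted-residual block - expand, depthwise-convolve, project - per
#' down-sampling stage, with stride-1 residual blocks in the two deepest
#' stages) feeding a U-Net decoder (nearest-neighbour upsampling, skip
#' concatenation with the encoder map of equal resolution, 3x3
#' convolution), ReLU activations inside and a single-channel sigmoid
#' output. Trained with Dice loss and Adam.
#'
#' The package default is the desk-scale preset used throughout the test
#' suite: 64x64 patches, width multiplier 0.35, depth 4, and a short
#' 15-epoch schedule whose learning rate (1e-2) is sized for that
#' schedule. [network_config_reference()] returns the
#' published full-scale training configuration (256x256 patches, learning
#' rate 1e-4, 90 epochs) for users with real data and patience.
#'
#' @param input_size square patch side; must be divisible by 2^encoder_depth.
#' @param batch_size minibatch size.
#' @param learning_rate initial Adam learning rate.
#' @param max_epochs training epoch cap.
#' @param width_multiplier encoder channel scale in (0, 1].
#' @param encoder_depth number of 2x down-sampling stages.
#' @param expansion inverted-residual expansion factor.
#' @param plateau_factor learning-rate multiplier applied after
#'   `plateau_patience` epochs without validation improvement.
#' @param plateau_patience consecutive non-improving epochs before the
#'   learning-rate drop (default 4).
#' @param early_stop_patience epochs without validation improvement before
#'   training stops (default 10).
#' @param pretrained_encoder load encoder weights from a checkpoint file
#'   given in `encoder_checkpoint` instead of random initialization.
#' @param encoder_checkpoint path used when `pretrained_encoder` is TRUE.
#' @return object of class `network_config`.
#' @export
network_config <- function(input_size = 64L, batch_size = 8L,
                           learning_rate = 1e-2, max_epochs = 15L,
                           width_multiplier = 0.35, encoder_depth = 4L,
                           expansion = 2L,
                           plateau_factor = 0.01, plateau_patience = 4L,
                           early_stop_patience = 10L,
                           pretrained_encoder = FALSE,
                           encoder_checkpoint = NULL) {
  cfg <- list(input_size = as.integer(input_size),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
              width_multiplier = width_multiplier,
              encoder_depth = as.integer(encoder_depth),
              expansion = as.integer(expansion),
              plateau_factor = plateau_factor,
              plateau_patience = as.integer(plateau_patience),
              early_stop_patience = as.integer(early_stop_patience),
              pretrained_encoder = isTRUE(pretrained_encoder),
              encoder_checkpoint = encoder_checkpoint)
  vals <- c(cfg$input_size, cfg$batch_size, cfg$learning_rate, cfg$max_epochs,
            cfg$width_multiplier, cfg$encoder_depth, cfg$expansion,
            cfg$plateau_factor, cfg$plateau_patience, cfg$early_stop_patience)
  if (any(vals <= 0)) stopf("all network hyperparameters must be positive")
  if (cfg$input_size %% 2L^cfg$encoder_depth != 0L) {
    stopf("input_size %d is not divisible by 2^%d; repeated 2x down-sampling needs that",
          cfg$input_size, cfg$encoder_depth)
  }
  structure(cfg, class = "network_config")
}

#' @rdname network_config
#' @export
network_config_reference <- function() {
  network_config(input_size = 256L, batch_size = 8L, learning_rate = 1e-4,
                 max_epochs = 90L, width_multiplier = 1, encoder_depth = 4L)
}

make_divisible <- function(v, div = 4L) pmax(div, as.integer(round(v / div) * div))

#' Build the segmentation model
#'
#' Constructs the layer graph and randomly initializes the weights
#' (He-normal convolutions, unit-gain batch norm). With
#' `config$pretrained_encoder` the encoder parameters are loaded from the
#' checkpoint file instead.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `seg_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  D <- config$encoder_depth
  base <- c(24, 48 * 1.5^(0:(D - 1)))
  ch <- make_divisible(base * config$width_multiplier)
  t <- config$expansion
  plan <- list()
  params <- list()
  add_conv <- function(name, cin, cout, k, stride, src, dst) {
    params[[paste0(name, "_W")]] <<- he_init(k * k * cin, cout, k * k * cin)
    params[[paste0(name, "_b")]] <<- numeric(cout)
    plan[[length(plan) + 1L]] <<- list(op = "conv", name = name, k = k,
                                       stride = stride, ins = src, out = dst)
  }
  add_dw <- function(name, c, stride, src, dst) {
    params[[paste0(name, "_W")]] <<- he_init(9L, c, 9L)
    params[[paste0(name, "_b")]] <<- numeric(c)
    plan[[length(plan) + 1L]] <<- list(op = "dwconv", name = name, k = 3L,
                                       stride = stride, ins = src, out = dst)
  }
  add_bn <- function(name, c, src, dst) {
    params[[paste0(name, "_g")]] <<- rep(1, c)
    params[[paste0(name, "_be")]] <<- numeric(c)
    plan[[length(plan) + 1L]] <<- list(op = "bn", name = name, ins = src, out = dst)
  }
  add_op <- function(op, src, dst) {
    plan[[length(plan) + 1L]] <<- list(op = op, ins = src, out = dst)
  }
  invres <- function(tag, cin, cout, stride, src) {
    cexp <- cin * t
    add_conv(paste0(tag, "_ex"), cin, cexp, 1L, 1L, src, paste0(tag, "_e"))
    add_bn(paste0(tag, "_bn1"), cexp, paste0(tag, "_e"), paste0(tag, "_e1"))
    add_op("relu", paste0(tag, "_e1"), paste0(tag, "_e2"))
    add_dw(paste0(tag, "_dw"), cexp, stride, paste0(tag, "_e2"), paste0(tag, "_d"))
    add_bn(paste0(tag, "_bn2"), cexp, paste0(tag, "_d"), paste0(tag, "_d1"))
    add_op("relu", paste0(tag, "_d1"), paste0(tag, "_d2"))
    add_conv(paste0(tag, "_pr"), cexp, cout, 1L, 1L, paste0(tag, "_d2"), paste0(tag, "_p"))
    add_bn(paste0(tag, "_bn3"), cout, paste0(tag, "_p"), paste0(tag, "_out"))
    if (stride == 1L && cin == cout) {
      add_op("add", c(paste0(tag, "_out"), src), paste0(tag, "_res"))
      paste0(tag, "_res")
    } else paste0(tag, "_out")
  }
  he_init <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  with_seed(seed, {
    # stem
    add_conv("stem", 1L, ch[1], 3L, 1L, "input", "stem_c")
    add_bn("stem_bn", ch[1], "stem_c", "stem_b")
    add_op("relu", "stem_b", "skip0")
    cur <- "skip0"
    for (i in seq_len(D)) {
      cur <- invres(sprintf("enc%d", i), ch[i], ch[i + 1], 2L, cur)
      if (i >= D - 1L) {
        cur <- invres(sprintf("enc%db", i), ch[i + 1], ch[i + 1], 1L, cur)
      }
      if (i < D) {
        add_op("ident", cur, sprintf("skip%d", i))
        cur <- sprintf("skip%d", i)
      }
    }
    for (i in rev(seq_len(D))) {
      add_op("upsample", cur, sprintf("dec%d_up", i))
      add_op("concat", c(sprintf("dec%d_up", i), sprintf("skip%d", i - 1L)),
             sprintf("dec%d_cat", i))
      cin <- ch[i + 1] + ch[i]
      add_conv(sprintf("dec%d", i), cin, ch[i], 3L, 1L,
               sprintf("dec%d_cat", i), sprintf("dec%d_c", i))
      add_bn(sprintf("dec%d_bn", i), ch[i], sprintf("dec%d_c", i),
             sprintf("dec%d_b", i))
      add_op("relu", sprintf("dec%d_b", i), sprintf("dec%d_out", i))
      cur <- sprintf("dec%d_out", i)
    }
    add_conv("head", ch[1], 1L, 1L, 1L, cur, "logits")
    add_op("sigmoid", "logits", "prob")
  })
  model <- structure(list(config = config, plan = plan, params = params,
                          bn_stats = list(), channels = ch, trained = FALSE),
                     class = "seg_network")
  if (config$pretrained_encoder) {
    if (is.null(config$encoder_checkpoint) || !file.exists(config$encoder_checkpoint)) {
      stopf("pretrained_encoder=TRUE requires an existing encoder_checkpoint file")
    }
    enc <- readRDS(config$encoder_checkpoint)
    keep <- intersect(names(enc$params), grep("^(stem|enc)", names(model$params), value = TRUE))
    model$params[keep] <- enc$params[keep]
  }
  model
}

#' Number of trainable parameters
#' @param model a `seg_network`.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.seg_network <- function(x, ...) {
  cat(sprintf("<seg_network> depth %d, width %.2f, channels %s, %d params, %s\n",
              x$config$encoder_depth, x$config$width_multiplier,
              paste(x$channels, collapse = "/"), count_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Forward pass over the op plan. Returns final output and per-op caches.
net_forward <- function(model, x4, train = TRUE) {
  vals <- list(input = x4)
  caches <- vector("list", length(model$plan))
  bn_batch <- list()
  for (i in seq_along(model$plan)) {
    op <- model$plan[[i]]
    r <- switch(op$op,
      conv = conv_fwd(vals[[op$ins]], model$params[[paste0(op$name, "_W")]],
                      model$params[[paste0(op$name, "_b")]], op$k, op$stride),
      dwconv = dwconv_fwd(vals[[op$ins]], model$params[[paste0(op$name, "_W")]],
                          model$params[[paste0(op$name, "_b")]], op$k, op$stride),
      bn = bn_fwd(vals[[op$ins]], model$params[[paste0(op$name, "_g")]],
                  model$params[[paste0(op$name, "_be")]],
                  train = train, stats = model$bn_stats[[op$name]]),
      relu = relu_fwd(vals[[op$ins]]),
      sigmoid = sigmoid_fwd(vals[[op$ins]]),
      upsample = upsample2_fwd(vals[[op$ins]]),
      ident = list(y = vals[[op$ins]], cache = NULL),
      add = list(y = vals[[op$ins[1]]] + vals[[op$ins[2]]], cache = NULL),
      concat = {
        a <- vals[[op$ins[1]]]; b <- vals[[op$ins[2]]]
        da <- dim(a); db_ <- dim(b)
        list(y = {
          out <- array(0, c(da[1], da[2], da[3], da[4] + db_[4]))
          out[, , , seq_len(da[4])] <- a
          out[, , , da[4] + seq_len(db_[4])] <- b
          out
        }, cache = c(da[4], db_[4]))
      },
      stopf("unknown op %s", op$op))
    vals[[op$out]] <- r$y
    caches[[i]] <- r$cache
    if (op$op == "bn" && train) bn_batch[[op$name]] <- r$batch_stats
  }
  list(out = vals[["prob"]], vals = vals, caches = caches, bn_batch = bn_batch)
}

# Backward pass: gradient of scalar loss wrt every parameter, given
# d(loss)/d(prob). Gradients on reused tensors accumulate.
net_backward <- function(model, fw, dprob) {
  grads <- list(prob = dprob)
  gp <- list()
  for (i in rev(seq_along(model$plan))) {
    op <- model$plan[[i]]
    dy <- grads[[op$out]]
    if (is.null(dy)) next
    acc <- function(var, g) grads[[var]] <<- if (is.null(grads[[var]])) g else grads[[var]] + g
    switch(op$op,
      conv = {
        r <- conv_bwd(dy, model$params[[paste0(op$name, "_W")]], fw$caches[[i]])
        gp[[paste0(op$name, "_W")]] <- r$dW; gp[[paste0(op$name, "_b")]] <- r$db
        acc(op$ins, r$dx)
      },
      dwconv = {
        r <- dwconv_bwd(dy, model$params[[paste0(op$name, "_W")]], fw$caches[[i]])
        gp[[paste0(op$name, "_W")]] <- r$dW; gp[[paste0(op$name, "_b")]] <- r$db
        acc(op$ins, r$dx)
      },
      bn = {
        r <- bn_bwd(dy, model$params[[paste0(op$name, "_g")]], fw$caches[[i]])
        gp[[paste0(op$name, "_g")]] <- r$dgamma; gp[[paste0(op$name, "_be")]] <- r$dbeta
        acc(op$ins, r$dx)
      },
      relu = acc(op$ins, relu_bwd(dy, fw$caches[[i]])),
      sigmoid = acc(op$ins, sigmoid_bwd(dy, fw$caches[[i]])),
      upsample = acc(op$ins, upsample2_bwd(dy, fw$caches[[i]])),
      ident = acc(op$ins, dy),
      add = { acc(op$ins[1], dy); acc(op$ins[2], dy) },
      concat = {
        ca <- fw$caches[[i]]
        acc(op$ins[1], dy[, , , seq_len(ca[1]), drop = FALSE])
        acc(op$ins[2], dy[, , , ca[1] + seq_len(ca[2]), drop = FALSE])
      })
  }
  gp
}

#' Dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum p + sum t + eps)` with eps = 1e-6,
#' computed over the whole array. Always in [0, 1]; 0 for a perfect binary
#' match, ~1 for disjoint prediction and truth. Symmetric in its
#' arguments.
#'
#' @param prediction probability array, values in [0, 1].
#' @param truth binary array of the same shape (a [segmentation_mask()]
#'   is also accepted).
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(prediction, truth, eps = 1e-6) {
  if (inherits(truth, "segmentation_mask")) truth <- truth$voxels
  if (inherits(prediction, "segmentation_mask")) prediction <- prediction$voxels
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(truth) %||% length(truth))) {
    stopf("dice_loss: prediction and truth shapes differ")
  }
  if (any(prediction < 0) || any(prediction > 1)) {
    stopf("dice_loss expects probabilities in [0, 1]")
  }
  s1 <- sum(prediction * truth)
  s2 <- sum(prediction) + sum(truth)
  1 - (2 * s1 + eps) / (s2 + eps)
}

dice_loss_grad <- function(prediction, truth, eps = 1e-6) {
  s1 <- sum(prediction * truth)
  s2 <- sum(prediction) + sum(truth)
  -(2 * truth * (s2 + eps) - (2 * s1 + eps)) / (s2 + eps)^2
}

## ---- training ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# Reduce-on-plateau / early-stop bookkeeping, exposed for unit testing:
# given the sequence of validation losses so far, returns the learning
# rate used at each epoch, whether training should stop, and the best
# epoch. A "plateau" is `patience` consecutive epochs without improving
# the best validation loss; each plateau multiplies the LR by `factor`.
lr_schedule_from_losses <- function(val_losses, lr0, factor = 0.01,
                                    patience = 4L, stop_patience = 10L) {
  lr <- lr0; best <- Inf; since <- 0L; since_drop <- 0L
  lrs <- numeric(length(val_losses)); stop_at <- NA_integer_; best_epoch <- NA_integer_
  for (e in seq_along(val_losses)) {
    lrs[e] <- lr
    if (val_losses[e] < best - 1e-12) {
      best <- val_losses[e]; best_epoch <- e; since <- 0L; since_drop <- 0L
    } else {
      since <- since + 1L; since_drop <- since_drop + 1L
      if (since_drop == patience) { lr <- lr * factor; since_drop <- 0L }
      if (since >= stop_patience && is.na(stop_at)) stop_at <- e
    }
  }
  list(lrs = lrs, stop_at = stop_at, best_epoch = best_epoch)
}

# z-score a single patch; constant patches pass through unchanged.
zscore_patch <- function(m) {
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

#' Assemble (patch, mask) training pairs from a phantom dataset split
#'
#' Each item's image is z-score normalized and center/random-cropped (or
#' reflect-padded) to `size` x `size`. Images already at the target size
#' pass through unchanged.
#'
#' @param items list of phantom items (`image`, `mask`).
#' @param size patch side.
#' @param seed crop-jitter seed.
#' @return list of `list(x = matrix, y = matrix)` pairs.
#' @export
as_patches <- function(items, size = 64L, seed = 1L) {
  jit <- derive_seeds(seed, length(items))
  lapply(seq_along(items), function(i) {
    img <- items[[i]]$image$voxels
    msk <- items[[i]]$mask$voxels
    if (length(dim(img)) == 3L) {  # largest-mask axial slice
      z <- which.max(apply(msk, 1L, sum))
      img <- img[z, , ]; msk <- msk[z, , ]
    }
    d <- dim(img)
    if (any(d < size)) {
      pad <- pmax(size - d, 0L)
      img <- img[c(seq_len(d[1]), rev(seq_len(pad[1]))), , drop = FALSE]
      msk <- msk[c(seq_len(d[1]), rev(seq_len(pad[1]))), , drop = FALSE]
      img <- img[, c(seq_len(d[2]), rev(seq_len(pad[2]))), drop = FALSE]
      msk <- msk[, c(seq_len(d[2]), rev(seq_len(pad[2]))), drop = FALSE]
      d <- dim(img)
    }
    off <- with_seed(jit[i], c(sample.int(d[1] - size + 1L, 1L),
                               sample.int(d[2] - size + 1L, 1L)))
    x <- img[off[1] + seq_len(size) - 1L, off[2] + seq_len(size) - 1L]
    y <- msk[off[1] + seq_len(size) - 1L, off[2] + seq_len(size) - 1L]
    list(x = zscore_patch(x), y = y)
  })
}

# Stack patches into the network's [H, W, B, C] layout (single channel).
stack_batch <- function(patches, idx) {
  S <- nrow(patches[[1]]$x)
  x <- array(0, c(S, S, length(idx), 1L))
  y <- array(0, c(S, S, length(idx), 1L))
  for (j in seq_along(idx)) {
    x[, , j, 1L] <- patches[[idx[j]]]$x
    y[, , j, 1L] <- patches[[idx[j]]]$y
  }
  list(x = x, y = y)
}

#' Train the segmentation network
#'
#' Minibatch Adam on Dice loss with the published schedule rules: when the
#' validation Dice loss fails to improve for `plateau_patience` (4)
#' consecutive epochs the learning rate is multiplied by `plateau_factor`;
#' after `early_stop_patience` (10) epochs without improvement training
#' stops; the best-validation weights are restored at the end. With a
#' fixed seed the whole loss trajectory is reproducible.
#'
#' @param model a `seg_network` from [build_network()].
#' @param train_patches,val_patches lists of `list(x, y)` pairs (see
#'   [as_patches()]); both must be nonempty.
#' @param config a [network_config()] (defaults to the model's).
#' @param seed shuffling seed.
#' @param verbose print per-epoch losses?
#' @return list with the trained `model` and `state` (class `train_state`):
#'   per-epoch train/validation Dice loss, learning rate, best epoch,
#'   epochs-without-improvement counter.
#' @export
train_network <- function(model, train_patches, val_patches,
                          config = model$config, seed = 1L, verbose = FALSE) {
  if (!length(train_patches) || !length(val_patches)) {
    stopf("train and validation splits must both be nonempty")
  }
  n <- length(train_patches)
  bs <- min(config$batch_size, n)
  lr <- config$learning_rate
  opt <- adam_init(model$params)
  best <- Inf; best_params <- model$params; best_bn <- model$bn_stats
  since <- 0L; since_drop <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  esd <- derive_seeds(seed, config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(esd[epoch], sample.int(n))
    tr_losses <- numeric()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      bt <- stack_batch(train_patches, idx)
      fw <- net_forward(model, bt$x, train = TRUE)
      # momentum-free running BN stats: exponential update per batch
      for (nm in names(fw$bn_batch)) {
        prev <- model$bn_stats[[nm]]
        cur <- fw$bn_batch[[nm]]
        model$bn_stats[[nm]] <- if (is.null(prev)) cur else {
          list(mean = 0.9 * prev$mean + 0.1 * cur$mean,
               var = 0.9 * prev$var + 0.1 * cur$var)
        }
      }
      loss <- dice_loss(fw$out, bt$y)
      tr_losses <- c(tr_losses, loss)
      dprob <- dice_loss_grad(fw$out, bt$y)
      gp <- net_backward(model, fw, dprob)
      upd <- adam_step(model$params, gp, opt, lr)
      model$params <- upd$params; opt <- upd$state
    }
    val_loss <- mean(vapply(val_patches, function(pp) {
      fw <- net_forward(model, array(pp$x, c(dim(pp$x), 1L, 1L)), train = FALSE)
      dice_loss(fw$out, array(pp$y, c(dim(pp$y), 1L, 1L)))
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(tr_losses),
                                   val_loss = val_loss, lr = lr))
    if (verbose) message(sprintf("epoch %2d  train %.4f  val %.4f  lr %.2g",
                                 epoch, mean(tr_losses), val_loss, lr))
    if (val_loss < best - 1e-12) {
      best <- val_loss; best_params <- model$params; best_bn <- model$bn_stats
      since <- 0L; since_drop <- 0L
    } else {
      since <- since + 1L; since_drop <- since_drop + 1L
      if (since_drop == config$plateau_patience) {
        lr <- lr * config$plateau_factor
        since_drop <- 0L
      }
      if (since >= config$early_stop_patience) break
    }
  }
  model$params <- best_params
  model$bn_stats <- best_bn
  model$trained <- TRUE
  state <- structure(list(history = hist, best_val_loss = best,
                          best_epoch = hist$epoch[which.min(hist$val_loss)],
                          epochs_since_improvement = since,
                          final_lr = lr),
                     class = "train_state")
  list(model = model, state = state)
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> %d epochs, best val Dice loss %.4f at epoch %d\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' Predict a segmentation mask for an image volume
#'
#' Tiles the (z-scored) image into `input_size` patches with 50% overlap,
#' averages the sigmoid probabilities at seams, and thresholds. 3-D
#' volumes are processed slice-wise along z. Output shape and spacing
#' always equal the input's.
#'
#' @param model a trained `seg_network`.
#' @param volume an [image_volume()].
#' @param threshold probability cut in [0, 1] (default 0.5).
#' @return a [segmentation_mask()].
#' @export
predict_mask <- function(model, volume, threshold = 0.5) {
  stopifnot(inherits(model, "seg_network"))
  if (!model$trained) stopf("model has not been trained; call train_network() first")
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  nd <- length(dim(v))
  if (nd == 3L) {
    out <- array(0L, dim(v))
    for (z in seq_len(dim(v)[1])) out[z, , ] <- predict_slice(model, v[z, , ], threshold)
    return(segmentation_mask(out, volume$spacing_mm))
  }
  segmentation_mask(predict_slice(model, v, threshold), volume$spacing_mm)
}

predict_slice <- function(model, m, threshold) {
  S <- model$config$input_size
  d <- dim(m)
  # reflect-pad up to a patch multiple
  target <- pmax(S, as.integer(ceiling(d / S) * S))
  pr <- reflect_pad_idx(d[1], target[1]); pc <- reflect_pad_idx(d[2], target[2])
  mp <- m[pr, pc]
  dp <- dim(mp)
  prob <- array(0, dp); wt <- array(0, dp)
  step <- max(S %/% 2L, 1L)
  r_starts <- unique(pmin(seq(1L, dp[1], by = step), dp[1] - S + 1L))
  c_starts <- unique(pmin(seq(1L, dp[2], by = step), dp[2] - S + 1L))
  for (r0 in r_starts) for (c0 in c_starts) {
    tile <- zscore_patch(mp[r0 + seq_len(S) - 1L, c0 + seq_len(S) - 1L])
    fw <- net_forward(model, array(tile, c(S, S, 1L, 1L)), train = FALSE)
    prob[r0 + seq_len(S) - 1L, c0 + seq_len(S) - 1L] <-
      prob[r0 + seq_len(S) - 1L, c0 + seq_len(S) - 1L] + fw$out[, , 1, 1]
    wt[r0 + seq_len(S) - 1L, c0 + seq_len(S) - 1L] <-
      wt[r0 + seq_len(S) - 1L, c0 + seq_len(S) - 1L] + 1
  }
  ((prob / wt)[seq_len(d[1]), seq_len(d[2])] >= threshold) * 1L
}

reflect_pad_idx <- function(n, target) {
  if (target <= n) return(seq_len(n))
  extra <- target - n
  c(seq_len(n), rev(seq_len(n))[seq_len(extra)])
}

#' Save / load a trained network checkpoint
#'
#' Single-file checkpoint with a versioned header; round trips are exact,
#' so decision values reproduce bit-for-bit.
#'
#' @param model a `seg_network`.
#' @param path checkpoint file.
#' @export
save_network <- function(model, path) {
  saveRDS(list(format = "ctnodule-seg-1", config = model$config,
               plan = model$plan, params = model$params,
               bn_stats = model$bn_stats, channels = model$channels,
               trained = model$trained), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ctnodule-seg-1")) stopf("not a ctnodule network checkpoint: %s", path)
  structure(x[c("config", "plan", "params", "bn_stats", "channels", "trained")],
            class = "seg_network")
}
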