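#' End-to-end pipeline configuration
#'
#' One structured configuration drives the whole run: phantom synthesis,
#' denoising, feature extraction, network training, segmentation of the
#' held-out split, benign/malignant classification and evaluation. Every
#' stochastic stage derives its stream from the single global `seed`.
#'
#' @param out_dir run directory (created; all outputs go here, inputs are
#'   never modified).
#' @param seed global integer seed.
#' @param n_phantoms dataset size.
#' @param image_shape,spacing_mm,noise_sigma,diameter_range_mm,lung_field
#'   phantom synthesis settings (see [phantom_spec()] /
#'   [generate_dataset()]).
#' @param fractions train/val/test split fractions.
#' @param stages character vector of enabled stages, a subset of
#'   `c("synth", "denoise", "features", "train", "segment", "classify",
#'   "evaluate")` in pipeline order.
#' @param denoise a [denoise_params()].
#' @param glcm a [glcm_config()].
#' @param network a [network_config()].
#' @param classifier_backend `"rule"`, `"svm"`, or
#'   `"svm_with_rule_fallback"`.
#' @param mask_threshold probability cut for [predict_mask()].
#' @param export_files write per-item image/mask files (slower but fully
#'   inspectable)? Default TRUE.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ctnodule_run_"),
                            seed = 1L,
                            n_phantoms = 20L,
                            image_shape = c(64L, 64L), spacing_mm = 0.5,
                            noise_sigma = 0.2,
                            diameter_range_mm = c(2, 12),
                            lung_field = list(center = c(32.5, 32.5),
                                              semiaxes_mm = c(14, 14),
                                              level = -0.5),
                            fractions = c(train = 0.6, val = 0.2, test = 0.2),
                            stages = c("synth", "denoise", "features", "train",
                                       "segment", "classify", "evaluate"),
                            denoise = denoise_params(),
                            glcm = glcm_config(),
                            network = network_config(),
                            classifier_backend = "rule",
                            mask_threshold = 0.5,
                            export_files = TRUE) {
  all_stages <- c("synth", "denoise", "features", "train", "segment",
                  "classify", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  need <- list(denoise = "synth", features = "denoise", train = "denoise",
               segment = "train", classify = "segment", evaluate = "classify")
  for (s in stages) {
    dep <- need[[s]]
    if (!is.null(dep) && !dep %in% stages) {
      stopf("stage '%s' is enabled but its upstream stage '%s' is not", s, dep)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_phantoms = as.integer(n_phantoms),
                 image_shape = image_shape, spacing_mm = spacing_mm,
                 noise_sigma = noise_sigma,
                 diameter_range_mm = diameter_range_mm,
                 lung_field = lung_field, fractions = fractions,
                 stages = stages, denoise = denoise, glcm = glcm,
                 network = network,
                 classifier_backend = classifier_backend,
                 mask_threshold = mask_threshold,
                 export_files = isTRUE(export_files)),
            class = "pipeline_config")
}

#' Run the integrated pipeline
#'
#' Executes the enabled stages in architecture order (pre-processing,
#' feature extraction, segmentation, classification, evaluation), writes
#' all artifacts under `config$out_dir`, and returns a manifest recording
#' the package version, seeds, per-stage outputs with md5 checksums, and
#' the evaluation metrics. Any stage failure aborts with a message naming
#' the stage. Two runs with the same config and seed produce identical
#' artifacts and manifests up to timestamps.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress?
#' @return the manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(config$seed, 8L)
  manifest <- list(package = "ctnodule",
                   version = as.character(utils::packageVersion("ctnodule")),
                   seed = config$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  art <- function(paths) {
    paths <- paths[file.exists(paths)]
    lapply(paths, function(p) list(path = basename(p),
                                   md5 = unname(tools::md5sum(p))))
  }
  run_stage <- function(name, fn) {
    say("[%s]", name)
    tryCatch(fn(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  env <- new.env()

  if ("synth" %in% config$stages) {
    run_stage("synth", function() {
      tmpl <- phantom_spec(config$image_shape, config$spacing_mm,
                           background_level = 0,
                           lung_field = config$lung_field,
                           noise_sigma = config$noise_sigma,
                           seed = seeds[1])
      env$data <- generate_dataset(config$n_phantoms, tmpl, seed = seeds[1],
                                   fractions = config$fractions,
                                   diameter_range_mm = config$diameter_range_mm)
      files <- character(0)
      if (config$export_files) {
        for (split in names(env$data)) {
          d <- file.path(config$out_dir, "phantoms", split)
          for (it in env$data[[split]]) {
            files <- c(files, export_phantom(it, d, sprintf("phantom_%03d", it$id)))
          }
        }
      }
      manifest$stages$synth <<- list(
        n = config$n_phantoms,
        split_sizes = as.list(lengths(env$data)),
        artifacts = art(files))
    })
  }

  if ("denoise" %in% config$stages) {
    run_stage("denoise", function() {
      logs <- list()
      for (split in names(env$data)) {
        env$data[[split]] <- lapply(env$data[[split]], function(it) {
          dn <- denoise_volume(zscore_normalize(it$image), config$denoise)
          it$denoised <- dn$volume
          logs[[length(logs) + 1L]] <<- cbind(id = it$id, sigma_n = dn$sigma_n, dn$log)
          it
        })
      }
      log_df <- do.call(rbind, logs)
      lf <- file.path(config$out_dir, "denoise_log.csv")
      utils::write.csv(log_df, lf, row.names = FALSE)
      manifest$stages$denoise <<- list(
        params = config$denoise[c("wavelet_name", "levels", "threshold_mode")],
        mean_sigma_n = mean(log_df$sigma_n), artifacts = art(lf))
    })
  }

  if ("features" %in% config$stages) {
    run_stage("features", function() {
      rows <- list()
      for (split in names(env$data)) {
        for (it in env$data[[split]]) {
          fv <- extract_features(it$denoised, it$mask, config$glcm)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(id = it$id, split = split, label = it$labels[1],
                       diameter_mm = it$diameters_mm[1]), fv)
        }
      }
      env$features <- do.call(rbind, rows)
      ff <- file.path(config$out_dir, "features.csv")
      utils::write.csv(env$features, ff, row.names = FALSE)
      manifest$stages$features <<- list(n_rows = nrow(env$features),
                                        artifacts = art(ff))
    })
  }

  if ("train" %in% config$stages) {
    run_stage("train", function() {
      get_img <- function(it) image_volume(it$denoised$voxels, it$denoised$spacing_mm)
      tr_items <- lapply(env$data$train, function(it) list(image = get_img(it), mask = it$mask))
      va_items <- lapply(env$data$val, function(it) list(image = get_img(it), mask = it$mask))
      tr <- as_patches(tr_items, config$network$input_size, seed = seeds[2])
      va <- as_patches(va_items, config$network$input_size, seed = seeds[3])
      model <- build_network(config$network, seed = seeds[4])
      res <- train_network(model, tr, va, config$network, seed = seeds[5])
      env$model <- res$model
      env$train_state <- res$state
      ck <- file.path(config$out_dir, "network.ckpt")
      save_network(res$model, ck)
      lg <- file.path(config$out_dir, "training_log.csv")
      utils::write.csv(res$state$history, lg, row.names = FALSE)
      manifest$stages$train <<- list(
        epochs_run = nrow(res$state$history),
        best_val_dice_loss = res$state$best_val_loss,
        best_epoch = res$state$best_epoch,
        artifacts = art(c(ck, lg)))
    })
  }

  if ("segment" %in% config$stages) {
    run_stage("segment", function() {
      files <- character(0)
      dices <- numeric(0)
      env$data$test <- lapply(env$data$test, function(it) {
        pm <- predict_mask(env$model, it$denoised, config$mask_threshold)
        it$pred_mask <- pm
        dices <<- c(dices, 1 - dice_loss(pm$voxels * 1.0, it$mask$voxels))
        if (config$export_files) {
          f <- file.path(config$out_dir, "pred_masks",
                         sprintf("pred_%03d.png", it$id))
          dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
          write_mask(pm, f)
          files <<- c(files, f)
        }
        it
      })
      env$test_dice <- dices
      manifest$stages$segment <<- list(
        n_test = length(dices), mean_dice = mean(dices),
        artifacts = art(files))
    })
  }

  if ("classify" %in% config$stages) {
    run_stage("classify", function() {
      backend <- config$classifier_backend
      svm_model <- NULL
      if (backend %in% c("svm", "svm_with_rule_fallback")) {
        trf <- env$features[env$features$split == "train", ]
        svm_model <- train_svm(trf[, feature_names()], trf$label)
        save_svm(svm_model, file.path(config$out_dir, "svm.ckpt"))
      }
      calls <- lapply(env$data$test, function(it) {
        res <- classify_nodules(it$pred_mask, image = it$denoised,
                                backend = backend, svm_model = svm_model,
                                glcm = config$glcm)
        # single-nodule phantoms: the largest component is the call;
        # an empty prediction has diameter 0 -> benign
        if (nrow(res) == 0) {
          data.frame(id = it$id, equivalent_diameter_mm = 0,
                     predicted = "benign", truth = it$labels[1])
        } else {
          data.frame(id = it$id,
                     equivalent_diameter_mm = res$equivalent_diameter_mm[1],
                     predicted = res$label[1], truth = it$labels[1])
        }
      })
      env$calls <- do.call(rbind, calls)
      cf <- file.path(config$out_dir, "classification.csv")
      utils::write.csv(env$calls, cf, row.names = FALSE)
      manifest$stages$classify <<- list(backend = backend,
                                        n = nrow(env$calls),
                                        artifacts = art(cf))
    })
  }

  if ("evaluate" %in% config$stages) {
    run_stage("evaluate", function() {
      cc <- confusion(env$calls$predicted, env$calls$truth)
      mets <- compute_metrics(cc)
      ev <- file.path(config$out_dir, "metrics.json")
      jsonlite::write_json(list(counts = unclass(cc), metrics = as.list(mets)),
                           ev, auto_unbox = TRUE, digits = NA, null = "null")
      manifest$stages$evaluate <<- list(counts = unclass(cc),
                                        metrics = as.list(mets),
                                        artifacts = art(ev))
    })
  }

  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  say("manifest written to %s", mf)
  invisible(manifest)
}
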