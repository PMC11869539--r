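#' Measure nodules in a segmentation mask
#'
#' Finds connected components (8-connectivity in 2-D, 26-connectivity in
#' 3-D), measures each on its largest axial slice, and reports the area
#' (pixel count x pixel area) and the equivalent circular diameter
#' `2 sqrt(area / pi)`. Components are ordered by area, largest first.
#' An empty mask yields an empty result, not an error.
#'
#' @param mask a [segmentation_mask()].
#' @return data.frame with `component_id`, `area_mm2`,
#'   `equivalent_diameter_mm`, `voxels`.
#' @export
measure_nodule <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  lab <- label_components(mask$voxels)
  n <- max(lab)
  if (n == 0) {
    return(data.frame(component_id = integer(), area_mm2 = numeric(),
                      equivalent_diameter_mm = numeric(), voxels = integer()))
  }
  nd <- length(dim(mask$voxels))
  px_area <- if (nd == 2L) prod(mask$spacing_mm) else prod(mask$spacing_mm[2:3])
  rows <- lapply(seq_len(n), function(i) {
    comp <- lab == i
    if (nd == 3L) {
      sl_areas <- apply(comp, 1L, sum)
      npx <- max(sl_areas)    # largest axial slice of this component
    } else {
      npx <- sum(comp)
    }
    area <- npx * px_area
    data.frame(component_id = i, area_mm2 = area,
               equivalent_diameter_mm = 2 * sqrt(area / pi),
               voxels = sum(comp))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$area_mm2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Connected-component labeling, 8-connectivity (2-D) / 26-connectivity
# (3-D). EBImage handles the 2-D case; 3-D uses slice-wise labels merged
# with a union-find pass across adjacent slices.
label_components <- function(v) {
  nd <- length(dim(v))
  if (nd == 2L) return(EBImage::bwlabel(v))
  nz <- dim(v)[1]
  labs <- array(0L, dim(v))
  offset <- 0L
  for (z in seq_len(nz)) {
    l <- EBImage::bwlabel(v[z, , ])
    l[l > 0] <- l[l > 0] + offset
    labs[z, , ] <- l
    offset <- max(offset, max(l))
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  dyx <- expand.grid(dy = -1:1, dx = -1:1)
  for (z in seq_len(nz - 1L)) {
    a <- labs[z, , ]; b <- labs[z + 1L, , ]
    nr <- nrow(a); nc <- ncol(a)
    for (j in seq_len(nrow(dyx))) {
      dy <- dyx$dy[j]; dx <- dyx$dx[j]
      y1 <- max(1, 1 - dy):min(nr, nr - dy)
      x1 <- max(1, 1 - dx):min(nc, nc - dx)
      aa <- a[y1, x1]; bb <- b[y1 + dy, x1 + dx]
      ok <- which(aa > 0 & bb > 0)
      if (length(ok)) {
        pairs <- unique(cbind(aa[ok], bb[ok]))
        for (r in seq_len(nrow(pairs))) union2(pairs[r, 1], pairs[r, 2])
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  labs[labs > 0] <- dense[labs[labs > 0]]
  labs
}

#' Benign/malignant size rule
#'
#' A nodule with equivalent diameter >= 3.0 mm (inclusive) is called
#' malignant; smaller ones benign. Monotone in diameter.
#'
#' @param diameter_mm nonnegative diameter(s), or the data.frame returned
#'   by [measure_nodule()].
#' @return character vector of `"benign"` / `"malignant"`.
#' @export
size_rule_classify <- function(diameter_mm) {
  if (is.data.frame(diameter_mm)) diameter_mm <- diameter_mm$equivalent_diameter_mm
  if (any(diameter_mm < 0)) stopf("diameters must be >= 0")
  ifelse(diameter_mm >= 3.0, "malignant", "benign")
}

#' Radial basis function kernel
#'
#' `R(a, b) = exp(-||a - b||^2 / s^2)` with kernel scale `s > 0` (note the
#' `s^2` denominator; set `standard_form = TRUE` for the common `2 s^2`
#' variant). Symmetric, in (0, 1], equal to 1 iff a = b.
#'
#' @param a,b equal-length numeric vectors.
#' @param s positive kernel scale.
#' @param standard_form use the 2 s^2 denominator instead.
#' @return kernel value.
#' @export
rbf_kernel <- function(a, b, s, standard_form = FALSE) {
  if (length(a) != length(b)) stopf("rbf_kernel: vectors of unequal length (%d vs %d)",
                                    length(a), length(b))
  if (!is.numeric(s) || length(s) != 1 || s <= 0) stopf("kernel scale s must be > 0")
  den <- if (standard_form) 2 * s^2 else s^2
  exp(-sum((a - b)^2) / den)
}

#' Train the RBF-kernel SVM nodule classifier
#'
#' A maximum-margin binary classifier in the RBF-induced feature space,
#' fitted on standardized feature rows (the per-feature mean/scale are
#' stored in the model and re-applied at prediction). The kernel scale
#' `s` maps onto the usual gamma parametrization as gamma = 1/s^2, so the
#' fitted machine uses exactly [rbf_kernel()] as its similarity.
#'
#' @param features numeric matrix or data.frame, one row per nodule (e.g.
#'   rows of [extract_features()]).
#' @param labels factor/character of `"benign"` / `"malignant"` (both
#'   classes must be present).
#' @param s kernel scale (default `sqrt(ncol(features))`, i.e. gamma =
#'   1/ncol, the conventional default).
#' @param C regularization constant (default 1).
#' @return object of class `svm_model`.
#' @export
train_svm <- function(features, labels, s = sqrt(ncol(features)), C = 1) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stopf("SVM training needs both classes present, got only: %s",
          paste(unique(labels), collapse = ""))
  }
  if (nrow(X) != length(labels)) stopf("features/labels length mismatch")
  mu <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sc, `/`)
  y <- factor(labels, levels = c("benign", "malignant"))
  fit <- e1071::svm(Xs, y, type = "C-classification", kernel = "radial",
                    gamma = 1 / s^2, cost = C, scale = FALSE)
  structure(list(fit = fit, center = mu, scale = sc, s = s, C = C,
                 feature_names = colnames(X)),
            class = "svm_model")
}

#' Classify feature rows with a trained SVM
#'
#' Deterministic sign-of-decision-function classification into
#' benign/malignant.
#'
#' @param model an `svm_model` from [train_svm()].
#' @param features matrix/data.frame with the same columns used in
#'   training.
#' @param decision_values also return the raw decision values?
#' @return character labels (with a `decision_values` attribute if
#'   requested).
#' @export
svm_classify <- function(model, features, decision_values = FALSE) {
  stopifnot(inherits(model, "svm_model"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (ncol(X) != length(model$center)) {
    stopf("feature dimensionality %d does not match model (%d)",
          ncol(X), length(model$center))
  }
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  pr <- stats::predict(model$fit, Xs, decision.values = decision_values)
  out <- as.character(pr)
  if (decision_values) {
    attr(out, "decision_values") <- as.numeric(attr(pr, "decision.values"))
  }
  out
}

#' Save / load an SVM model
#'
#' Round trips reproduce decision values bit-for-bit.
#' @param model an `svm_model`.
#' @param path file path.
#' @export
save_svm <- function(model, path) {
  saveRDS(list(format = "ctnodule-svm-1", model = model), path)
  invisible(path)
}

#' @rdname save_svm
#' @export
load_svm <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ctnodule-svm-1")) stopf("not a ctnodule SVM file: %s", path)
  x$model
}

#' Classify every nodule in a mask
#'
#' The end-of-pipeline call: measures connected components and applies the
#' configured backend. `"rule"` uses [size_rule_classify()] alone;
#' `"svm"` uses a trained SVM on extracted features; and
#' `"svm_with_rule_fallback"` uses the SVM where features are computable
#' and falls back to the size rule otherwise.
#'
#' @param mask a [segmentation_mask()].
#' @param image the paired [image_volume()] (required for SVM backends).
#' @param backend `"rule"`, `"svm"`, or `"svm_with_rule_fallback"`.
#' @param svm_model an `svm_model` (required for SVM backends).
#' @param glcm a [glcm_config()] for feature extraction.
#' @return data.frame: per-component measurements plus `label`.
#' @export
classify_nodules <- function(mask, image = NULL,
                             backend = c("rule", "svm", "svm_with_rule_fallback"),
                             svm_model = NULL, glcm = glcm_config()) {
  backend <- match.arg(backend)
  meas <- measure_nodule(mask)
  if (nrow(meas) == 0) {
    meas$label <- character(0)
    return(meas)
  }
  if (backend == "rule") {
    meas$label <- size_rule_classify(meas)
    return(meas)
  }
  if (is.null(svm_model) || is.null(image)) {
    stopf("backend '%s' needs both an image and a trained svm_model", backend)
  }
  lab_arr <- label_components(mask$voxels)
  labels <- character(nrow(meas))
  for (i in seq_len(nrow(meas))) {
    comp_mask <- segmentation_mask((lab_arr == meas$component_id[i]) * 1L,
                                   mask$spacing_mm)
    fv <- tryCatch(extract_features(image, comp_mask, glcm), error = function(e) NULL)
    labels[i] <- if (is.null(fv)) {
      if (backend == "svm_with_rule_fallback") {
        size_rule_classify(meas$equivalent_diameter_mm[i])
      } else {
        stopf("feature extraction failed for component %d", meas$component_id[i])
      }
    } else {
      svm_classify(svm_model, fv)
    }
  }
  meas$label <- labels
  meas
}
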