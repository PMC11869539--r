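#' Specification of a synthetic CT phantom
#'
#' Describes a reproducible CT-like test image: a uniform background, an
#' optional darker elliptical "lung field", one or more bright ellipsoidal
#' nodules of known physical diameter, and additive Gaussian noise. The
#' phantom emulates, at desk scale, the kind of inputs found in public
#' lung-CT collections (nodules of a few mm to a few cm on a dark lung
#' background) so every pipeline stage can be exercised against exact
#' ground truth.
#'
#' A voxel belongs to a nodule when its *center* lies inside the nodule
#' ellipsoid; the rasterized mask is therefore unambiguous and noise-free
#' (noise is added after rasterization). Identical specs (including seed)
#' produce bit-identical output.
#'
#' @param image_shape integer vector of voxels per axis: (y, x) or (z, y, x).
#' @param spacing_mm mm per voxel per axis (scalar recycled).
#' @param background_level background intensity (HU-like, arbitrary units).
#' @param lung_field NULL, or `list(center=, semiaxes_mm=, level=)` giving an
#'   ellipse/ellipsoid (center in voxel coordinates, semi-axes in mm) filled
#'   at intensity `level`.
#' @param nodules list of nodules, each `list(center=, diameter_mm=,
#'   intensity=, axis_ratio=)`: center in voxel coordinates (may be
#'   fractional), physical diameter in mm, additive intensity, and optional
#'   per-axis semi-axis ratios (default 1 = sphere; the semi-axis along axis
#'   i is `diameter_mm/2 * axis_ratio[i]`).
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed driving the single noise stream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(64, 64), spacing_mm = 0.5,
                         background_level = 0,
                         lung_field = NULL,
                         nodules = list(),
                         noise_sigma = 0, seed = 1L) {
  image_shape <- as.integer(image_shape)
  nd <- length(image_shape)
  if (!nd %in% c(2L, 3L)) stopf("image_shape must be 2-D or 3-D")
  if (any(image_shape < 4L)) stopf("image_shape axes must be >= 4 voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be positive, one per axis")
  }
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  nodules <- lapply(nodules, normalize_nodule, nd = nd)
  spec <- structure(list(image_shape = image_shape, spacing_mm = spacing_mm,
                         background_level = background_level,
                         lung_field = lung_field, nodules = nodules,
                         noise_sigma = noise_sigma, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

normalize_nodule <- function(nod, nd) {
  if (is.null(nod$center) || is.null(nod$diameter_mm)) {
    stopf("each nodule needs center and diameter_mm")
  }
  nod$center <- as.numeric(nod$center)
  if (length(nod$center) != nd) stopf("nodule center must have %d coordinates", nd)
  nod$intensity <- nod$intensity %||% 1
  ar <- nod$axis_ratio %||% rep(1, nd)
  if (length(ar) == 1L) ar <- rep(ar, nd)
  if (length(ar) != nd || any(ar <= 0)) stopf("axis_ratio must be positive, one per axis")
  nod$axis_ratio <- as.numeric(ar)
  nod
}

validate_phantom_spec <- function(spec) {
  nd <- length(spec$image_shape)
  for (i in seq_along(spec$nodules)) {
    nod <- spec$nodules[[i]]
    if (nod$diameter_mm / min(spec$spacing_mm) < 2) {
      stopf("nodule %d: diameter %.3g mm spans < 2 voxels at spacing %.3g mm",
            i, nod$diameter_mm, min(spec$spacing_mm))
    }
    semi_vox <- (nod$diameter_mm / 2 * nod$axis_ratio) / spec$spacing_mm
    lo <- nod$center - semi_vox
    hi <- nod$center + semi_vox
    if (any(lo < 1) || any(hi > spec$image_shape)) {
      stopf("nodule %d (center %s, diameter %.3g mm) extends outside image bounds",
            i, paste(signif(nod$center, 4), collapse = ","), nod$diameter_mm)
    }
    if (!is.null(spec$lung_field)) {
      lf <- spec$lung_field
      cdist <- sqrt(sum((((nod$center - lf$center) * spec$spacing_mm) / lf$semiaxes_mm)^2))
      bulge <- max((nod$diameter_mm / 2 * nod$axis_ratio) / lf$semiaxes_mm)
      if (cdist + bulge > 1 + 1e-9) {
        stopf("nodule %d does not lie fully inside the lung field", i)
      }
    }
  }
  invisible(spec)
}

# Squared normalized ellipsoid distance of every voxel center to an
# ellipsoid (center in voxels, semi-axes in mm). Returns an array.
ellipsoid_field <- function(shape, spacing_mm, center, semiaxes_mm) {
  nd <- length(shape)
  ax <- lapply(seq_len(nd), function(i) {
    ((seq_len(shape[i]) - center[i]) * spacing_mm[i] / semiaxes_mm[i])^2
  })
  if (nd == 2L) {
    outer(ax[[1]], ax[[2]], `+`)
  } else {
    d <- array(0, shape)
    d <- d + ax[[1]]                                 # recycles along dim 1
    d <- d + rep(ax[[2]], each = shape[1])
    d <- d + rep(ax[[3]], each = shape[1] * shape[2])
    d
  }
}

#' Generate a synthetic phantom
#'
#' Rasterizes the background, lung field and nodules of a [phantom_spec()],
#' producing the image, the exact ground-truth nodule mask (voxel centers
#' inside any nodule ellipsoid), and a per-nodule benign/malignant label
#' from the >= 3 mm diameter rule applied to the *specified* diameter.
#' Gaussian noise is added after mask rasterization, so the mask is exact.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` ([image_volume()]), `mask`
#'   ([segmentation_mask()]), `labels` (character per nodule),
#'   `diameters_mm`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  shape <- spec$image_shape
  img <- array(spec$background_level, shape)
  if (!is.null(spec$lung_field)) {
    lf <- spec$lung_field
    inside <- ellipsoid_field(shape, spec$spacing_mm, lf$center, lf$semiaxes_mm) <= 1
    img[inside] <- lf$level %||% (spec$background_level - 1)
  }
  mask <- array(0L, shape)
  for (nod in spec$nodules) {
    semi <- nod$diameter_mm / 2 * nod$axis_ratio
    inside <- ellipsoid_field(shape, spec$spacing_mm, nod$center, semi) <= 1
    img[inside] <- img[inside] + nod$intensity
    mask[inside] <- 1L
  }
  if (spec$noise_sigma > 0) {
    img <- img + with_seed(spec$seed,
                           array(stats::rnorm(prod(shape), 0, spec$noise_sigma), shape))
  }
  diam <- vapply(spec$nodules, `[[`, numeric(1), "diameter_mm")
  list(image = image_volume(img, spec$spacing_mm, source_id = "phantom"),
       mask = segmentation_mask(mask, spec$spacing_mm),
       labels = if (length(diam)) ifelse(diam >= 3, "malignant", "benign") else character(0),
       diameters_mm = diam,
       spec = spec)
}

#' Generate a reproducible phantom dataset with train/val/test splits
#'
#' Draws `n` single-nodule phantoms from a spec template: nodule diameters
#' are sampled uniformly from `diameter_range_mm` (default 2-30 mm,
#' covering the 3-30 mm annotated range of public lung-CT collections plus
#' sub-3 mm benign cases) and nodule centers uniformly over positions that
#' keep the nodule inside the lung field (or image). Splits are disjoint
#' by construction and the whole draw is a pure function of `seed`.
#'
#' @param n number of phantoms (>= 3).
#' @param spec_template a [phantom_spec()] whose geometry/noise settings are
#'   reused for every item; its nodule list is replaced per item.
#' @param seed integer seed.
#' @param fractions named numeric (train, val, test) summing to 1.
#' @param diameter_range_mm sampled nodule diameter range in mm.
#' @return list of `train`, `val`, `test`; each a list of phantom items as
#'   returned by [generate_phantom()].
#' @export
generate_dataset <- function(n, spec_template = phantom_spec(), seed = 1L,
                             fractions = c(train = 0.6, val = 0.2, test = 0.2),
                             diameter_range_mm = c(2, 30)) {
  if (!is_count(n) || n < 3) stopf("n must be an integer >= 3")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("split fractions must sum to 1")
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  if (any(counts < 1)) {
    stopf("n = %d too small for fractions (%s): some split would be empty",
          n, paste(signif(fractions, 3), collapse = "/"))
  }
  shape <- spec_template$image_shape
  sp <- spec_template$spacing_mm
  seeds <- derive_seeds(seed, n + 1L)
  items <- with_seed(seeds[n + 1L], {
    lapply(seq_len(n), function(i) {
      d <- stats::runif(1, diameter_range_mm[1], diameter_range_mm[2])
      semi_vox <- (d / 2) / sp
      ok <- FALSE
      for (try in 1:200) {
        ctr <- vapply(seq_along(shape), function(a) {
          stats::runif(1, 1 + semi_vox[a] + 1, shape[a] - semi_vox[a] - 1)
        }, numeric(1))
        sp_i <- try(phantom_spec(shape, sp,
                                 background_level = spec_template$background_level,
                                 lung_field = spec_template$lung_field,
                                 nodules = list(list(center = ctr, diameter_mm = d,
                                                     intensity = 1)),
                                 noise_sigma = spec_template$noise_sigma,
                                 seed = seeds[i]),
                    silent = TRUE)
        if (!inherits(sp_i, "try-error")) { ok <- TRUE; break }
      }
      if (!ok) stopf("could not place a %.3g mm nodule inside the field", d)
      c(generate_phantom(sp_i), list(id = i))
    })
  })
  idx <- with_seed(seeds[n + 1L] %% 1000000L + 7L, sample.int(n))
  bounds <- cumsum(counts)
  list(train = items[idx[seq_len(bounds[1])]],
       val   = items[idx[(bounds[1] + 1):bounds[2]]],
       test  = items[idx[(bounds[2] + 1):bounds[3]]])
}

#' Export one phantom to image + mask files with a JSON sidecar
#'
#' 2-D phantoms are written as 16-bit PNG (image) and 8-bit {0,255} PNG
#' (mask); 3-D phantoms as NIfTI. The sidecar records the generating spec,
#' ground-truth diameters and labels, and the PNG intensity scale so the
#' float image can be recovered exactly to 16-bit precision.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
export_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- length(dim(phantom$image$voxels))
  ext <- if (nd == 2L) ".png" else ".nii.gz"
  img_path <- file.path(dir, paste0(stem, ext))
  mask_path <- file.path(dir, paste0(stem, "_mask", ext))
  info <- write_image(phantom$image, img_path)
  write_mask(phantom$mask, mask_path)
  sidecar <- file.path(dir, paste0(stem, ".json"))
  spec <- phantom$spec
  jsonlite::write_json(
    list(image = basename(img_path), mask = basename(mask_path),
         image_shape = spec$image_shape, spacing_mm = spec$spacing_mm,
         background_level = spec$background_level,
         noise_sigma = spec$noise_sigma, seed = spec$seed,
         nodules = spec$nodules,
         labels = phantom$labels, diameters_mm = phantom$diameters_mm,
         intensity_range = info$intensity_range),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(image = img_path, mask = mask_path, sidecar = sidecar))
}
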