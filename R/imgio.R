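#' Image volume container
#'
#' The carrier of all image math in the pipeline: a 2-D or 3-D grayscale
#' voxel array with per-axis spacing in millimetres. Intensities are
#' unbounded floats (HU-like, arbitrary units); quantization only happens
#' inside the feature-extraction stage. Axis order is fixed as (y, x) for
#' 2-D and (z, y, x) for 3-D; all readers permute into this convention.
#'
#' @param voxels numeric array, 2-D or 3-D.
#' @param spacing_mm numeric vector, mm per voxel along each axis (same
#'   order as the array dimensions); all entries must be positive.
#' @param source_id free-text provenance string.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = rep(1, length(dim(voxels))),
                         source_id = "") {
  if (is.null(dim(voxels))) dim(voxels) <- c(1L, length(voxels))
  nd <- length(dim(voxels))
  if (!nd %in% c(2L, 3L)) stopf("image_volume must be 2-D or 3-D, got %d dims", nd)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd) stopf("spacing_mm must have one entry per axis")
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be positive and finite")
  }
  structure(list(voxels = voxels + 0.0, spacing_mm = spacing_mm,
                 source_id = as.character(source_id)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' A binary voxel array aligned voxel-for-voxel with its paired
#' [image_volume()]: identical shape and spacing, values in {0, 1}.
#'
#' @param voxels array of 0/1 (logical or numeric).
#' @param spacing_mm mm per voxel per axis.
#' @return an object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, spacing_mm = rep(1, length(dim(voxels)))) {
  if (is.null(dim(voxels))) dim(voxels) <- c(1L, length(voxels))
  v <- voxels
  storage.mode(v) <- "integer"
  bad <- setdiff(unique(as.vector(v)), c(0L, 1L))
  if (length(bad)) stopf("mask values must be 0/1; found: %s",
                         paste(utils::head(bad, 5), collapse = ", "))
  nd <- length(dim(v))
  if (!nd %in% c(2L, 3L)) stopf("segmentation_mask must be 2-D or 3-D")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be positive, one entry per axis")
  }
  structure(list(voxels = v, spacing_mm = spacing_mm),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s voxels, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

check_pair <- function(image, mask) {
  if (!identical(dim(image$voxels), dim(mask$voxels))) {
    stopf("image and mask shapes differ: %s vs %s",
          paste(dim(image$voxels), collapse = "x"),
          paste(dim(mask$voxels), collapse = "x"))
  }
  if (!isTRUE(all.equal(image$spacing_mm, mask$spacing_mm))) {
    stopf("image and mask spacing differ")
  }
  invisible(TRUE)
}

## ---- PNG -------------------------------------------------------------

# Minimal 16-bit grayscale PNG writer. The png package reads 16-bit PNGs
# but only writes 8-bit, so the 16-bit dialect is emitted here directly:
# IHDR/IDAT/IEND chunks, filter type 0, zlib stream via memCompress.
write_png16 <- function(img01, path) {
  h <- nrow(img01); w <- ncol(img01)
  if (any(img01 < 0) || any(img01 > 1)) stopf("write_png16 expects values in [0,1]")
  u <- round(img01 * 65535)
  be32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
  chunk <- function(type, data) {
    td <- c(charToRaw(type), data)
    c(be32(length(data)), td, writeBin(crc32(td), raw(), size = 4, endian = "big"))
  }
  sl <- raw(h * (1L + 2L * w))
  for (r in seq_len(h)) {
    off <- (r - 1L) * (1L + 2L * w)
    sl[off + 1L + seq_len(2L * w)] <-
      writeBin(as.integer(u[r, ]), raw(), size = 2, endian = "big")
  }
  ihdr <- c(be32(w), be32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr),
           chunk("IDAT", memCompress(sl, "gzip")),
           chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

## ---- Readers / writers ------------------------------------------------

#' Read a grayscale image into an [image_volume()]
#'
#' Supported formats: PNG (8/16-bit grayscale), NIfTI-1 (`.nii`, `.nii.gz`)
#' and single-frame uncompressed DICOM. Spacing is taken from the NIfTI
#' header (`pixdim`) or the DICOM PixelSpacing / SliceThickness elements;
#' a missing or unparseable DICOM PixelSpacing is a hard error, never a
#' silent default. PNG carries no physical spacing, so 1.0 mm per pixel is
#' assumed and a warning is emitted.
#'
#' PNG intensities arrive on the [0, 1] scale that `png::readPNG` uses
#' (16-bit precision preserved); NIfTI and DICOM keep their stored units
#' (DICOM rescale slope/intercept applied when present).
#'
#' @param path file to read.
#' @param format `"auto"` (by extension) or one of `"png"`, `"nifti"`,
#'   `"dicom"`.
#' @return an [image_volume()].
#' @export
read_image <- function(path, format = c("auto", "png", "nifti", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    png = {
      warning("PNG carries no physical spacing; assuming 1.0 mm per pixel",
              call. = FALSE)
      v <- png::readPNG(path)
      if (length(dim(v)) == 3L) v <- v[, , 1L]  # drop color channels
      image_volume(v, spacing_mm = c(1, 1), source_id = path)
    },
    nifti = {
      img <- RNifti::readNifti(path)
      v <- as.array(img)
      pd <- RNifti::pixdim(img)
      nd <- length(dim(v))
      if (!nd %in% c(2L, 3L)) stopf("NIfTI with %d dims not supported", nd)
      # NIfTI stores (x, y, z); permute to internal (z, y, x)
      if (nd == 3L) {
        v <- aperm(v, c(3L, 2L, 1L))
        sp <- rev(pd[seq_len(3L)])
      } else {
        v <- t(v)
        sp <- rev(pd[seq_len(2L)])
      }
      image_volume(v, spacing_mm = sp, source_id = path)
    },
    dicom = read_dicom_image(path)
  )
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) return("png")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.dcm$", lp) || grepl("\\.ima$", lp)) return("dicom")
  stopf("cannot guess image format from path: %s", path)
}

#' Write an [image_volume()] to PNG (2-D, 16-bit) or NIfTI
#'
#' 2-D volumes written to `.png` are min-max scaled to the 16-bit range;
#' the scale is returned so callers (e.g. the phantom exporter sidecar)
#' can invert it. NIfTI output stores raw float intensities and spacing.
#'
#' @param volume an [image_volume()].
#' @param path output path, `.png` or `.nii`/`.nii.gz`.
#' @return invisibly, a list with `path` and the `intensity_range` used
#'   for PNG scaling (NULL for NIfTI).
#' @export
write_image <- function(volume, path) {
  fmt <- guess_format(path)
  if (fmt == "png") {
    if (length(dim(volume$voxels)) != 2L) stopf("PNG export requires a 2-D volume")
    rng <- range(volume$voxels)
    den <- if (diff(rng) > 0) diff(rng) else 1
    write_png16((volume$voxels - rng[1]) / den, path)
    return(invisible(list(path = path, intensity_range = rng)))
  }
  if (fmt == "nifti") {
    v <- volume$voxels
    nd <- length(dim(v))
    if (nd == 3L) {
      out <- aperm(v, c(3L, 2L, 1L)); sp <- rev(volume$spacing_mm)
    } else {
      out <- t(v); sp <- rev(volume$spacing_mm)
    }
    img <- RNifti::asNifti(out)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    return(invisible(list(path = path, intensity_range = NULL)))
  }
  stopf("unsupported output format for %s", path)
}

#' Write / read a binary [segmentation_mask()]
#'
#' Dialects: PNG 8-bit with values {0, 255}, or NIfTI uint8 {0, 1}. Round
#' trips are bit-exact. Reading a PNG mask with any pixel value other than
#' 0 or 255 (or a NIfTI mask outside {0,1}) is an error that lists the
#' offending values.
#'
#' @param mask a [segmentation_mask()].
#' @param path `.png` (2-D) or `.nii`/`.nii.gz`.
#' @export
write_mask <- function(mask, path) {
  fmt <- guess_format(path)
  if (fmt == "png") {
    if (length(dim(mask$voxels)) != 2L) stopf("PNG mask export requires 2-D")
    png::writePNG(mask$voxels * 1.0, path)  # {0,1} -> 8-bit {0,255}
  } else if (fmt == "nifti") {
    v <- mask$voxels
    nd <- length(dim(v))
    out <- if (nd == 3L) aperm(v, c(3L, 2L, 1L)) else t(v)
    sp <- rev(mask$spacing_mm)
    img <- RNifti::asNifti(out)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else stopf("unsupported mask format for %s", path)
  invisible(path)
}

#' @rdname write_mask
#' @param spacing_mm spacing to attach when reading PNG masks (PNG stores
#'   none); ignored for NIfTI, which carries its own.
#' @export
read_mask <- function(path, spacing_mm = NULL) {
  fmt <- guess_format(path)
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  if (fmt == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    u <- round(v * 255)
    bad <- setdiff(unique(as.vector(u)), c(0, 255))
    if (length(bad)) stopf("mask PNG has non-binary values: %s",
                           paste(utils::head(bad, 8), collapse = ", "))
    segmentation_mask((u == 255) * 1L, spacing_mm %||% c(1, 1))
  } else if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    v <- as.array(img)
    pd <- RNifti::pixdim(img)
    nd <- length(dim(v))
    bad <- setdiff(unique(as.vector(v)), c(0, 1))
    if (length(bad)) stopf("mask NIfTI has non-binary values: %s",
                           paste(utils::head(bad, 8), collapse = ", "))
    if (nd == 3L) {
      v <- aperm(v, c(3L, 2L, 1L)); sp <- rev(pd[1:3])
    } else {
      v <- t(v); sp <- rev(pd[1:2])
    }
    segmentation_mask(v, sp)
  } else stopf("unsupported mask format for %s", path)
}
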