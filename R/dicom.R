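# Minimal DICOM reader: explicit-VR little-endian, uncompressed monochrome
# pixel data. No R DICOM parser is shipped with this package's dependency
# set, and the pipeline only needs pixel data plus geometry, so the subset
# of PS3.10 required for that is parsed here directly. Unsupported transfer
# syntaxes fail loudly rather than guessing.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_u16 <- function(con) readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
read_u32 <- function(con) readBin(con, "integer", size = 4, endian = "little")

# Parse one data set (after the preamble / meta header) into a tag->value list.
parse_dicom_elements <- function(raw, start) {
  con <- rawConnection(raw)
  on.exit(close(con))
  seek(con, start)
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (seek(con, NA) < n) {
    grp <- read_u16(con); el <- read_u16(con)
    if (length(grp) == 0) break
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% long_vrs) {
      readBin(con, "raw", 2)  # reserved
      len <- read_u32(con)
    } else {
      len <- read_u16(con)
    }
    if (is.na(len) || len < 0) stopf("DICOM element (%04x,%04x) with undefined length unsupported", grp, el)
    val <- readBin(con, "raw", len)
    tag <- sprintf("%04x%04x", grp, el)
    out[[tag]] <- list(vr = vr, bytes = val)
  }
  out
}

dcm_str <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$bytes))
}

dcm_u16 <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read a single-frame DICOM file
#'
#' Supports explicit-VR little-endian transfer syntax with uncompressed
#' monochrome pixel data (8 or 16 bits allocated). Pixel spacing is taken
#' from PixelSpacing (0028,0030); its absence is a hard error because a
#' CT pipeline must not silently assume geometry. Rescale slope/intercept
#' are applied when present.
#'
#' @param path DICOM file.
#' @return an [image_volume()] (2-D).
#' @export
read_dicom_image <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 136 || rawToChar(raw[129:132]) != "DICM") {
    stopf("not a DICOM part-10 file (missing DICM magic): %s", path)
  }
  els <- parse_dicom_elements(raw, 132)
  ts <- dcm_str(els, "00020010")
  if (!is.null(ts) && ts != DCM_EXPLICIT_LE) {
    stopf("unsupported DICOM transfer syntax %s in %s", ts, path)
  }
  rows <- dcm_u16(els, "00280010"); cols <- dcm_u16(els, "00280011")
  if (is.null(rows) || is.null(cols)) stopf("DICOM missing Rows/Columns: %s", path)
  ps <- dcm_str(els, "00280030")
  if (is.null(ps) || !nzchar(ps)) {
    stopf("DICOM PixelSpacing (0028,0030) missing in %s; refusing to default", path)
  }
  sp <- suppressWarnings(as.numeric(strsplit(ps, "\\\\")[[1]]))
  if (length(sp) != 2 || any(is.na(sp)) || any(sp <= 0)) {
    stopf("DICOM PixelSpacing unparseable ('%s') in %s", ps, path)
  }
  bits <- dcm_u16(els, "00280100") %||% 16L
  pixrep <- dcm_u16(els, "00280103") %||% 0L
  pd <- els[["7fe00010"]]
  if (is.null(pd)) stopf("DICOM missing PixelData in %s", path)
  vals <- if (bits == 16L) {
    readBin(pd$bytes, "integer", n = rows * cols, size = 2,
            endian = "little", signed = pixrep == 1L)
  } else if (bits == 8L) {
    readBin(pd$bytes, "integer", n = rows * cols, size = 1, signed = FALSE)
  } else stopf("unsupported BitsAllocated=%d in %s", bits, path)
  slope <- as.numeric(dcm_str(els, "00281053") %||% "1")
  inter <- as.numeric(dcm_str(els, "00281052") %||% "0")
  # PixelData is row-major (rows of the image); fill by row -> (y, x)
  m <- matrix(vals * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  # PixelSpacing is (row spacing, column spacing) = (y, x): already our order
  image_volume(m, spacing_mm = sp, source_id = path)
}

#' Read a multi-frame DICOM series into one 3-D volume
#'
#' Slices are assembled in ascending InstanceNumber (0020,0013) order;
#' slice spacing comes from SliceThickness (0018,0050).
#'
#' @param paths character vector of single-frame DICOM files.
#' @return an [image_volume()] (3-D, axes z,y,x).
#' @export
read_dicom_series <- function(paths) {
  if (!length(paths)) stopf("empty DICOM series")
  inst <- vapply(paths, function(p) {
    raw <- readBin(p, "raw", file.size(p))
    els <- parse_dicom_elements(raw, 132)
    as.integer(dcm_str(els, "00200013") %||% NA_character_)
  }, integer(1))
  if (any(is.na(inst))) stopf("DICOM series member missing InstanceNumber")
  ord <- order(inst)
  slices <- lapply(paths[ord], read_dicom_image)
  sp2 <- slices[[1]]$spacing_mm
  dims <- dim(slices[[1]]$voxels)
  raw1 <- readBin(paths[ord][1], "raw", file.size(paths[ord][1]))
  st <- as.numeric(dcm_str(parse_dicom_elements(raw1, 132), "00180050") %||% "1")
  vol <- array(0, c(length(slices), dims))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]$voxels), dims)) stopf("DICOM series slice shapes differ")
    vol[i, , ] <- slices[[i]]$voxels
  }
  image_volume(vol, spacing_mm = c(st, sp2), source_id = paths[ord][1])
}
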