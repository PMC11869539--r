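# Shared fixtures: all inputs are generated in code at test time.

# One-nodule 2-D phantom spec centered in a 64x64 field.
simple_spec <- function(diameter_mm = 5, noise_sigma = 0, seed = 1L,
                        shape = c(64, 64), spacing = 0.5, intensity = 1) {
  phantom_spec(shape, spacing,
               nodules = list(list(center = (shape + 1) / 2,
                                   diameter_mm = diameter_mm,
                                   intensity = intensity)),
               noise_sigma = noise_sigma, seed = seed)
}

# Brute-force GLCM oracle: enumerate every in-mask pixel pair per offset.
brute_glcm <- function(window, mask = NULL, config = glcm_config()) {
  if (is.null(mask)) mask <- array(1L, dim(window))
  n <- config$levels
  vals <- window[mask == 1]
  rng <- range(vals)
  lv <- matrix(NA_integer_, nrow(window), ncol(window))
  if (diff(rng) == 0) {
    lv[mask == 1] <- 0L
  } else {
    q <- floor((window - rng[1]) / diff(rng) * n)
    lv[mask == 1] <- pmin(q[mask == 1], n - 1)
  }
  counts <- matrix(0, n, n)
  for (k in seq_len(nrow(config$offsets))) {
    dy <- config$offsets[k, 1]; dx <- config$offsets[k, 2]
    for (i in seq_len(nrow(window))) for (j in seq_len(ncol(window))) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 >= 1 && i2 <= nrow(window) && j2 >= 1 && j2 <= ncol(window) &&
          !is.na(lv[i, j]) && !is.na(lv[i2, j2])) {
        counts[lv[i, j] + 1, lv[i2, j2] + 1] <-
          counts[lv[i, j] + 1, lv[i2, j2] + 1] + 1
      }
    }
  }
  if (config$symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Brute-force GLCM summary statistics straight from the matrix definition.
brute_glcm_stats <- function(g) {
  n <- nrow(g)
  con <- 0; hom <- 0; ent <- 0
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    p <- g[x + 1, y + 1]
    con <- con + p * (x - y)^2
    hom <- hom + p / (1 + abs(x - y))
    if (p > 0) ent <- ent - p * log(p)
  }
  px <- rowSums(g); py <- colSums(g)
  mx <- sum((0:(n - 1)) * px); my <- sum((0:(n - 1)) * py)
  sx <- sqrt(sum(((0:(n - 1)) - mx)^2 * px))
  sy <- sqrt(sum(((0:(n - 1)) - my)^2 * py))
  cor <- 0
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    cor <- cor + g[x + 1, y + 1] * (x - mx) * (y - my) / (sx * sy)
  }
  list(contrast = con, homogeneity = hom, entropy = ent, correlation = cor)
}

# Minimal synthetic DICOM writer (explicit VR little endian) used to test
# the reader without shipping binary fixtures.
write_synthetic_dicom <- function(path, pixels, spacing = c(0.7, 0.7),
                                  instance = 1L, slice_thickness = 1.0,
                                  omit_spacing = FALSE) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  el_short <- function(grp, el, vr, bytes) {
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(if (vr %in% c("UI")) 0 else 0x20))
    c(u16(grp), u16(el), charToRaw(vr), u16(length(bytes)), bytes)
  }
  el_long <- function(grp, el, vr, bytes) {
    c(u16(grp), u16(el), charToRaw(vr), as.raw(c(0, 0)), u32(length(bytes)), bytes)
  }
  str_el <- function(grp, el, vr, s) el_short(grp, el, vr, charToRaw(s))
  rows <- nrow(pixels); cols <- ncol(pixels)
  px <- as.integer(round(t(pixels)))  # row-major pixel order
  body <- c(
    str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    str_el(0x0008, 0x0060, "CS", "CT"),
    str_el(0x0018, 0x0050, "DS", format(slice_thickness)),
    str_el(0x0020, 0x0013, "IS", as.character(instance)),
    el_short(0x0028, 0x0010, "US", u16(rows)),
    el_short(0x0028, 0x0011, "US", u16(cols)),
    if (!omit_spacing) str_el(0x0028, 0x0030, "DS",
                              paste(format(spacing), collapse = "\\")) else raw(0),
    el_short(0x0028, 0x0100, "US", u16(16L)),
    el_short(0x0028, 0x0103, "US", u16(0L)),
    el_long(0x7fe0, 0x0010, "OW", writeBin(px, raw(), size = 2, endian = "little"))
  )
  writeBin(c(raw(128), charToRaw("DICM"), body), path)
  invisible(path)
}

# Tiny two-class Gaussian feature clusters for SVM tests.
gaussian_clusters <- function(n_per_class = 100, separation = 4, d = 5, seed = 1L) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per_class * d), n_per_class, d)
  x2 <- matrix(rnorm(n_per_class * d), n_per_class, d)
  x2[, 1] <- x2[, 1] + separation
  X <- rbind(x1, x2)
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = rep(c("benign", "malignant"), each = n_per_class))
}
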