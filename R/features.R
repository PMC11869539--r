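#' Gray-level co-occurrence matrix configuration
#'
#' @param levels number of gray levels n (>= 2) after uniform quantization
#'   of the ROI's min-max intensity range.
#' @param offsets integer matrix, one displacement vector (dy, dx) per row;
#'   default the four standard 2-D directions at distance 1.
#' @param symmetric count each pair in both orders?
#' @return object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 8L,
                        offsets = rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                        symmetric = TRUE) {
  if (!is_count(levels) || levels < 2) stopf("levels must be an integer >= 2")
  offsets <- rbind(offsets)
  if (any(rowSums(abs(offsets)) == 0)) stopf("offsets must be nonzero")
  structure(list(levels = as.integer(levels), offsets = offsets,
                 symmetric = isTRUE(symmetric)),
            class = "glcm_config")
}

# Uniform quantization of in-mask intensities into 0..(n-1).
quantize_levels <- function(values, n) {
  rng <- range(values)
  if (diff(rng) == 0) return(rep(0L, length(values)))
  q <- floor((values - rng[1]) / diff(rng) * n)
  as.integer(pmin(q, n - 1L))
}

#' Normalized gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray levels at the configured
#' offsets, restricted to pixel pairs with *both* pixels inside the mask,
#' sums the counts over offsets (plus transposes when symmetric) and
#' normalizes to total mass 1.
#'
#' @param window 2-D numeric matrix of intensities.
#' @param mask 2-D 0/1 matrix (same shape); NULL means all pixels.
#' @param config a [glcm_config()].
#' @return n x n matrix, entries >= 0 summing to 1.
#' @export
compute_glcm <- function(window, mask = NULL, config = glcm_config()) {
  if (length(dim(window)) != 2L) stopf("compute_glcm expects a 2-D window")
  if (is.null(mask)) mask <- array(1L, dim(window))
  if (!identical(dim(window), dim(mask))) stopf("window/mask shapes differ")
  n <- config$levels
  inm <- mask == 1
  if (!any(inm)) stopf("empty mask")
  lv <- matrix(NA_integer_, nrow(window), ncol(window))
  lv[inm] <- quantize_levels(window[inm], n)
  counts <- matrix(0, n, n)
  nr <- nrow(window); nc <- ncol(window)
  for (k in seq_len(nrow(config$offsets))) {
    dy <- config$offsets[k, 1]; dx <- config$offsets[k, 2]
    y1 <- max(1, 1 - dy):min(nr, nr - dy)
    x1 <- max(1, 1 - dx):min(nc, nc - dx)
    a <- lv[y1, x1, drop = FALSE]
    b <- lv[y1 + dy, x1 + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tt <- table(factor(a[ok], levels = 0:(n - 1)),
                factor(b[ok], levels = 0:(n - 1)))
    counts <- counts + tt
  }
  if (config$symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0) stopf("no valid in-mask pixel pairs for any offset")
  counts / tot
}

#' GLCM contrast
#'
#' `sum_{x,y} P(x,y) (x - y)^2`: large when co-occurring levels differ.
#' @param glcm normalized co-occurrence matrix.
#' @return scalar >= 0.
#' @export
glcm_contrast <- function(glcm) {
  n <- nrow(glcm)
  idx <- 0:(n - 1)
  sum(glcm * outer(idx, idx, function(x, y) (x - y)^2))
}

#' GLCM correlation
#'
#' `sum P(x,y) (x - mu_x)(y - mu_y) / (sigma_x sigma_y)`, in [-1, 1].
#' Degenerate marginals (zero variance) are an error.
#' @inheritParams glcm_contrast
#' @export
glcm_correlation <- function(glcm) {
  n <- nrow(glcm)
  idx <- 0:(n - 1)
  px <- rowSums(glcm); py <- colSums(glcm)
  mx <- sum(idx * px); my <- sum(idx * py)
  vx <- sum((idx - mx)^2 * px); vy <- sum((idx - my)^2 * py)
  if (vx <= 0 || vy <= 0) stopf("GLCM correlation undefined: a marginal has zero variance")
  sum(glcm * outer(idx - mx, idx - my)) / sqrt(vx * vy)
}

#' GLCM homogeneity (inverse difference)
#'
#' `sum P(x,y) / (1 + |x - y|)`, in (0, 1]; 1 iff all mass is diagonal.
#' @inheritParams glcm_contrast
#' @export
glcm_homogeneity <- function(glcm) {
  n <- nrow(glcm)
  idx <- 0:(n - 1)
  sum(glcm / (1 + abs(outer(idx, idx, `-`))))
}

#' GLCM entropy
#'
#' `-sum P log P` over nonzero entries (natural log), >= 0.
#' @inheritParams glcm_contrast
#' @export
glcm_entropy <- function(glcm) {
  p <- glcm[glcm > 0]
  -sum(p * log(p))
}

## ---- Shape features ---------------------------------------------------

# Largest-area axial slice of a 3-D mask (2-D masks pass through).
largest_axial_slice <- function(mask) {
  v <- mask$voxels
  if (length(dim(v)) == 2L) {
    return(list(slice = v, spacing = mask$spacing_mm))
  }
  areas <- apply(v, 1L, sum)
  z <- which.max(areas)
  list(slice = v[z, , ], spacing = mask$spacing_mm[2:3])
}

#' Shape features of a segmented nodule
#'
#' Computed on the largest axial slice (3-D masks) from the largest
#' connected component (8-connectivity):
#' \itemize{
#'   \item area: pixel count x pixel area (mm^2);
#'   \item aspect_rate: major / minor axis length of the best-fit ellipse
#'     (from second central moments of the component's pixel centers), >= 1;
#'   \item perimeter: closed polygon length through the ordered boundary
#'     pixel centers (mm);
#'   \item roundness: isoperimetric ratio 4 pi A / L^2 with L the perimeter;
#'   \item circularity: 4 pi A / D^2 with D also the boundary length, so it
#'     equals roundness under this boundary estimator (both are reported).
#' }
#'
#' @param mask a [segmentation_mask()] (nonempty).
#' @return named list: `area_mm2`, `aspect_rate`, `roundness`,
#'   `perimeter_mm`, `circularity`.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (sum(mask$voxels) == 0) stopf("shape features undefined for an empty mask")
  ax <- largest_axial_slice(mask)
  sl <- ax$slice; sp <- ax$spacing
  lab <- EBImage::bwlabel(sl)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  comp <- (lab == main) * 1
  npx <- sum(comp)
  area <- npx * prod(sp)
  # best-fit ellipse axes from the eigenvalues of the coordinate covariance
  idx <- which(comp == 1, arr.ind = TRUE)
  xy <- sweep(idx, 2L, colMeans(idx))
  xy <- sweep(xy, 2L, sp, `*`)
  if (npx > 1) {
    ev <- eigen(crossprod(xy) / npx, symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    aspect <- if (ev[2] > 0) sqrt(ev[1] / ev[2]) else Inf
  } else aspect <- 1
  # ordered outer boundary (EBImage ocontour, 0-based (x, y) pairs)
  oc <- EBImage::ocontour(comp)[[1]]
  if (nrow(oc) >= 2) {
    d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
    # ocontour coordinates are (row, col) of the matrix = (y, x)
    steps <- sweep(d, 2L, sp, `*`)
    perim <- sum(sqrt(rowSums(steps^2)))
  } else perim <- 0
  roundness <- if (perim > 0) 4 * pi * area / perim^2 else NA_real_
  list(area_mm2 = area, aspect_rate = max(aspect, 1),
       roundness = roundness, perimeter_mm = perim,
       circularity = roundness)
}

## ---- Histogram (first-order texture) features -------------------------

#' Histogram features of a nodule ROI
#'
#' In-mask intensities are binned into `levels` equal-width bins over the
#' ROI's min-max range; `P_i` is the bin center (raw intensity units) and
#' `HS(P_i)` the normalized histogram. Reported:
#' uniformity = sum HS^2; mean = sum P_i HS; standard_variance =
#' sum (P_i - mean)^2 HS; kurtosis and skewness are the *raw* fourth and
#' third central moments (no sigma normalization); smoothness =
#' 1 - 1/(1 + sigma_01^2) with sigma_01 the standard deviation on the
#' min-max-normalized [0,1] intensity scale.
#'
#' @param window numeric array of intensities.
#' @param mask 0/1 array, same shape (NULL = all).
#' @param levels histogram bin count (default 256).
#' @return named list of the six features.
#' @export
histogram_features <- function(window, mask = NULL, levels = 256L) {
  if (is.null(mask)) mask <- array(1L, dim(window) %||% length(window))
  vals <- window[mask == 1]
  if (length(vals) < 2) stopf("histogram features need >= 2 in-mask voxels")
  rng <- range(vals)
  if (diff(rng) == 0) {
    return(list(uniformity = 1, mean = rng[1], standard_variance = 0,
                kurtosis = 0, skewness = 0, smoothness = 0))
  }
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  ct <- tabulate(pmin(findInterval(vals, br, rightmost.closed = TRUE), levels),
                 nbins = levels)
  hs <- ct / sum(ct)
  centers <- (br[-1] + br[-length(br)]) / 2
  mu <- sum(centers * hs)
  v2 <- sum((centers - mu)^2 * hs)
  v3 <- sum((centers - mu)^3 * hs)
  v4 <- sum((centers - mu)^4 * hs)
  sigma01sq <- v2 / diff(rng)^2
  list(uniformity = sum(hs^2), mean = mu, standard_variance = v2,
       kurtosis = v4, skewness = v3,
       smoothness = 1 - 1 / (1 + sigma01sq))
}

## ---- Combined feature vector ------------------------------------------

#' Column order of the exported feature table
#' @export
feature_names <- function() {
  c("correlation", "contrast", "homogeneity", "entropy",
    "area_mm2", "aspect_rate", "roundness", "perimeter_mm", "circularity",
    "uniformity", "mean", "standard_variance", "kurtosis", "skewness",
    "smoothness")
}

#' Extract the 15-element radiomic feature vector of a nodule
#'
#' Texture (GLCM) and histogram features are computed from the image
#' intensities inside the mask's bounding window (GLCM on the largest
#' axial slice for 3-D input); shape features from the mask alone, so they
#' are invariant to intensity changes. Fixed column order given by
#' [feature_names()].
#'
#' @param image an [image_volume()].
#' @param mask the paired [segmentation_mask()].
#' @param config a [glcm_config()].
#' @param hist_levels histogram bin count for [histogram_features()].
#' @return one-row data.frame with the 15 features.
#' @export
extract_features <- function(image, mask, config = glcm_config(),
                             hist_levels = 256L) {
  check_pair(image, mask)
  if (sum(mask$voxels) == 0) stopf("cannot extract features from an empty mask")
  v <- image$voxels; m <- mask$voxels
  if (length(dim(v)) == 3L) {
    z <- which.max(apply(m, 1L, sum))
    v2 <- v[z, , ]; m2 <- m[z, , ]
  } else {
    v2 <- v; m2 <- m
  }
  # bounding window with 1-pixel margin for co-occurrence context
  idx <- which(m2 == 1, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  rr <- c(max(1, rr[1] - 1L), min(nrow(m2), rr[2] + 1L))
  cc <- c(max(1, cc[1] - 1L), min(ncol(m2), cc[2] + 1L))
  win <- v2[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mwin <- m2[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  g <- compute_glcm(win, mwin, config)
  corr <- tryCatch(glcm_correlation(g), error = function(e) NA_real_)
  shp <- shape_features(mask)
  hst <- histogram_features(v, m, hist_levels)
  out <- data.frame(correlation = corr, contrast = glcm_contrast(g),
                    homogeneity = glcm_homogeneity(g), entropy = glcm_entropy(g),
                    area_mm2 = shp$area_mm2, aspect_rate = shp$aspect_rate,
                    roundness = shp$roundness, perimeter_mm = shp$perimeter_mm,
                    circularity = shp$circularity,
                    uniformity = hst$uniformity, mean = hst$mean,
                    standard_variance = hst$standard_variance,
                    kurtosis = hst$kurtosis, skewness = hst$skewness,
                    smoothness = hst$smoothness)
  out[, feature_names()]
}
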