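#' Denoising parameters
#'
#' Controls the Bayesian-threshold wavelet denoiser. The defaults reduce
#' the threshold rule to classical BayesShrink: each detail sub-band is
#' soft-thresholded at T = sigma_noise^2 / sigma_signal, where sigma_noise
#' comes from the median-absolute-deviation estimate on the finest
#' diagonal band and sigma_signal from the band's empirical second moment.
#' Two opt-in extensions are exposed: a polynomial gain gamma(delta)
#' multiplying every threshold (see [gamma_factor()]) and a universal
#' sqrt(2 log N^2) factor with N the per-axis size.
#'
#' @param wavelet_name orthogonal wavelet (default "db2").
#' @param levels decomposition levels (>= 1).
#' @param threshold_mode "soft" or "hard".
#' @param gamma_coeffs numeric length 4 `(rho1, rho2, rho3, rho)` for the
#'   cubic gain `gamma = rho1 d^3 + rho2 d^2 + rho3 d + rho`; the default
#'   `(0,0,0,1)` fixes gamma = 1.
#' @param use_universal_factor multiply thresholds by sqrt(2 log N^2)?
#' @return object of class `denoise_params`.
#' @export
denoise_params <- function(wavelet_name = "db2", levels = 1L,
                           threshold_mode = c("soft", "hard"),
                           gamma_coeffs = c(0, 0, 0, 1),
                           use_universal_factor = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  wavelet_filters(wavelet_name)  # validates the name
  if (!is_count(levels)) stopf("levels must be an integer >= 1")
  if (length(gamma_coeffs) != 4) stopf("gamma_coeffs must have length 4")
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels),
                 threshold_mode = threshold_mode,
                 gamma_coeffs = as.numeric(gamma_coeffs),
                 use_universal_factor = isTRUE(use_universal_factor)),
            class = "denoise_params")
}

#' Z-score normalization
#'
#' Rescales an image volume to zero mean and unit standard deviation, the
#' pre-processing applied before denoising and before network patches are
#' formed. Constant images have no meaningful Z-score and are rejected.
#'
#' @param volume an [image_volume()].
#' @return an [image_volume()] with mean 0 and sd 1 (population sd).
#' @export
zscore_normalize <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  if (length(v) < 2) stopf("z-score normalization needs > 1 voxel")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stopf("z-score normalization undefined for a constant image")
  image_volume((v - mu) / sdv, volume$spacing_mm, volume$source_id)
}

#' Global noise level from the finest diagonal sub-band
#'
#' The robust median-absolute-deviation estimator: sigma_N =
#' median(|c|) / 0.6745 over the coefficients of the highest-frequency
#' band (HHH in 3-D, HH in 2-D) of the first decomposition level.
#'
#' @param subbands a `subband_set` from [decompose()].
#' @return nonnegative scalar sigma_N.
#' @export
estimate_noise_sigma <- function(subbands) {
  stopifnot(inherits(subbands, "subband_set"))
  nd <- length(subbands$input_dim)
  hh <- subbands$levels[[1L]][[strrep("H", nd)]]
  if (!length(hh)) stopf("highest-frequency band is empty")
  stats::median(abs(as.vector(hh))) / 0.6745
}

#' Sub-band signal scale
#'
#' sigma_sn = sqrt(max(sigma_b^2 - sigma_N^2, 0)), where sigma_b^2 is the
#' band's empirical second moment. A band whose energy does not exceed the
#' noise floor gets sigma_sn = 0 (and is zeroed entirely by the threshold
#' rule).
#'
#' @param band coefficient array.
#' @param sigma_n global noise sigma from [estimate_noise_sigma()].
#' @return nonnegative scalar sigma_sn.
#' @export
estimate_subband_sigma <- function(band, sigma_n) {
  if (sigma_n < 0) stopf("sigma_n must be >= 0")
  sb2 <- mean(as.vector(band)^2)
  sqrt(max(sb2 - sigma_n^2, 0))
}

#' Bayesian sub-band threshold
#'
#' T = sigma_N^2 / sigma_sn. When the sub-band signal scale is zero but
#' noise is present the threshold is +Inf (the band is pure noise and is
#' zeroed); when both are zero the threshold is 0.
#'
#' @param sigma_n global noise sigma.
#' @param sigma_sn sub-band signal sigma.
#' @return threshold value (possibly Inf).
#' @export
bayes_threshold <- function(sigma_n, sigma_sn) {
  if (sigma_n < 0 || sigma_sn < 0) stopf("sigmas must be >= 0")
  if (sigma_sn > 0) return(sigma_n^2 / sigma_sn)
  if (sigma_n > 0) return(Inf)
  0
}

#' Polynomial threshold gain
#'
#' gamma = rho1 delta^3 + rho2 delta^2 + rho3 delta + rho, a curve-fit gain
#' in the noise level delta applied multiplicatively to every sub-band
#' threshold. The default coefficients (0,0,0,1) give gamma = 1, i.e. pure
#' BayesShrink. A non-positive gamma would invert the threshold's meaning
#' and is rejected.
#'
#' @param delta noise standard deviation.
#' @param coeffs numeric length 4 `(rho1, rho2, rho3, rho)`.
#' @return positive scalar gamma.
#' @export
gamma_factor <- function(delta, coeffs = c(0, 0, 0, 1)) {
  if (length(coeffs) != 4 || any(!is.finite(coeffs))) {
    stopf("coeffs must be 4 finite numbers")
  }
  g <- coeffs[1] * delta^3 + coeffs[2] * delta^2 + coeffs[3] * delta + coeffs[4]
  if (!is.finite(g) || g <= 0) stopf("gamma factor must be positive, got %g", g)
  g
}

#' Soft / hard coefficient thresholding
#'
#' Soft: sign(c) * max(|c| - T, 0). Hard: c * 1[|c| > T].
#'
#' @param band coefficient array.
#' @param threshold nonnegative threshold (Inf zeroes the band).
#' @param mode "soft" or "hard".
#' @return thresholded array, same shape.
#' @export
apply_threshold <- function(band, threshold, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (threshold < 0) stopf("threshold must be >= 0")
  if (mode == "soft") {
    out <- sign(band) * pmax(abs(band) - threshold, 0)
  } else {
    out <- band * (abs(band) > threshold)
  }
  if (is.infinite(threshold)) out[] <- 0  # Inf - Inf guards
  if (!is.null(dim(band))) dim(out) <- dim(band)
  out
}

#' Bayesian-threshold wavelet denoising
#'
#' Decomposes the volume, thresholds every detail sub-band at
#' T_band = T_Bay * gamma (optionally * sqrt(2 log N^2)), leaves the pure
#' approximation band untouched, and inverse-transforms. Shape and spacing
#' are always preserved.
#'
#' @param volume an [image_volume()].
#' @param params a [denoise_params()].
#' @param verbose print per-band sigma_b, sigma_sn and threshold?
#' @return list with `volume` (denoised [image_volume()]) and `log`
#'   (data.frame of per-band statistics: level, band, sigma_b, sigma_sn,
#'   threshold).
#' @export
denoise_volume <- function(volume, params = denoise_params(), verbose = FALSE) {
  stopifnot(inherits(volume, "image_volume"))
  sb <- decompose(volume, params)
  nd <- length(sb$input_dim)
  sigma_n <- estimate_noise_sigma(sb)
  gam <- gamma_factor(sigma_n, params$gamma_coeffs)
  ufac <- if (params$use_universal_factor) {
    n_ax <- max(sb$input_dim)
    sqrt(2 * log(n_ax^2))
  } else 1
  approx_name <- strrep("L", nd)
  logs <- list()
  for (lev in seq_along(sb$levels)) {
    for (bn in names(sb$levels[[lev]])) {
      if (bn == approx_name) next
      band <- sb$levels[[lev]][[bn]]
      s_sn <- estimate_subband_sigma(band, sigma_n)
      thr <- bayes_threshold(sigma_n, s_sn) * gam * ufac
      sb$levels[[lev]][[bn]] <- apply_threshold(band, thr, params$threshold_mode)
      logs[[length(logs) + 1L]] <- data.frame(
        level = lev, band = bn, sigma_b = sqrt(mean(band^2)),
        sigma_sn = s_sn, threshold = thr)
    }
  }
  log_df <- do.call(rbind, logs)
  if (verbose) {
    message(sprintf("sigma_N = %.6g (MAD on %s)", sigma_n, strrep("H", nd)))
    for (i in seq_len(nrow(log_df))) {
      message(sprintf("  L%d %s: sigma_b=%.4g sigma_sn=%.4g T=%.4g",
                      log_df$level[i], log_df$band[i], log_df$sigma_b[i],
                      log_df$sigma_sn[i], log_df$threshold[i]))
    }
  }
  out <- reconstruct(sb)
  out$source_id <- volume$source_id
  list(volume = out, sigma_n = sigma_n, log = log_df)
}
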