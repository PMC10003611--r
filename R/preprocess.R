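# Grayscale preprocessing chain: FFT bandpass, unsharp mask, despeckle.
# Applied, in that order, before thresholding. Each step returns an 8-bit
# image (values rounded and clipped to 0..255), matching a pipeline whose
# every intermediate is an 8-bit raster.

#' Preprocessing parameters
#'
#' Defaults follow the reference workflow's documented bandpass structure
#' sizes (larger than 40 px suppressed, smaller than 3 px suppressed,
#' autoscale on) and its unsharp-mask defaults (Gaussian sigma 1 px,
#' weight 0.6). The default saturation is 0 (pure min/max rescale): for
#' sparsely stained fields, clipping a fixed pixel percentage at the dark
#' tail collapses the stained class into the zero bin and destabilizes
#' maximum-entropy thresholding; dense fields are insensitive to the
#' choice. Saturation remains available for images with extreme-value
#' outliers.
#'
#' @param bandpass_large_px structures larger than this (px) are suppressed.
#' @param bandpass_small_px structures smaller than this (px) are suppressed.
#' @param bandpass_saturate_pct percentage of pixels clipped (both tails
#'   together) when autoscaling the filtered result.
#' @param bandpass_autoscale rescale the filtered image to 0..255.
#' @param unsharp_radius_px Gaussian sigma of the unsharp mask, px.
#' @param unsharp_weight mask weight in (0, 1).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(bandpass_large_px = 40,
                              bandpass_small_px = 3,
                              bandpass_saturate_pct = 0,
                              bandpass_autoscale = TRUE,
                              unsharp_radius_px = 1.0,
                              unsharp_weight = 0.6) {
  if (!(bandpass_large_px > bandpass_small_px && bandpass_small_px >= 0))
    stop_input("requires bandpass_large_px > bandpass_small_px >= 0")
  if (!(unsharp_weight > 0 && unsharp_weight < 1))
    stop_input("unsharp_weight must lie strictly in (0, 1)")
  if (bandpass_saturate_pct < 0 || bandpass_saturate_pct >= 100)
    stop_input("bandpass_saturate_pct must lie in [0, 100)")
  structure(list(bandpass_large_px = bandpass_large_px,
                 bandpass_small_px = bandpass_small_px,
                 bandpass_saturate_pct = bandpass_saturate_pct,
                 bandpass_autoscale = isTRUE(bandpass_autoscale),
                 unsharp_radius_px = unsharp_radius_px,
                 unsharp_weight = unsharp_weight),
            class = "preprocess_params")
}

# Gaussian low-pass transfer values for structure size d on an N x N grid,
# evaluated at integer frequency radius r (cycles per padded image):
#   LP_d(r) = exp(-(r d / N)^2)
# i.e. attenuation to 1/e at the frequency whose period equals d pixels.
# The band filter is the difference of two such low-passes. This explicit
# form is the documented contract; tests rebuild it independently.
bandpass_transfer <- function(r, small_px, large_px, n) {
  lp <- function(d) if (d <= 0) 1 else exp(-(r * d / n)^2)
  lp(small_px) - lp(large_px)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

pad_replicate <- function(m, n) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(seq_len(h), rep(h, n - h))
  ci <- c(seq_len(w), rep(w, n - w))
  m[ri, ci, drop = FALSE]
}

#' FFT bandpass filter
#'
#' Suppresses image structure outside a spatial-scale band: features smaller
#' than `bandpass_small_px` (noise) and larger than `bandpass_large_px`
#' (slow background variation, including the DC level) are attenuated,
#' leaving cells and branches. The image is padded by edge replication to a
#' square power-of-two side before the FFT (removes wraparound artifacts)
#' and cropped afterwards. With `bandpass_autoscale`, the filtered result is
#' linearly rescaled to 0..255 with `bandpass_saturate_pct` of pixels
#' clipped, split symmetrically between both tails; without it, the input
#' mean is added back and the result clipped.
#'
#' @param image a `calibrated_image` or 8-bit grayscale matrix.
#' @param params a [preprocess_params()] object.
#' @return Same type as `image`, filtered, values in 0..255.
#' @export
fft_bandpass <- function(image, params = preprocess_params()) {
  px <- as_pixels(image)
  if (length(px) == 0) stop_input("empty image")
  h <- nrow(px); w <- ncol(px)
  n <- next_pow2(max(h, w))
  padded <- pad_replicate(px, n)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f)  # cycles per image along each axis
  r <- sqrt(outer(f^2, f^2, "+"))
  tr <- bandpass_transfer(r, params$bandpass_small_px,
                          params$bandpass_large_px, n)
  filt <- Re(stats::fft(stats::fft(padded) * tr, inverse = TRUE)) / n^2
  filt <- filt[seq_len(h), seq_len(w), drop = FALSE]
  out <- if (params$bandpass_autoscale) {
    s <- params$bandpass_saturate_pct / 100
    q <- stats::quantile(filt, c(s / 2, 1 - s / 2), names = FALSE, type = 7)
    if (q[2] - q[1] < .Machine$double.eps^0.5) filt * 0
    else (filt - q[1]) * (255 / (q[2] - q[1]))
  } else {
    filt + mean(px)
  }
  out <- matrix(iround(out), h, w)
  out[out < 0L] <- 0L; out[out > 255L] <- 255L
  rewrap(image, out)
}

rewrap <- function(template, pixels) {
  if (inherits(template, "calibrated_image"))
    calibrated_image(pixels, template$um_per_px)
  else pixels
}

#' Unsharp mask
#'
#' Sharpens by subtracting a weighted Gaussian blur:
#' `out = (I - weight * G_sigma(I)) / (1 - weight)`, with `sigma =
#' radius_px`, then clips to 0..255. Constant regions are unchanged; edges
#' gain over/undershoot, which makes thin processes survive thresholding.
#'
#' @param image a `calibrated_image` or grayscale matrix.
#' @param radius_px Gaussian sigma in pixels.
#' @param weight mask weight, strictly in (0, 1).
#' @return Same type as `image`.
#' @export
unsharp_mask <- function(image, radius_px = 1.0, weight = 0.6) {
  if (!(weight > 0 && weight < 1))
    stop_input("unsharp 'weight' must lie strictly in (0, 1)")
  if (radius_px <= 0) stop_input("unsharp 'radius_px' must be positive")
  px <- as_pixels(image)
  blur <- cpp_gaussian_blur(px + 0, radius_px)
  out <- (px - weight * blur) / (1 - weight)
  out <- matrix(iround(out), nrow(px), ncol(px))
  out[out < 0L] <- 0L; out[out > 255L] <- 255L
  rewrap(image, out)
}

#' Despeckle (3x3 median filter)
#'
#' Removes salt-and-pepper noise: every pixel is replaced by the median of
#' its 3x3 neighborhood, with edge pixels handled by replication. Applied
#' both to the grayscale image before thresholding and to the binary mask
#' after it.
#'
#' @param image a `calibrated_image`, `binary_mask` or matrix.
#' @return Same type as `image`.
#' @export
despeckle <- function(image) {
  px <- as_pixels(image)
  if (length(px) == 0) stop_input("empty image")
  out <- cpp_median3x3(px + 0)
  if (inherits(image, "binary_mask"))
    binary_mask(matrix(as.integer(out), nrow(px), ncol(px)), image$um_per_px)
  else rewrap(image, matrix(iround(out), nrow(px), ncol(px)))
}
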