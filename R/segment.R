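# Segmentation: maximum-entropy (Kapur) thresholding plus the binary
# cleanup chain (despeckle, close, remove outliers) that turns the
# preprocessed photomicrograph into a clean mask of stained structures.

#' Intensity histogram of an 8-bit image
#'
#' @param image a `calibrated_image` or matrix with values in 0..255.
#' @return Integer vector of 256 counts, index `i` counting gray level
#'   `i - 1`.
#' @export
intensity_histogram <- function(image) {
  px <- as_pixels(image)
  tabulate(as.integer(px) + 1L, nbins = 256L)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Returns the gray level `t` maximizing the sum of Shannon entropies of
#' the two classes the level induces: below = levels `0..t`, above =
#' `t+1..255`, each entropy computed on the class-normalized histogram.
#' Zero-probability bins contribute zero entropy; candidate levels are
#' restricted to those where both classes carry mass (otherwise the
#' degenerate empty/full split, whose empty class contributes zero, would
#' always win); ties are broken by the smallest `t`. This criterion
#' separates DAB-stained structures from unevenly bright background
#' better than variance-based thresholds for astrocyte counting.
#'
#' @param hist integer vector of 256 histogram counts.
#' @return Integer threshold level in 0..255.
#' @export
max_entropy_threshold <- function(hist) {
  if (length(hist) != 256 || any(hist < 0) || anyNA(hist))
    stop_input("'hist' must be 256 non-negative counts")
  if (sum(hist > 0) < 2)
    stop_input("degenerate histogram: all mass in a single bin")
  p <- hist / sum(hist)
  # cumulative class mass and cumulative plogp
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Ptot <- P[256]; Stot <- S[256]
  crit <- rep(-Inf, 256)
  for (t in 0:255) {
    p1 <- P[t + 1]; p2 <- Ptot - p1
    if (p1 <= 0 || p2 <= 0) next  # both classes must carry mass
    h1 <- log(p1) - S[t + 1] / p1
    h2 <- log(p2) - (Stot - S[t + 1]) / p2
    crit[t + 1] <- h1 + h2
  }
  which.max(crit) - 1L  # which.max takes the first maximum: smallest t
}

#' Apply a threshold to produce a binary mask
#'
#' With `dark_foreground = TRUE` (the default; DAB staining is dark on a
#' bright background) pixels at or below the threshold become foreground 1.
#' The mask convention is always foreground = stained structures = 1,
#' regardless of any display-time black/white background option.
#'
#' @param image a `calibrated_image` or matrix.
#' @param t threshold level from [max_entropy_threshold()].
#' @param dark_foreground logical; if `FALSE`, pixels above `t` become
#'   foreground instead.
#' @return A [binary_mask()].
#' @export
apply_threshold <- function(image, t, dark_foreground = TRUE) {
  px <- as_pixels(image)
  fg <- if (dark_foreground) px <= t else px > t
  binary_mask(matrix(as.integer(fg), nrow(px), ncol(px)),
              um_per_px_of(image))
}

#' Mask cleanup parameters
#'
#' Defaults are the workflow's printed values: outlier removal with pixel
#' radius 2 and threshold 50 (bright polarity, i.e. removing white specks
#' from the displayed 0/255 mask), and one round of binary closing.
#'
#' @param outlier_radius_px disk radius for the median, px.
#' @param outlier_threshold minimum deviation from the disk median for a
#'   pixel to be replaced.
#' @param outlier_polarity `"bright"` or `"dark"`.
#' @param close_iterations number of dilation (then erosion) passes.
#' @export
cleanup_params <- function(outlier_radius_px = 2,
                           outlier_threshold = 50,
                           outlier_polarity = c("bright", "dark"),
                           close_iterations = 1L) {
  outlier_polarity <- match.arg(outlier_polarity)
  if (outlier_radius_px < 1) stop_input("outlier_radius_px must be >= 1")
  if (outlier_threshold < 0) stop_input("outlier_threshold must be >= 0")
  if (close_iterations < 1) stop_input("close_iterations must be >= 1")
  structure(list(outlier_radius_px = outlier_radius_px,
                 outlier_threshold = outlier_threshold,
                 outlier_polarity = outlier_polarity,
                 close_iterations = as.integer(close_iterations)),
            class = "cleanup_params")
}

#' Binary closing
#'
#' Morphological closing with a 3x3 square structuring element:
#' `iterations` dilations followed by `iterations` erosions (closing by the
#' iterated element). Connects foreground runs separated by a two-pixel
#' background gap, uniformizing open particles. Out-of-image pixels count
#' as background for dilation and foreground for erosion, so closing is
#' extensive (input is a subset of output) and idempotent, borders
#' included.
#'
#' @param mask a [binary_mask()] (or 0/1 matrix).
#' @param iterations positive integer.
#' @return Same type as `mask`.
#' @export
binary_close <- function(mask, iterations = 1L) {
  if (iterations < 1) stop_input("'iterations' must be >= 1")
  px <- as_pixels(mask)
  m <- matrix(as.integer(px != 0), nrow(px), ncol(px))
  for (k in seq_len(iterations)) m <- cpp_dilate3x3(m)
  for (k in seq_len(iterations)) m <- cpp_erode3x3(m)
  if (inherits(mask, "binary_mask")) binary_mask(m, mask$um_per_px) else m
}

#' Remove outlier pixels by a disk median
#'
#' For every pixel, the median over the disk of radius `outlier_radius_px`
#' (pixels whose centre distance is at most the radius, centre included) is
#' computed; a pixel deviating from that median by more than
#' `outlier_threshold` in the configured direction is replaced by the
#' median. With bright polarity this deletes isolated white specks left by
#' mask conversion. Binary masks are processed on their 0/255 display
#' representation so the printed threshold of 50 applies unchanged.
#'
#' @param image a `calibrated_image`, [binary_mask()] or numeric matrix.
#' @param params a [cleanup_params()] object.
#' @return Same type as `image`.
#' @export
remove_outliers <- function(image, params = cleanup_params()) {
  pol <- if (params$outlier_polarity == "bright") 1L else -1L
  if (inherits(image, "binary_mask")) {
    disp <- image$pixels * 255
    out <- cpp_remove_outliers(disp + 0, params$outlier_radius_px,
                               params$outlier_threshold, pol)
    binary_mask(matrix(as.integer(out >= 128), nrow(out), ncol(out)),
                image$um_per_px)
  } else {
    px <- as_pixels(image)
    out <- cpp_remove_outliers(px + 0, params$outlier_radius_px,
                               params$outlier_threshold, pol)
    rewrap(image, matrix(iround(out), nrow(out), ncol(out)))
  }
}

#' Segment a preprocessed image into a clean binary mask
#'
#' Fixed order: maximum-entropy threshold, despeckle, close, remove
#' outliers. The order is part of the contract (each step repairs the
#' artifacts the previous one can leave).
#'
#' @param image a preprocessed `calibrated_image`.
#' @param params a [cleanup_params()] object.
#' @param dark_foreground passed to [apply_threshold()].
#' @return List with elements `mask` (the cleaned [binary_mask()]),
#'   `threshold` (the level used) and `raw_mask` (before cleanup).
#' @export
segment_image <- function(image, params = cleanup_params(),
                          dark_foreground = TRUE) {
  t <- max_entropy_threshold(intensity_histogram(image))
  raw <- apply_threshold(image, t, dark_foreground)
  m <- despeckle(raw)
  m <- binary_close(m, params$close_iterations)
  m <- remove_outliers(m, params)
  list(mask = m, threshold = t, raw_mask = raw)
}
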