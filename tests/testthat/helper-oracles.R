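# Independent brute-force oracles. These deliberately share no code with
# the package: naive loops and explicit DFT matrices only.

# Kapur criterion by direct evaluation of both class entropies at every
# candidate level; ties broken by the smallest level.
oracle_max_entropy <- function(hist) {
  p <- hist / sum(hist)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:255) {
    lo <- p[seq_len(t + 1)]
    hi <- if (t < 255) p[(t + 2):256] else numeric(0)
    if (sum(lo) <= 0 || sum(hi) <= 0) next  # both classes must carry mass
    ent <- function(q) {
      q <- q[q > 0] / sum(q)
      -sum(q * log(q))
    }
    val <- ent(lo) + ent(hi)
    if (val > best) {
      best <- val
      best_t <- t
    }
  }
  best_t
}

# 3x3 median with edge replication, double loop
oracle_median3x3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (i in 1:h) for (j in 1:w) {
    ii <- pmin(pmax(i + (-1:1), 1), h)
    jj <- pmin(pmax(j + (-1:1), 1), w)
    out[i, j] <- median(as.vector(img[ii, jj]))
  }
  out
}

# disk-median outlier replacement, double loop; median of an even count is
# the mean of the two central order statistics (package convention)
oracle_remove_outliers <- function(img, radius, threshold, bright = TRUE) {
  h <- nrow(img); w <- ncol(img)
  offs <- expand.grid(di = -floor(radius):floor(radius),
                      dj = -floor(radius):floor(radius))
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- img
  for (i in 1:h) for (j in 1:w) {
    ii <- pmin(pmax(i + offs$di, 1), h)
    jj <- pmin(pmax(j + offs$dj, 1), w)
    v <- sort(img[cbind(ii, jj)])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    dev <- if (bright) img[i, j] - med else med - img[i, j]
    if (dev > threshold) out[i, j] <- med
  }
  out
}

# frequency-domain bandpass via explicit DFT matrices (no stats::fft),
# same padding and transfer function as documented by the package
oracle_bandpass_raw <- function(px, small_px, large_px) {
  h <- nrow(px); w <- ncol(px)
  n <- 2^ceiling(log2(max(h, w)))
  ri <- c(seq_len(h), rep(h, n - h)); ci <- c(seq_len(w), rep(w, n - w))
  padded <- px[ri, ci, drop = FALSE]
  om <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  F2 <- om %*% padded %*% om            # 2D DFT
  f <- pmin(0:(n - 1), n - (0:(n - 1)))
  r <- sqrt(outer(f^2, f^2, "+"))
  lp <- function(d) if (d <= 0) matrix(1, n, n) else exp(-(r * d / n)^2)
  tr <- lp(small_px) - lp(large_px)
  omi <- Conj(om)
  back <- Re(omi %*% (F2 * tr) %*% omi) / n^2
  back[seq_len(h), seq_len(w), drop = FALSE]
}

# Gaussian blur by direct convolution with replicated edges
oracle_gaussian_blur <- function(img, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  out <- img
  tmp <- img
  for (i in 1:h) for (j in 1:w)
    tmp[i, j] <- sum(k * img[pmin(pmax(i + (-r:r), 1), h), j])
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- sum(k * tmp[i, pmin(pmax(j + (-r:r), 1), w)])
  out
}

# spreadsheet semantics: duplicate filter on Skeleton ID, then COUNTIF /
# SUMIF per remaining id, via a plain scan
oracle_spreadsheet <- function(ids, lens) {
  counts <- table(ids)
  keep <- names(counts)[counts > 1]
  keep_rows <- ids %in% as.integer(keep)
  ids2 <- ids[keep_rows]; lens2 <- lens[keep_rows]
  uids <- sort(unique(ids2))
  data.frame(
    skeleton_id = uids,
    branch_count = vapply(uids, function(u) sum(ids2 == u), 0L),
    total_branch_length_um = vapply(uids, function(u) sum(lens2[ids2 == u]), 0))
}
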