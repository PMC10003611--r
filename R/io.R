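# Image input/output and spatial calibration.
#
# No binary-image package is assumed: PNG (zlib streams via memCompress /
# memDecompress), uncompressed baseline TIFF and PNM are decoded natively.
# JPEG, being a lossy DCT codec far outside this package's scope, is decoded
# by delegating to a python interpreter with imageio/Pillow when one is on
# the PATH (photomicrographs are commonly exported as JPG).

iround <- function(x) as.integer(floor(x + 0.5))

# ---- domain types -------------------------------------------------------

#' Calibrated 8-bit grayscale image
#'
#' Bundles a 2D intensity raster (values in 0..255, rows = image rows) with
#' its spatial calibration in micrometers per pixel. Calibration is a stored
#' scalar, never a resampling: lengths are measured in pixels and multiplied
#' by `um_per_px`, areas by `um_per_px^2`.
#'
#' @param pixels numeric/integer matrix with values in `[0, 255]`.
#' @param um_per_px positive scalar, micrometers per pixel.
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `um_per_px`, `width_px`, `height_px`.
#' @export
calibrated_image <- function(pixels, um_per_px = 1) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop_input("'pixels' must be a non-empty matrix")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stop_input("'um_per_px' must be a positive scalar")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_input("pixel intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, um_per_px = as.numeric(um_per_px),
         width_px = ncol(pixels), height_px = nrow(pixels)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, range [%g, %g]\n",
              x$width_px, x$height_px, x$um_per_px,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask of stained structures
#'
#' Foreground (value 1) marks putative GFAP-stained structures; background
#' is 0. Carries the source image's calibration.
#'
#' @param pixels matrix of 0/1 values.
#' @param um_per_px positive scalar, micrometers per pixel.
#' @export
binary_mask <- function(pixels, um_per_px = 1) {
  if (!is.matrix(pixels)) stop_input("'pixels' must be a matrix")
  if (!all(pixels == 0L | pixels == 1L))
    stop_input("mask must be strictly binary (0/1)")
  if (um_per_px <= 0) stop_input("'um_per_px' must be positive")
  m <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  structure(list(pixels = m, um_per_px = as.numeric(um_per_px)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<%s> %d x %d px, %.4g um/px, %d foreground px\n",
              class(x)[1], ncol(x$pixels), nrow(x$pixels), x$um_per_px,
              sum(x$pixels)))
  invisible(x)
}

# accept calibrated_image / binary_mask / plain matrix
as_pixels <- function(x) {
  if (inherits(x, "calibrated_image") || inherits(x, "binary_mask"))
    x$pixels
  else if (is.matrix(x)) x
  else stop_input("expected an image object or a matrix")
}

um_per_px_of <- function(x, default = 1) {
  if (inherits(x, "calibrated_image") || inherits(x, "binary_mask"))
    x$um_per_px
  else default
}

# ---- low-level binary helpers ------------------------------------------

rd_uint <- function(bytes, size, endian = "big", n = 1) {
  # sizes 1-2 read unsigned; size 4 must be signed in R (values < 2^31)
  readBin(bytes, "integer", n = n, size = size, signed = size >= 4,
          endian = endian)
}

# CRC-32 (PNG chunk checksums), table-driven
crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[idx + 1])
  }
  bitwXor(crc, -1L)
}

u32_bytes <- function(x) {
  # x is a 32-bit pattern stored in an R integer
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
}

# ---- PNM (PGM/PPM) ------------------------------------------------------

read_pnm <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  n <- length(bytes)
  pos <- 1
  next_token <- function() {
    while (pos <= n) {
      ch <- rawToChar(bytes[pos])
      if (ch == "#") { while (pos <= n && rawToChar(bytes[pos]) != "\n") pos <<- pos + 1 }
      else if (grepl("[ \t\r\n]", ch)) pos <<- pos + 1
      else break
    }
    start <- pos
    while (pos <= n && !grepl("[ \t\r\n#]", rawToChar(bytes[pos]))) pos <<- pos + 1
    if (start > n) stop_input("truncated PNM file: ", path)
    rawToChar(bytes[start:(pos - 1)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_input("unsupported PNM magic '", magic, "' in ", path)
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || w <= 0 || h <= 0)
    stop_input("invalid or zero-size PNM image: ", path)
  ch <- if (magic %in% c("P3", "P6")) 3L else 1L
  nval <- w * h * ch
  if (magic %in% c("P2", "P3")) {
    vals <- integer(nval)
    for (i in seq_len(nval)) vals[i] <- as.integer(next_token())
  } else {
    pos <- pos + 1  # single whitespace after maxval
    bytes_per <- if (maxval > 255) 2L else 1L
    need <- nval * bytes_per
    if (n - pos + 1 < need) stop_input("truncated PNM file: ", path)
    dat <- bytes[pos:(pos + need - 1)]
    vals <- if (bytes_per == 2L) {
      v <- as.integer(dat)
      v[seq(1, need, 2)] * 256L + v[seq(2, need, 2)]
    } else as.integer(dat)
  }
  samples_to_raster(vals, w, h, ch, maxval)
}

# row-major interleaved samples -> matrix or h x w x ch array
samples_to_raster <- function(vals, w, h, ch, maxval) {
  out <- if (ch == 1L) {
    t(matrix(vals, nrow = w, ncol = h))
  } else {
    a <- array(vals, dim = c(ch, w, h))
    aperm(a, c(3, 2, 1))
  }
  attr(out, "maxval") <- as.integer(maxval)
  out
}

write_pnm <- function(raster, path) {
  raster <- as_pixels_or_array(raster)
  maxval <- 255L
  if (length(dim(raster)) == 3) {
    h <- dim(raster)[1]; w <- dim(raster)[2]
    hdr <- sprintf("P6\n%d %d\n%d\n", w, h, maxval)
    dat <- as.raw(as.vector(aperm(raster, c(3, 2, 1))))
  } else {
    h <- nrow(raster); w <- ncol(raster)
    hdr <- sprintf("P5\n%d %d\n%d\n", w, h, maxval)
    dat <- as.raw(as.vector(t(raster)))
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(dat, con)
  invisible(path)
}

as_pixels_or_array <- function(x) {
  if (inherits(x, "calibrated_image")) x$pixels
  else if (inherits(x, "binary_mask")) x$pixels * 255L
  else x
}

# ---- PNG ----------------------------------------------------------------

png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

read_png <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8 || !identical(bytes[1:8], png_sig))
    stop_input("not a PNG file: ", path)
  pos <- 9
  idat <- list(); ihdr <- NULL
  while (pos + 7 <= length(bytes)) {
    len <- rd_uint(bytes[pos:(pos + 3)], 4)
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    dstart <- pos + 8
    if (len > 0 && dstart + len - 1 > length(bytes))
      stop_input("truncated PNG file: ", path)
    data <- if (len > 0) bytes[dstart:(dstart + len - 1)] else raw(0)
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1]] <- data
    else if (type == "IEND") break
    pos <- dstart + len + 4
  }
  if (is.null(ihdr) || length(idat) == 0)
    stop_input("truncated PNG file: ", path)
  w <- rd_uint(ihdr[1:4], 4); h <- rd_uint(ihdr[5:8], 4)
  depth <- as.integer(ihdr[9]); ctype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (w <= 0 || h <= 0) stop_input("zero-size PNG image: ", path)
  if (interlace != 0) stop_input("interlaced PNG not supported: ", path)
  if (!depth %in% c(8L, 16L))
    stop_input("unsupported PNG bit depth ", depth, ": ", path)
  ch <- switch(as.character(ctype), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop_input("unsupported PNG color type ", ctype, ": ", path))
  bytes_per <- depth %/% 8L
  bpp <- ch * bytes_per
  stride <- w * bpp
  raw_dat <- tryCatch(memDecompress(do.call(c, idat), "gzip"),
                      error = function(e)
                        stop_input("corrupt PNG stream in ", path))
  if (length(raw_dat) != h * (stride + 1))
    stop_input("truncated PNG pixel data: ", path)
  vals <- png_unfilter(as.integer(raw_dat), h, stride, bpp)
  if (bytes_per == 2L) {
    vals <- vals[seq(1, length(vals), 2)] * 256L + vals[seq(2, length(vals), 2)]
  }
  samples_to_raster(vals, w, h, ch, if (depth == 16L) 65535L else 255L)
}

png_unfilter <- function(dat, h, stride, bpp) {
  out <- integer(h * stride)
  prev <- integer(stride)
  strides <- seq_len(stride)
  for (i in seq_len(h)) {
    off <- (i - 1) * (stride + 1)
    ft <- dat[off + 1]
    row <- dat[off + 1 + strides]
    if (ft == 0L) {
      r <- row
    } else if (ft == 2L) {
      r <- (row + prev) %% 256L
    } else if (ft == 1L) {
      r <- row
      if (stride > bpp)
        for (x in (bpp + 1):stride) r[x] <- (r[x] + r[x - bpp]) %% 256L
    } else if (ft == 3L) {
      r <- row
      for (x in strides) {
        a <- if (x > bpp) r[x - bpp] else 0L
        r[x] <- (r[x] + (a + prev[x]) %/% 2L) %% 256L
      }
    } else if (ft == 4L) {
      r <- row
      for (x in strides) {
        a <- if (x > bpp) r[x - bpp] else 0L
        b <- prev[x]
        cc <- if (x > bpp) prev[x - bpp] else 0L
        p <- a + b - cc
        pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
        pr <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        r[x] <- (r[x] + pr) %% 256L
      }
    } else stop_input("invalid PNG filter type ", ft)
    out[(i - 1) * stride + strides] <- r
    prev <- r
  }
  out
}

#' Write an 8-bit PNG
#'
#' Grayscale matrices are written as 8-bit gray PNG, `h x w x 3` arrays as
#' RGB. Binary masks are scaled to 0/255 for display.
#'
#' @param raster matrix, 3D array, `calibrated_image` or `binary_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(raster, path) {
  raster <- as_pixels_or_array(raster)
  if (length(dim(raster)) == 3) {
    h <- dim(raster)[1]; w <- dim(raster)[2]
    ctype <- 2L
    scan <- rbind(0L, matrix(as.vector(aperm(raster, c(3, 2, 1))), nrow = 3 * w))
  } else {
    h <- nrow(raster); w <- ncol(raster)
    ctype <- 0L
    scan <- rbind(0L, t(raster))
  }
  zdat <- memCompress(as.raw(as.vector(scan)), "gzip")  # zlib stream
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(png_sig, con)
  wchunk <- function(type, data) {
    writeBin(u32_bytes(length(data)), con)
    payload <- c(charToRaw(type), data)
    writeBin(payload, con)
    writeBin(u32_bytes(crc32(payload)), con)
  }
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(8L, ctype, 0L, 0L, 0L)))
  wchunk("IHDR", ihdr)
  wchunk("IDAT", zdat)
  wchunk("IEND", raw(0))
  invisible(path)
}

# ---- TIFF (uncompressed baseline) --------------------------------------

read_tiff <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8) stop_input("truncated TIFF file: ", path)
  order <- rawToChar(bytes[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big"
            else stop_input("not a TIFF file: ", path)
  if (rd_uint(bytes[3:4], 2, endian) != 42L)
    stop_input("not a TIFF file: ", path)
  ifd_off <- rd_uint(bytes[5:8], 4, endian)
  if (ifd_off + 1 > length(bytes)) stop_input("truncated TIFF file: ", path)
  nent <- rd_uint(bytes[(ifd_off + 1):(ifd_off + 2)], 2, endian)
  tags <- list()
  for (k in seq_len(nent)) {
    e <- ifd_off + 2 + (k - 1) * 12
    if (e + 12 > length(bytes)) stop_input("truncated TIFF file: ", path)
    tag <- rd_uint(bytes[(e + 1):(e + 2)], 2, endian)
    typ <- rd_uint(bytes[(e + 3):(e + 4)], 2, endian)
    cnt <- rd_uint(bytes[(e + 5):(e + 8)], 4, endian)
    sz <- switch(as.character(typ), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
    if (is.na(sz)) next
    total <- sz * cnt
    voff <- if (total <= 4) e + 8 else rd_uint(bytes[(e + 9):(e + 12)], 4, endian)
    if (voff + total > length(bytes)) stop_input("truncated TIFF file: ", path)
    vals <- rd_uint(bytes[(voff + 1):(voff + total)], sz, endian, n = cnt)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_input("TIFF missing tag ", tag, ": ", path)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  if (w <= 0 || h <= 0) stop_input("zero-size TIFF image: ", path)
  spp <- need(277, 1L)
  bits <- need(258, 8L)[1]
  if (need(259, 1L) != 1L)
    stop_input("compressed TIFF not supported: ", path)
  if (need(284, 1L) != 1L)
    stop_input("planar TIFF not supported: ", path)
  if (!bits %in% c(8L, 16L))
    stop_input("unsupported TIFF bit depth ", bits, ": ", path)
  offs <- need(273); cnts <- need(279)
  dat <- raw(0)
  for (k in seq_along(offs)) {
    if (offs[k] + cnts[k] > length(bytes))
      stop_input("truncated TIFF pixel data: ", path)
    dat <- c(dat, bytes[(offs[k] + 1):(offs[k] + cnts[k])])
  }
  nval <- w * h * spp
  bytes_per <- bits %/% 8L
  if (length(dat) < nval * bytes_per)
    stop_input("truncated TIFF pixel data: ", path)
  v <- as.integer(dat[seq_len(nval * bytes_per)])
  vals <- if (bytes_per == 2L) {
    if (endian == "big") v[seq(1, length(v), 2)] * 256L + v[seq(2, length(v), 2)]
    else v[seq(2, length(v), 2)] * 256L + v[seq(1, length(v), 2)]
  } else v
  maxval <- if (bits == 16L) 65535L else 255L
  photo <- need(262, 1L)
  if (photo == 0L) vals <- maxval - vals  # white-is-zero
  samples_to_raster(vals, w, h, spp, maxval)
}

# ---- format dispatch ----------------------------------------------------

#' Load an image file
#'
#' Reads TIFF (uncompressed baseline), PNG (non-interlaced, 8/16-bit), PNM
#' (PGM/PPM) and JPEG photomicrographs. The format is detected from the
#' file's magic bytes, not its extension. The raster is returned with its
#' original bit depth (`maxval` attribute); use [to_8bit_gray()] before
#' analysis. JPEG is decoded through a `python` interpreter with
#' imageio/Pillow if one is available on the PATH.
#'
#' @param path path to an image file.
#' @return An integer matrix (grayscale) or `h x w x channels` array with a
#'   `maxval` attribute.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop_input("cannot read image file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 4) stop_input("cannot read image file: ", path)
  magic <- readBin(path, "raw", 8)
  if (length(magic) >= 8 && identical(magic[1:8], png_sig)) return(read_png(path))
  m2 <- rawToChar(magic[1:2])
  if (m2 %in% c("II", "MM")) return(read_tiff(path))
  if (m2 %in% c("P2", "P3", "P5", "P6")) return(read_pnm(path))
  if (identical(magic[1:2], as.raw(c(0xff, 0xd8)))) return(read_jpeg_via_python(path))
  stop_input("unrecognized image format: ", path)
}

read_jpeg_via_python <- function(path) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop_input("JPEG decoding requires a python interpreter with ",
               "imageio or Pillow on the PATH; none found (file: ", path, ")")
  tmp <- tempfile(fileext = ".pnm")
  script <- paste(
    "import sys",
    "src, dst = sys.argv[1], sys.argv[2]",
    "try:",
    "    import imageio.v3 as iio",
    "    a = iio.imread(src)",
    "except Exception:",
    "    from PIL import Image",
    "    import numpy as np",
    "    a = np.asarray(Image.open(src))",
    "import numpy as np",
    "a = np.asarray(a)",
    "if a.ndim == 3 and a.shape[2] == 1: a = a[:, :, 0]",
    "hdr = ('P6' if a.ndim == 3 else 'P5')",
    "with open(dst, 'wb') as f:",
    "    f.write(('%s\\n%d %d\\n255\\n' % (hdr, a.shape[1], a.shape[0])).encode())",
    "    f.write(a.astype('uint8').tobytes())",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tmp))
    stop_input("failed to decode JPEG file: ", path)
  on.exit(unlink(tmp))
  read_pnm(tmp)
}

# ---- 8-bit conversion ---------------------------------------------------

#' Convert a raster to 8-bit grayscale
#'
#' Multichannel rasters are collapsed to one channel: RGB by the unweighted
#' mean `(R + G + B) / 3` rounded to nearest integer (the reference
#' workflow's default) or, with `weights = "luminance"`, by the 0.299 /
#' 0.587 / 0.114 luminance weights. An alpha channel is dropped. Rasters
#' deeper than 8 bits are linearly rescaled so the darkest pixel maps to 0
#' and the brightest to 255.
#'
#' @param raster matrix or array as returned by [load_image()].
#' @param weights `"mean"` (default) or `"luminance"`.
#' @return Integer matrix with values in 0..255.
#' @export
to_8bit_gray <- function(raster, weights = c("mean", "luminance")) {
  weights <- match.arg(weights)
  maxval <- attr(raster, "maxval")
  if (is.null(maxval)) maxval <- if (max(raster) > 255) 65535L else 255L
  d <- dim(raster)
  if (length(d) == 3) {
    ch <- d[3]
    if (ch > 4) stop_input("images with more than 4 channels not supported")
    if (ch == 4) raster <- raster[, , 1:3, drop = FALSE]   # drop alpha
    if (ch == 2) raster <- raster[, , 1, drop = FALSE]     # gray + alpha
    g <- if (dim(raster)[3] == 3) {
      wts <- if (weights == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
      raster[, , 1] * wts[1] + raster[, , 2] * wts[2] + raster[, , 3] * wts[3]
    } else raster[, , 1]
  } else if (length(d) == 2) {
    g <- raster
  } else stop_input("raster must be a 2D matrix or 3D array")
  g <- matrix(as.numeric(g), d[1], d[2])
  if (maxval > 255L) {
    lo <- min(g); hi <- max(g)
    g <- if (hi > lo) (g - lo) * (255 / (hi - lo)) else g * (255 / maxval)
  }
  m <- matrix(iround(g), d[1], d[2])
  m[m < 0L] <- 0L; m[m > 255L] <- 255L
  m
}

# ---- calibration --------------------------------------------------------

#' Derive micrometers-per-pixel from a scale bar
#'
#' The analog of drawing a straight line over a printed scale bar and
#' setting the scale globally: given the bar's length in pixels and its
#' known physical length, returns the calibration factor applied to every
#' image of a batch.
#'
#' @param line_length_px length of the drawn line, pixels (> 0).
#' @param known_distance_um physical length of the scale bar, um (> 0).
#' @return `known_distance_um / line_length_px` (um per pixel).
#' @examples
#' calibrate_from_scale_bar(100, 50)  # 0.5 um/px
#' @export
calibrate_from_scale_bar <- function(line_length_px, known_distance_um) {
  for (v in list(line_length_px, known_distance_um))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_input("scale-bar lengths must be positive finite scalars")
  known_distance_um / line_length_px
}

#' Read an image as a calibrated 8-bit grayscale image
#'
#' Convenience wrapper: [load_image()] then [to_8bit_gray()] then
#' [calibrated_image()].
#'
#' @inheritParams load_image
#' @inheritParams calibrated_image
#' @param weights passed to [to_8bit_gray()].
#' @export
read_calibrated <- function(path, um_per_px = 1, weights = "mean") {
  calibrated_image(to_8bit_gray(load_image(path), weights = weights),
                   um_per_px = um_per_px)
}
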