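# Image and disparity-map I/O.
#
# Grayscale rasters are R numeric matrices in [0,1] (row, col). PNG goes
# through the png package, TIFF through the tiff package when available,
# PGM (P2/P5) and Middlebury PFM are parsed here. PFM stores float32
# scanlines bottom-to-top; the sign of the scale line encodes endianness
# (negative = little-endian).

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM by file extension. Multi-channel input is
#' converted to grayscale with the Rec. 601 luma weights
#' (0.299, 0.587, 0.114).
#'
#' @param path File path.
#' @return Numeric matrix in \[0,1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the tiff package", call. = FALSE)
      tiff::readTIFF(path)
    },
    pgm = return(read_pgm(path)),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(x)) == 3) {
    w <- c(0.299, 0.587, 0.114)
    nc <- dim(x)[3]
    if (nc >= 3) x <- x[, , 1] * w[1] + x[, , 2] * w[2] + x[, , 3] * w[3]
    else x <- x[, , 1]
  }
  x
}

#' Write a grayscale image
#'
#' Values are clipped to \[0,1\]. PNG is written at 8-bit depth (16-bit
#' grayscale PNG is available through [write_disparity_png16()]); TIFF and
#' PGM honour `bits`.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param path Destination; format chosen by extension.
#' @param bits 8 or 16 (TIFF/PGM).
#' @export
write_image <- function(img, path, bits = 8) {
  assert_gray(img)
  img <- clamp01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the tiff package", call. = FALSE)
      tiff::writeTIFF(img, path, bits.per.sample = bits)
    },
    pgm = write_pgm(img, path, maxval = if (bits == 16) 65535L else 255L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG with values {0, 255}
#'
#' @param mask Binary matrix.
#' @param path Destination PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic ", magic, ")", call. = FALSE)
  W <- as.integer(read_token()); H <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- H * W
  if (magic == "P5") {
    if (maxval < 256) v <- as.integer(readBin(con, "raw", n))
    else v <- readBin(con, "integer", n, size = 2, signed = FALSE,
                      endian = "big")
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  matrix(v / maxval, H, W, byrow = TRUE)
}

write_pgm <- function(img, path, maxval = 255L) {
  v <- round(t(clamp01(img)) * maxval)  # row-major order for the file
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval), con,
            eos = NULL)
  if (maxval < 256) writeBin(as.raw(as.integer(v)), con)
  else writeBin(as.integer(v), con, size = 2, endian = "big")
  invisible(path)
}

#' Read a Middlebury PFM disparity/float map
#'
#' Grayscale (`Pf`) maps only. Nonpositive and nonfinite values are returned
#' as stored; Middlebury encodes unknown disparities as `Inf`.
#'
#' @param path PFM file path.
#' @return Numeric matrix (row 1 = top of the image).
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line_raw <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("malformed PFM header at byte ",
                               seek(con, NA), call. = FALSE)
      if (b == as.raw(10)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  magic <- trimws(read_line_raw())
  if (magic != "Pf")
    stop("not a grayscale PFM file (magic '", magic, "')", call. = FALSE)
  dims <- strsplit(trimws(read_line_raw()), "[[:space:]]+")[[1]]
  W <- as.integer(dims[1]); H <- as.integer(dims[2])
  scale <- as.numeric(trimws(read_line_raw()))
  if (is.na(W) || is.na(H) || is.na(scale))
    stop("malformed PFM header at byte ", seek(con, NA), call. = FALSE)
  endian <- if (scale < 0) "little" else "big"
  v <- readBin(con, "numeric", n = H * W, size = 4, endian = endian)
  m <- matrix(v, H, W, byrow = TRUE)     # scanlines are left-to-right rows
  m[seq(H, 1), , drop = FALSE]           # stored bottom-to-top
}

#' Write a Middlebury PFM map (little-endian)
#'
#' @param m Numeric matrix (row 1 = top).
#' @param path Destination path.
#' @export
write_pfm <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("Pf\n%d %d\n-1.0\n", ncol(m), nrow(m)), con, eos = NULL)
  flipped <- m[seq(nrow(m), 1), , drop = FALSE]
  writeBin(as.numeric(t(flipped)), con, size = 4, endian = "little")
  invisible(path)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(writeBin(length(data), raw(), size = 4, endian = "big"),
    body,
    cpp_crc32(body))
}

# Minimal 16-bit grayscale PNG encoder (filter 0 scanlines, zlib via
# memCompress). png::writePNG only emits 8-bit output.
write_png16 <- function(u16, path) {
  H <- nrow(u16); W <- ncol(u16)
  v <- as.integer(round(t(u16)))                  # row-major sample order
  hi <- v %/% 256L; lo <- v %% 256L
  samples <- as.raw(as.vector(rbind(hi, lo)))     # big-endian 16-bit
  dim(samples) <- NULL
  rows <- matrix(samples, nrow = 2L * W)
  scan <- as.raw(rbind(raw(ncol(rows)), rows))    # filter byte 0 per row
  ihdr <- c(writeBin(W, raw(), size = 4, endian = "big"),
            writeBin(H, raw(), size = 4, endian = "big"),
            as.raw(c(16, 0, 0, 0, 0)))            # depth 16, grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.raw(scan), "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write a disparity map as 16-bit PNG plus a YAML sidecar with the scale
#'
#' The PNG stores `round(d * scale)` clipped to \[0, 65535\]; invalid (`NA`)
#' pixels become 0 and the sidecar records the scale and invalid
#' convention.
#'
#' @param d Disparity matrix (pixels; `NA` = invalid).
#' @param path PNG path; the sidecar is `<path>.yaml`.
#' @param scale Multiplier applied before quantisation.
#' @export
write_disparity_png16 <- function(d, path, scale = 256) {
  v <- d * scale
  v[!is.finite(v)] <- 0
  write_png16(pmin(pmax(v, 0), 65535), path)
  yaml::write_yaml(list(scale = scale, invalid = 0, max_value = 65535),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a 16-bit disparity PNG written by [write_disparity_png16()]
#'
#' @param path PNG path with its `<path>.yaml` sidecar.
#' @return Disparity matrix in pixels with 0-coded pixels returned as `NA`.
#' @export
read_disparity_png16 <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  v <- png::readPNG(path) * meta$max_value / meta$scale
  v[v == meta$invalid] <- NA_real_
  v
}
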