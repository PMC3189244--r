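# Thumbnail and mask I/O. PNG/JPEG go through the optional png/jpeg packages;
# PGM/PPM (both ASCII and binary) and CSV matrices are handled natively so the
# package has a dependency-free text path.

#' Read a slide thumbnail image
#'
#' Supported formats by extension: `.png`, `.jpg`/`.jpeg` (via the optional
#' \pkg{png} / \pkg{jpeg} packages), `.pgm`, `.ppm` (native), `.csv` (numeric
#' matrix). Returns intensities in `[0, 1]`: a matrix for grayscale input or
#' an `[h, w, 3]` array for RGB.
#'
#' @param path file path.
#' @return numeric matrix or 3-slice array in `[0, 1]`.
#' @export
read_thumbnail <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG requires the 'png' package; convert to PGM/PPM or CSV")
      }
      png::readPNG(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package; convert to PGM/PPM or CSV")
      }
      jpeg::readJPEG(path)
    },
    pgm = ,
    ppm = read_pnm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext)
  )
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  storage.mode(img) <- "double"
  if (max(img) > 1) img <- img / 255
  img
}

# Minimal PGM/PPM reader (P2/P3 ASCII, P5/P6 binary), 8- or 16-bit.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("not a supported PNM file: ", path)
  vals <- integer(0)
  # header tokens: width, height, maxval (comments start with '#')
  tok <- character(0)
  buf <- ""
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop("truncated PNM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else {
      buf <- paste0(buf, ch)
    }
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); maxval <- as.integer(tok[3])
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * channels
  if (magic %in% c("P2", "P3")) {
    rest <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1]])[seq_len(n)]
  } else {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  }
  v <- vals / maxval
  if (channels == 1L) {
    matrix(v, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, c(h, w, 3L))
    for (k in 1:3) arr[, , k] <- matrix(v[seq(k, n, by = 3L)], h, w, byrow = TRUE)
    arr
  }
}

#' Write a grayscale matrix as PGM
#'
#' @param img numeric matrix in `[0, 1]` or non-negative integer matrix (e.g.
#'   a label image), written with the requested `maxval`.
#' @param path output path.
#' @param maxval 255 (8-bit) or 65535 (16-bit).
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img), maxval %in% c(255L, 65535L))
  v <- if (is.double(img) && max(img) <= 1) round(img * maxval) else round(img)
  v <- pmin(pmax(v, 0), maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval), con, eos = NULL)
  v <- as.integer(t(v))
  if (maxval < 256L) {
    writeBin(as.raw(v), con)
  } else {
    writeBin(v, con, size = 2L, endian = "big")
  }
  invisible(path)
}

#' Write an RGB array as PPM (or PNG when the png package is present)
#'
#' @param img `[h, w, 3]` array in `[0, 1]`.
#' @param path output path; extension decides the format.
#' @export
write_rgb <- function(img, path) {
  stopifnot(length(dim(img)) == 3L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package; use a .ppm path instead")
    }
    png::writePNG(img, path)
    return(invisible(path))
  }
  v <- round(pmin(pmax(img, 0), 1) * 255)
  h <- dim(img)[1]; w <- dim(img)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  inter <- integer(3L * w * h)
  for (k in 1:3) inter[seq(k, length(inter), by = 3L)] <- as.integer(t(v[, , k]))
  writeBin(as.raw(inter), con)
  invisible(path)
}

#' Convert an RGB array to grayscale (Rec. 601 luminance)
#'
#' @param img matrix (returned unchanged) or `[h, w, 3]` array.
#' @return numeric matrix.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
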