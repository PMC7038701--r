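# File I/O: 16-bit grayscale depth PNGs (millimetres, 0 = no return),
# 8-bit label-mask PNGs (pixel value = class ID), whitespace-delimited text
# grids of normalized depth, a little-endian float32 grid format with a
# plain-text header, and pseudo-colour rendering of density maps.
#
# Reading PNGs goes through png::readPNG. None of the available imaging
# packages can WRITE a 16-bit grayscale PNG, so a minimal encoder lives
# here: IHDR/IDAT/IEND chunks, filter type 0 per scanline, zlib stream from
# memCompress(), table-driven CRC-32.

# ---- CRC-32 (for PNG chunks) ----------------------------------------------

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b[i]), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

int_to_raw4 <- function(x) {
  # big-endian 4-byte encoding of a (possibly negative, i.e. high-bit) int
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  c(int_to_raw4(length(data)), body, int_to_raw4(crc32(body)))
}

# write a 16-bit grayscale PNG from an integer matrix in [0, 65535]
write_png16 <- function(ints, path) {
  h <- nrow(ints); w <- ncol(ints)
  ihdr <- c(int_to_raw4(w), int_to_raw4(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  vals <- as.integer(t(ints))
  hi <- as.raw(vals %/% 256L)
  lo <- as.raw(vals %% 256L)
  sample_bytes <- as.raw(rbind(hi, lo))
  scan <- matrix(sample_bytes, nrow = 2L * w)
  idat <- memCompress(as.raw(rbind(raw(ncol(scan)), scan)), type = "gzip")
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
}

# ---- depth images ----------------------------------------------------------

#' Read a depth image
#'
#' Reads either a 16-bit grayscale PNG holding raw depth in millimetres
#' (0 = no return) or a whitespace-delimited text grid of already-normalized
#' values; the format is chosen by the file extension (`.png` vs anything
#' else). PNG depths are normalized via [normalize_depth()].
#'
#' @param path file to read.
#' @param d_min,d_max normalization range in mm for PNG input.
#' @return numeric matrix of normalized depths in `[0, 1]`.
#' @export
read_depth <- function(path, d_min = 500, d_max = 4500) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 16L)
      stop_invalid(path, ": expected a 16-bit PNG, got ", info$bit.depth,
                   "-bit")
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] > 2L)
        stop_invalid(path, ": expected a grayscale PNG, got ",
                     dim(img)[3L], " channels")
      img <- img[, , 1L]
    }
    raw_mm <- round(img * 65535)
    normalize_depth(raw_mm, d_min, d_max)
  } else {
    vals <- utils::read.table(path, header = FALSE)
    m <- as.matrix(vals)
    dimnames(m) <- NULL
    check_depth_image(m, path)
    m
  }
}

#' Write a depth image
#'
#' Writes normalized depth to a 16-bit grayscale PNG in millimetres
#' (inverting [normalize_depth()]; exact zeros stay 0, the no-return value)
#' or, for non-`.png` extensions, to a whitespace-delimited text grid of the
#' normalized values.
#'
#' @param img numeric matrix of normalized depths in `[0, 1]`.
#' @param path destination; extension selects the format.
#' @param d_min,d_max normalization range in mm used for PNG output.
#' @return `path`, invisibly.
#' @export
write_depth <- function(img, path, d_min = 500, d_max = 4500) {
  check_depth_image(img)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    mm <- round(d_min + img * (d_max - d_min))
    mm[img == 0] <- 0L
    write_png16(mm, path)
  } else {
    utils::write.table(format(img, digits = 9), path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---- label masks -----------------------------------------------------------

#' Read a label mask from an 8-bit PNG
#'
#' Pixel values are raw class IDs (background = 0).
#'
#' @param path PNG file.
#' @return integer matrix of class IDs.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Write a label mask to an 8-bit PNG
#'
#' @param mask integer matrix of class IDs in `[0, 255]`.
#' @param path destination PNG.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_label_mask(mask)
  if (max(mask) > 255L) stop_invalid("class IDs above 255 do not fit 8 bits")
  png::writePNG(mask / 255, path)
  invisible(path)
}

# ---- float32 grid format ---------------------------------------------------

#' Write a real-valued grid (binary float32 with a text header)
#'
#' Serializes an h-by-w grid as a plain-text header line
#' (`DDGRID1 h w float32 key=value ...`) followed by little-endian float32
#' values in row-major order. Used for density maps and feature maps.
#'
#' @param x numeric matrix, or a `depth_density_map` (its `s`/`variant`
#'   go into the header).
#' @param path destination file.
#' @param meta optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path, meta = NULL) {
  if (inherits(x, "depth_density_map")) {
    meta <- c(meta, s = as.character(x$s), variant = x$variant)
    x <- x$values
  }
  if (!is.matrix(x) || !is.numeric(x)) stop_invalid("x must be a numeric matrix")
  fields <- c("DDGRID1", nrow(x), ncol(x), "float32")
  if (length(meta) > 0)
    fields <- c(fields, paste0(names(meta), "=", meta))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(fields, collapse = " "), "\n")), con)
  writeBin(as.numeric(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path file to read.
#' @return numeric matrix; header metadata (if any) in attribute `"meta"`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop_invalid(path, ": truncated header")
    if (ch == charToRaw("\n")) break
    header <- c(header, rawToChar(ch))
  }
  fields <- strsplit(paste(header, collapse = ""), " ", fixed = TRUE)[[1L]]
  if (length(fields) < 4L || fields[1L] != "DDGRID1" || fields[4L] != "float32")
    stop_invalid(path, ": not a DDGRID1 float32 file")
  h <- as.integer(fields[2L]); w <- as.integer(fields[3L])
  vals <- readBin(con, "numeric", h * w, size = 4L, endian = "little")
  if (length(vals) != h * w) stop_invalid(path, ": truncated data")
  out <- matrix(vals, h, w, byrow = TRUE)
  if (length(fields) > 4L) {
    kv <- strsplit(fields[-(1:4)], "=", fixed = TRUE)
    meta <- vapply(kv, `[`, "", 2L)
    names(meta) <- vapply(kv, `[`, "", 1L)
    attr(out, "meta") <- meta
  }
  out
}

# ---- rendering -------------------------------------------------------------

#' Render a density map to a pseudo-colour image
#'
#' Maps `[0, 1]` linearly (after 8-bit quantization, `round(dd * 255)`) onto
#' a named palette.
#'
#' @param dd a `depth_density_map` or numeric matrix in `[0, 1]`.
#' @param colormap palette name accepted by [grDevices::hcl.colors()]
#'   (see [grDevices::hcl.pals()]); low density maps to the first colour.
#' @param path optional PNG destination; when given the image is written.
#' @return h-by-w-by-3 array of RGB values in `[0, 1]`, invisibly when
#'   `path` is given.
#' @export
render_density <- function(dd, colormap = "viridis", path = NULL) {
  if (inherits(dd, "depth_density_map")) dd <- dd$values
  if (!is.matrix(dd) || anyNA(dd) || min(dd) < 0 || max(dd) > 1)
    stop_invalid("dd must be a numeric matrix in [0, 1]")
  hit <- match(tolower(colormap), tolower(grDevices::hcl.pals()))
  if (is.na(hit)) stop_invalid("unknown colormap: ", colormap)
  pal <- grDevices::hcl.colors(256, grDevices::hcl.pals()[hit])
  idx <- as.integer(round(dd * 255)) + 1L
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, c(nrow(dd), ncol(dd), 3L))
  out[, , 1L] <- rgb[1L, ]; out[, , 2L] <- rgb[2L, ]; out[, , 3L] <- rgb[3L, ]
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
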