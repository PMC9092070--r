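# Image file I/O. PNG via the png package; TIFF via a minimal built-in
# baseline codec (uncompressed strips, little-endian, 8- or 16-bit RGB) —
# sections were acquired as TIF and no TIFF package is available here.

#' Write an RGB image as PNG
#' @param img H x W x 3 array, 0-255.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a label map as a single-channel PNG
#'
#' The class id is stored directly as the 8-bit gray value, keeping ids
#' unambiguous; use [colorize_labels()] for a display rendering.
#'
#' @param labels integer label matrix.
#' @param path output path.
#' @export
write_labels_png <- function(labels, path) {
  check_labels(labels)
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read a label map written by [write_labels_png()]
#' @param path PNG path.
#' @return integer label matrix (validated against the schema).
#' @export
read_labels_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) {
    if (dim(m)[3] >= 3 &&
        (any(m[, , 1] != m[, , 2]) || any(m[, , 1] != m[, , 3]))) {
      stopf("label PNG %s is not single-channel", path)
    }
    m <- m[, , 1]
  }
  lab <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  check_labels(lab)
  lab
}

#' Render a label map in the schema's display palette
#' @param labels integer label matrix.
#' @return H x W x 3 array, 0-255.
#' @export
colorize_labels <- function(labels) {
  check_labels(labels)
  pal <- label_palette()
  out <- array(0L, c(nrow(labels), ncol(labels), 3))
  for (ch in 1:3) out[, , ch] <- matrix(pal[labels + 1L, ch], nrow(labels))
  out
}

# ---- minimal baseline TIFF ------------------------------------------------

tiff_entry <- function(tag, type, count, value_raw) {
  if (length(value_raw) < 4) {
    value_raw <- c(value_raw, raw(4 - length(value_raw)))
  }
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw[1:4])
}

le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
le2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

#' Write an RGB image as an uncompressed baseline TIFF
#'
#' Little-endian, single strip, interleaved samples; `bits = 16` scales the
#' 0-255 input onto 0-65535 (value * 257).
#'
#' @param img H x W x 3 array, 0-255.
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @export
write_tiff_rgb <- function(img, path, bits = 8L) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stopf("expected an H x W x 3 array")
  H <- d[1]; W <- d[2]
  # interleave samples row-major: R,G,B per pixel, pixels left-to-right
  px <- aperm(img, c(3, 2, 1))  # [sample, col, row]
  vals <- as.integer(round(as.vector(px)))
  n_entries <- 9L
  header_len <- 8L
  ifd_len <- 2L + n_entries * 12L + 4L
  bps_off <- header_len + ifd_len          # BitsPerSample triple (6 bytes)
  data_off <- bps_off + 6L
  data <- if (bits == 8L) {
    as.raw(vals)
  } else {
    writeBin(as.integer(vals * 257L), raw(), size = 2, endian = "little")
  }
  entries <- c(
    tiff_entry(256, 3, 1, le2(W)),                       # ImageWidth
    tiff_entry(257, 3, 1, le2(H)),                       # ImageLength
    tiff_entry(258, 3, 3, le4(bps_off)),                 # BitsPerSample
    tiff_entry(259, 3, 1, le2(1)),                       # Compression: none
    tiff_entry(262, 3, 1, le2(2)),                       # Photometric: RGB
    tiff_entry(273, 4, 1, le4(data_off)),                # StripOffsets
    tiff_entry(277, 3, 1, le2(3)),                       # SamplesPerPixel
    tiff_entry(278, 3, 1, le2(H)),                       # RowsPerStrip
    tiff_entry(279, 4, 1, le4(length(data)))             # StripByteCounts
  )
  out <- c(charToRaw("II"), le2(42), le4(header_len),
           le2(n_entries), entries, le4(0),
           le2(rep(bits, 3)),
           data)
  writeBin(out, path)
  invisible(path)
}

read_uint <- function(raws, size, endian) {
  p <- if (endian == "little") seq_along(raws) - 1 else rev(seq_along(raws)) - 1
  sum(as.integer(raws) * 256^p)
}

#' Read an uncompressed baseline RGB TIFF
#'
#' Supports both byte orders, multiple strips, and 8- or 16-bit samples;
#' 16-bit data is rescaled deterministically to 8-bit as
#' `round(value / 257)` (so 65535 maps to 255).
#'
#' @param path TIFF path.
#' @return H x W x 3 integer array, 0-255.
#' @export
read_tiff_rgb <- function(path) {
  raws <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(raws[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stopf("%s is not a TIFF file", path)
  u <- function(off, size) read_uint(raws[(off + 1):(off + size)], size, endian)
  if (u(2, 2) != 42) stopf("%s is not a TIFF file", path)
  ifd <- u(4, 4)
  n <- u(ifd, 2)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- u(e, 2); type <- u(e + 2, 2); count <- u(e + 4, 4)
    tsize <- c(1, 1, 2, 4, 8)[type]
    total <- tsize * count
    voff <- if (total <= 4) e + 8 else u(e + 8, 4)
    vals <- vapply(seq_len(count), function(j) u(voff + (j - 1) * tsize, tsize),
                   numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) tags[[as.character(tag)]] %||%
    stopf("TIFF tag %d missing in %s", tag, path)
  W <- need(256); H <- need(257)
  bits <- unique(need(258))
  if (length(bits) != 1 || !bits %in% c(8, 16)) {
    stopf("unsupported TIFF bit depth in %s", path)
  }
  if ((tags[["259"]] %||% 1) != 1) stopf("compressed TIFF not supported: %s", path)
  spp <- tags[["277"]] %||% 1
  if (spp != 3) stopf("expected RGB TIFF (3 samples/pixel) in %s", path)
  offs <- need(273); counts <- need(279)
  data <- unlist(lapply(seq_along(offs), function(i) {
    raws[(offs[i] + 1):(offs[i] + counts[i])]
  }))
  vals <- if (bits == 8) {
    as.integer(data)
  } else {
    ints <- as.integer(data)
    lo_first <- endian == "little"
    i1 <- seq(1, length(ints), 2)
    v16 <- if (lo_first) ints[i1] + 256L * ints[i1 + 1] else
      256L * ints[i1] + ints[i1 + 1]
    as.integer(round(v16 / 257))
  }
  img <- aperm(array(vals, c(3, W, H)), c(3, 2, 1))
  storage.mode(img) <- "integer"
  img
}
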