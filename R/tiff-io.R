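# Minimal baseline TIFF 6.0 codec for grayscale movie stacks.
#
# Scope: uncompressed, single-sample (grayscale), 8- or 16-bit unsigned,
# multi-page; writer emits little-endian with one strip per page, reader
# accepts either byte order and arbitrary strip layouts. This is
# deliberately not a general TIFF library — it exists because movie stacks
# must round-trip losslessly in an environment with no TIFF package, and it
# fails loudly on anything outside its scope (compression, palettes, tiles).

tiff_type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)   # BYTE, SHORT, LONG

#' Write a movie as a multi-page grayscale TIFF
#'
#' Pixels are rounded and clamped to the unsigned integer range of `bits`.
#' Writing then reading back yields a bit-identical pixel array.
#'
#' @param movie a [trial_movie()], 3-d array, or single matrix.
#' @param path output file.
#' @param bits 8 or 16 (default 16, the usual two-photon acquisition depth).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits = 16L) {
  frames <- if (inherits(movie, "trial_movie")) movie$frames else movie
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stop_ft("movie must be a matrix or 3-d array")
  if (!bits %in% c(8L, 16L)) stop_ft("bits must be 8 or 16")
  h <- dim(frames)[1]; w <- dim(frames)[2]; n <- dim(frames)[3]
  bpp <- bits %/% 8L
  maxval <- 2^bits - 1

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  data_bytes <- h * w * bpp
  first_ifd <- 8L + n * data_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (p in seq_len(n)) {
    v <- as.integer(pmin(pmax(round(t(frames[, , p])), 0), maxval))
    if (bits == 16L) {
      v[v > 32767L] <- v[v > 32767L] - 65536L
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.raw(v), con)
    }
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {   # SHORT: low 2 bytes of the value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  ifd_size <- 2L + 10L * 12L + 4L
  for (p in seq_len(n)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)                      # ImageWidth
    entry(257L, 4L, 1L, h)                      # ImageLength
    entry(258L, 3L, 1L, bits)                   # BitsPerSample
    entry(259L, 3L, 1L, 1L)                     # Compression: none
    entry(262L, 3L, 1L, 1L)                     # Photometric: BlackIsZero
    entry(273L, 4L, 1L, 8L + (p - 1L) * data_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                     # SamplesPerPixel
    entry(278L, 4L, 1L, h)                      # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, 1L)                     # SampleFormat: unsigned
    nxt <- if (p < n) first_ifd + p * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF movie
#'
#' Accepts uncompressed grayscale baseline TIFF (8/16-bit unsigned, either
#' byte order, any strip layout). Truncated files and unsupported features
#' raise explicit errors rather than returning a short or garbled stack.
#'
#' @param path TIFF file.
#' @return numeric array `height x width x n_frames` with attribute `bits`.
#' @export
read_movie <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 8) stop_ft("not a TIFF file (too short): %s", path)
  raw <- readBin(path, "raw", n = sz)
  order <- rawToChar(raw[1:2])
  en <- if (order == "II") "little" else if (order == "MM") "big"
        else stop_ft("not a TIFF file (bad byte-order mark): %s", path)
  rd <- function(off, size, n = 1L) {
    if (off + size * n - 1L > sz) stop_ft("truncated TIFF: %s", path)
    readBin(raw[off:(off + size * n - 1L)], "integer", n = n, size = size,
            signed = FALSE, endian = en)
  }
  rd32 <- function(off, n = 1L) {  # unsigned 32-bit via double
    v <- rd(off, 2, 2L * n)
    a <- v[seq(1L, 2L * n, by = 2L)]; b <- v[seq(2L, 2L * n, by = 2L)]
    if (en == "little") b * 65536 + a else a * 65536 + b
  }
  if (rd(3, 2) != 42L) stop_ft("not a TIFF file (bad magic): %s", path)

  pages <- list(); page_bits <- 16L
  ifd_off <- rd32(5)
  while (ifd_off != 0) {
    n_ent <- rd(ifd_off + 1, 2)
    tags <- list()
    for (i in seq_len(n_ent)) {
      eoff <- ifd_off + 2L + (i - 1L) * 12L + 1L
      tag <- rd(eoff, 2); type <- rd(eoff + 2, 2); count <- rd32(eoff + 4)
      size <- tiff_type_size[as.character(type)]
      if (is.na(size)) next   # skip RATIONAL etc. — not needed
      voff <- if (size * count <= 4) eoff + 8L else rd32(eoff + 8) + 1L
      vals <- if (size == 4) rd32(voff, count) else rd(voff, size, count)
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_ft("TIFF missing required tag %d", tag)
        default
      } else v
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 1L)
    if (need(259, 1L) != 1L) stop_ft("compressed TIFF not supported: %s", path)
    if (need(277, 1L) != 1L) stop_ft("multi-sample TIFF not supported: %s", path)
    if (!need(339, 1L) %in% c(1L)) stop_ft("non-unsigned sample format: %s", path)
    if (!bits %in% c(8L, 16L)) stop_ft("unsupported bit depth %d: %s", bits, path)
    offs <- need(273); cnts <- need(279)
    bpp <- bits %/% 8L
    if (sum(cnts) != h * w * bpp)
      stop_ft("strip byte counts disagree with frame size: %s", path)
    px <- unlist(lapply(seq_along(offs), function(s) {
      if (offs[s] + cnts[s] > sz) stop_ft("truncated TIFF: %s", path)
      rd(offs[s] + 1L, bpp, cnts[s] %/% bpp)
    }))
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    page_bits <- bits
    ifd_off <- rd32(ifd_off + 2L + n_ent * 12L + 1L)
  }
  if (length(pages) == 0) stop_ft("TIFF has no pages: %s", path)
  out <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  attr(out, "bits") <- page_bits
  out
}

#' Write / read a boolean ROI mask as a single-page TIFF
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `write_roi_mask`: the path, invisibly; `read_roi_mask`: a
#'   logical matrix.
#' @export
write_roi_mask <- function(mask, path) {
  write_movie(array((mask > 0) * 255, c(dim(mask), 1L)), path, bits = 8L)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  m <- read_movie(path)
  if (dim(m)[3] != 1L) stop_ft("ROI mask must be a single-page TIFF")
  m[, , 1] > 0
}
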