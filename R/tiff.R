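# Minimal baseline TIFF 6.0 codec for grayscale image stacks.
#
# The pre-installed R stack has no TIFF package, so oct_io carries its own
# reader/writer restricted to what intravascular OCT exports and derived maps
# need: single-sample grayscale, uncompressed, 8/16-bit unsigned or 32-bit
# float, one or more pages (IFDs) per file. The writer always emits
# little-endian files; the reader accepts either byte order, any strip layout.
# Round-trips are exercised against Python's tifffile in the test suite.

.tif_u16 <- function(x) as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
.tif_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, (x %/% 256) %% 256,
                         (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

# One 12-byte IFD entry; type 3 = SHORT, 4 = LONG. Count is always 1 here.
.tif_entry <- function(tag, type, value) {
  val <- if (type == 3L) c(.tif_u16(value), as.raw(c(0L, 0L))) else .tif_u32(value)
  c(.tif_u16(tag), .tif_u16(type), .tif_u32(1L), val)
}

.tif_encode_page <- function(m, bits, float) {
  v <- as.vector(t(m))                       # row-major pixel order
  if (float) {
    con <- rawConnection(raw(0L), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.double(v), con, size = 4L, endian = "little")
    rawConnectionValue(con)
  } else if (bits == 8L) {
    as.raw(as.integer(round(v)))
  } else {
    .tif_u16(as.integer(round(v)))
  }
}

#' Write a grayscale image stack as a multi-page TIFF
#'
#' @param pages a matrix or list of matrices (rows = image rows / A-lines,
#'   columns = image columns / depth samples). All pages must share dimensions.
#' @param path output file path.
#' @param bits bits per sample: 8 or 16 for unsigned integer data, 32 for
#'   IEEE float (used when exporting attenuation/backscatter maps).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L)) abort_validation("bits must be 8, 16 or 32")
  float <- bits == 32L
  n <- length(pages)
  if (n > 0L) {
    dims <- vapply(pages, dim, integer(2L))
    if (any(dims != dims[, 1L])) abort_format("all pages must share the same dimensions")
    if (!float) {
      rng <- range(vapply(pages, range, numeric(2L)))
      if (rng[1L] < 0 || rng[2L] > 2^bits - 1)
        abort_validation("pixel values exceed the ", bits, "-bit range")
    }
    h <- dims[1L, 1L]; w <- dims[2L, 1L]
    page_bytes <- as.numeric(w) * h * (bits %/% 8L)
    data_off <- 8 + page_bytes * (seq_len(n) - 1)
    n_entries <- 10L
    ifd_bytes <- 2L + n_entries * 12L + 4L
    ifd_off <- 8 + page_bytes * n + ifd_bytes * (seq_len(n) - 1)
    first_ifd <- ifd_off[1L]
  } else {
    first_ifd <- 0
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(charToRaw("II"), .tif_u16(42L), .tif_u32(first_ifd)), con)
  for (p in seq_len(n)) writeBin(.tif_encode_page(pages[[p]], bits, float), con)
  for (p in seq_len(n)) {
    nxt <- if (p < n) ifd_off[p + 1L] else 0
    ifd <- c(
      .tif_u16(n_entries),
      .tif_entry(256L, 4L, w),                       # ImageWidth
      .tif_entry(257L, 4L, h),                       # ImageLength
      .tif_entry(258L, 3L, bits),                    # BitsPerSample
      .tif_entry(259L, 3L, 1L),                      # Compression = none
      .tif_entry(262L, 3L, 1L),                      # Photometric = BlackIsZero
      .tif_entry(273L, 4L, data_off[p]),             # StripOffsets
      .tif_entry(277L, 3L, 1L),                      # SamplesPerPixel
      .tif_entry(278L, 4L, h),                       # RowsPerStrip
      .tif_entry(279L, 4L, page_bytes),              # StripByteCounts
      .tif_entry(339L, 3L, if (float) 3L else 1L),   # SampleFormat
      .tif_u32(nxt)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

.tif_rd_u16 <- function(raw, pos, le) {
  a <- as.integer(raw[pos]); b <- as.integer(raw[pos + 1L])
  if (le) a + 256L * b else 256L * a + b
}
.tif_rd_u32 <- function(raw, pos, le) {
  b <- as.numeric(as.integer(raw[pos + 0:3]))
  if (!le) b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

# Scalar (count-1) or small-vector tag value for integer-typed entries.
.tif_tag_values <- function(raw, pos, le) {
  type <- .tif_rd_u16(raw, pos + 2L, le)
  count <- .tif_rd_u32(raw, pos + 4L, le)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L,
                 abort_format("unsupported TIFF tag type ", type))
  total <- size * count
  vpos <- if (total <= 4) pos + 8L else .tif_rd_u32(raw, pos + 8L, le) + 1L
  vapply(seq_len(count), function(i) {
    p <- vpos + (i - 1L) * size
    switch(as.character(size),
           "1" = as.numeric(raw[p]),
           "2" = as.numeric(.tif_rd_u16(raw, p, le)),
           "4" = .tif_rd_u32(raw, p, le))
  }, numeric(1L))
}

#' Read a grayscale multi-page TIFF into a list of matrices
#'
#' Supports the subset written by [write_tiff_stack()] plus arbitrary strip
#' layouts and either byte order. Values are returned as numeric matrices.
#'
#' @param path TIFF file path.
#' @return list of matrices, one per page (possibly empty, with a warning);
#'   integer matrices for 8/16-bit data (exact round-trip), numeric for float.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) abort_format("no such file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  order <- rawToChar(raw[1:2])
  le <- order == "II"
  if (!le && order != "MM") abort_format("not a TIFF file: ", path)
  if (.tif_rd_u16(raw, 3L, le) != 42L) abort_format("not a TIFF file: ", path)
  ifd <- .tif_rd_u32(raw, 5L, le)
  pages <- list()
  n_guard <- 0L
  while (ifd != 0) {
    if ((n_guard <- n_guard + 1L) > 1e5L) abort_format("cyclic IFD chain")
    pos <- ifd + 1L
    n_entries <- .tif_rd_u16(raw, pos, le)
    tags <- list()
    for (e in seq_len(n_entries)) {
      epos <- pos + 2L + (e - 1L) * 12L
      tag <- .tif_rd_u16(raw, epos, le)
      if (tag %in% c(256L, 257L, 258L, 259L, 273L, 277L, 278L, 279L, 339L))
        tags[[as.character(tag)]] <- .tif_tag_values(raw, epos, le)
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if (is.null(w) || is.null(h)) abort_format("TIFF page missing dimensions")
    if ((tags[["259"]] %||% 1) != 1) abort_format("compressed TIFF not supported")
    if ((tags[["277"]] %||% 1) != 1) abort_format("multi-sample TIFF not supported")
    bits <- tags[["258"]] %||% 8
    fmt <- tags[["339"]] %||% 1
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    if (is.null(offs)) abort_format("TIFF page missing strip offsets")
    if (is.null(cnts)) cnts <- rep(w * h * bits / 8 / length(offs), length(offs))
    buf <- raw[unlist(lapply(seq_along(offs),
                             function(i) offs[i] + seq_len(cnts[i])))]
    npix <- w * h
    v <- if (fmt == 3 && bits == 32) {
      if (!le) buf <- as.raw(as.vector(matrix(buf, nrow = 4L)[4:1, ]))
      readBin(buf, "double", n = npix, size = 4L, endian = "little")
    } else if (fmt == 1 && bits == 16) {
      readBin(buf, "integer", n = npix, size = 2L,
              signed = FALSE, endian = if (le) "little" else "big")
    } else if (fmt == 1 && bits == 8) {
      as.integer(buf)
    } else {
      abort_format("unsupported TIFF sample layout (bits ", bits, ", format ", fmt, ")")
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd <- .tif_rd_u32(raw, pos + 2L + n_entries * 12L, le)
  }
  if (length(pages) == 0L) warning("empty TIFF stack: ", path, call. = FALSE)
  pages
}
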