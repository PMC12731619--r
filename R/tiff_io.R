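# Minimal baseline-TIFF codec.
#
# Supports exactly what confocal-export and classifier-export files need here:
# uncompressed, single-sample (grayscale) pages, 8- or 16-bit unsigned integer
# or 32-bit IEEE float samples, one or more pages (pages = channels), either
# byte order on read (always little-endian on write). Anything else errors
# loudly rather than decoding garbage.

.u16 <- function(raw, off, endian) {
  b <- as.integer(raw[off + 0:1])
  if (endian == "little") b[1] + 256L * b[2] else b[2] + 256L * b[1]
}

.u32 <- function(raw, off, endian) {
  b <- as.numeric(raw[off + 0:3])
  if (endian == "little")
    b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  else
    b[4] + 256 * b[3] + 65536 * b[2] + 16777216 * b[1]
}

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

.read_tag_values <- function(raw, type, count, val_off, endian) {
  size <- .tiff_type_size[[as.character(type)]]
  total <- size * count
  data_off <- if (total <= 4) val_off else .u32(raw, val_off, endian) + 1
  vals <- numeric(count)
  for (i in seq_len(count)) {
    o <- data_off + (i - 1L) * size
    vals[i] <- switch(as.character(type),
      `1` = as.integer(raw[o]),
      `3` = .u16(raw, o, endian),
      `4` = .u32(raw, o, endian),
      stop("unsupported TIFF tag value type: ", type)
    )
  }
  vals
}

#' Read a grayscale TIFF file
#'
#' Reads an uncompressed single-sample TIFF. Multi-page files yield one
#' matrix per page (used here to carry one fluorescence channel per page).
#'
#' @param path Path to the TIFF file.
#' @return A list of numeric matrices, one per page, row-major image
#'   orientation (row 1 = top of image). Each matrix has attributes
#'   `bits` (8, 16 or 32) and `sample_format` ("uint" or "float").
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  if (.u16(raw, 3, endian) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- .u32(raw, 5, endian)
  pages <- list()
  while (ifd_off != 0) {
    base <- ifd_off + 1  # 1-based index into raw
    n_tags <- .u16(raw, base, endian)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- base + 2 + (i - 1L) * 12L
      tag <- .u16(raw, e, endian)
      type <- .u16(raw, e + 2, endian)
      count <- .u32(raw, e + 4, endian)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        val_off = e + 8)
    }
    gett <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      .read_tag_values(raw, t$type, t$count, t$val_off, endian)
    }
    width <- gett(256); height <- gett(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- gett(258, 1)[1]
    compression <- gett(259, 1)
    if (compression != 1) stop("only uncompressed TIFF is supported (compression tag = ",
                               compression, ")")
    spp <- gett(277, 1)
    if (spp != 1) stop("only single-sample (grayscale) TIFF pages are supported; ",
                       "use one page per channel")
    fmt <- gett(339, 1)
    strip_offsets <- gett(273)
    strip_counts <- gett(279, width * height * bits / 8)
    if (is.null(strip_offsets)) stop("TIFF page missing strip offsets")
    buf <- raw(0)
    for (i in seq_along(strip_offsets))
      buf <- c(buf, raw[strip_offsets[i] + seq_len(strip_counts[i]) - 1 + 1])
    n_px <- width * height
    if (fmt == 3) {
      if (bits != 32) stop("float TIFF must be 32-bit")
      vals <- readBin(buf, "numeric", n = n_px, size = 4, endian = endian)
      sfmt <- "float"
    } else if (fmt %in% c(1, 4)) {
      if (!bits %in% c(8, 16)) stop("unsigned TIFF must be 8- or 16-bit")
      vals <- readBin(buf, "integer", n = n_px, size = bits / 8,
                      signed = FALSE, endian = endian)
      sfmt <- "uint"
    } else stop("unsupported TIFF sample format: ", fmt)
    if (length(vals) < n_px) stop("TIFF strip data truncated")
    m <- matrix(vals[seq_len(n_px)], nrow = height, ncol = width, byrow = TRUE)
    attr(m, "bits") <- as.integer(bits)
    attr(m, "sample_format") <- sfmt
    pages[[length(pages) + 1L]] <- m
    ifd_off <- .u32(raw, base + 2 + n_tags * 12L, endian)
  }
  if (length(pages) == 0) stop("TIFF file contains no pages: ", path)
  pages
}

.le16 <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.le32 <- function(v) {
  v <- as.numeric(v)
  out <- raw(4 * length(v))
  for (i in seq_along(v)) {
    x <- v[i]
    b <- c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256)
    out[(i - 1) * 4 + 1:4] <- as.raw(b)
  }
  out
}

.tiff_entry <- function(tag, type, count, value_raw4) {
  c(.le16(tag), .le16(type), .le32(count), value_raw4)
}

#' Write a grayscale TIFF file
#'
#' Writes one or more matrices as pages of an uncompressed little-endian
#' grayscale TIFF. Integer data are written at `bits` depth (8 or 16);
#' `sample_format = "float"` writes 32-bit IEEE floats (used for
#' probability masks stored at unit scale).
#'
#' @param pages A numeric matrix or list of numeric matrices.
#' @param path Output path.
#' @param bits Bit depth for unsigned-integer output, 8 or 16.
#' @param sample_format `"uint"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 8L, sample_format = c("uint", "float")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  if (sample_format == "float") bits <- 32L
  if (sample_format == "uint" && !bits %in% c(8L, 16L))
    stop("uint TIFF supports bits = 8 or 16")
  fmt_code <- if (sample_format == "float") 3L else 1L
  n <- length(pages)
  # encode pixel data for every page first so all offsets are known up front
  datas <- lapply(pages, function(m) {
    vals <- as.vector(t(m))  # row-major strip layout
    data <- if (sample_format == "float") {
      writeBin(as.numeric(vals), raw(), size = 4, endian = "little")
    } else {
      iv <- as.integer(round(vals))
      if (any(iv < 0) || any(iv > 2^bits - 1))
        stop("pixel values out of range for ", bits, "-bit unsigned output")
      if (bits == 8L) as.raw(iv) else .le16(iv)
    }
    if (length(data) %% 2 == 1) data <- c(data, as.raw(0))  # word-align IFD
    data
  })
  n_entries <- 10L
  ifd_len <- 2 + 12 * n_entries + 4
  data_offs <- ifd_offs <- numeric(n)
  pos <- 8
  for (p in seq_len(n)) {
    data_offs[p] <- pos
    ifd_offs[p] <- pos + length(datas[[p]])
    pos <- ifd_offs[p] + ifd_len
  }
  con_parts <- list()
  for (p in seq_len(n)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    data <- datas[[p]]
    data_off <- data_offs[p]
    entries <- list(
      .tiff_entry(256, 4, 1, .le32(w)),
      .tiff_entry(257, 4, 1, .le32(h)),
      .tiff_entry(258, 3, 1, c(.le16(bits), as.raw(c(0, 0)))),
      .tiff_entry(259, 3, 1, c(.le16(1), as.raw(c(0, 0)))),
      .tiff_entry(262, 3, 1, c(.le16(1), as.raw(c(0, 0)))),
      .tiff_entry(273, 4, 1, .le32(data_off)),
      .tiff_entry(277, 3, 1, c(.le16(1), as.raw(c(0, 0)))),
      .tiff_entry(278, 4, 1, .le32(h)),
      .tiff_entry(279, 4, 1, .le32(h * w * bits / 8)),
      .tiff_entry(339, 3, 1, c(.le16(fmt_code), as.raw(c(0, 0))))
    )
    next_off <- if (p < n) ifd_offs[p + 1] else 0
    ifd <- c(.le16(length(entries)), do.call(c, entries), .le32(next_off))
    con_parts[[length(con_parts) + 1L]] <- c(data, ifd)
  }
  header <- c(charToRaw("II"), .le16(42), .le32(ifd_offs[1]))
  writeBin(c(header, do.call(c, con_parts)), path)
  invisible(path)
}
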