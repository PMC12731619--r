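# Domain containers and file I/O for images, probability masks, ROIs and
# result tables.
#
# Conventions (fixed across the package):
#  * images are numeric matrices, row 1 = top of image, 0-based pixel indices
#    in user-facing coordinates;
#  * polygon vertices are (x = column, y = row) in the ImageJ pixel coordinate
#    system, so the centre of pixel (row r, col c) sits at (c + 0.5, r + 0.5);
#  * probability masks are unit-scale in memory regardless of on-disk depth.

#' Intensity image
#'
#' A 2D grid of non-negative fluorescence intensities in arbitrary units,
#' e.g. one channel of a merged confocal z-projection.
#'
#' @param pixels Numeric matrix of intensities, all `>= 0`.
#' @param channel_name Text label for the channel.
#' @param pixel_size_um Optional physical pixel edge length in micrometres.
#' @return An `intensity_image` object.
#' @export
intensity_image <- function(pixels, channel_name = "", pixel_size_um = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (length(pixels) == 0) stop("image grid is empty")
  if (anyNA(pixels) || any(pixels < 0)) stop("intensities must be finite and >= 0")
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    stop("pixel_size_um must be > 0")
  structure(list(pixels = pixels, channel_name = channel_name,
                 pixel_size_um = pixel_size_um),
            class = "intensity_image")
}

#' Probability mask
#'
#' Per-pixel likelihood (in \[0, 1\]) that the pixel belongs to the signal of
#' interest, as exported by a pixel classifier.
#'
#' @param probs Numeric matrix with every value in \[0, 1\].
#' @param channel_name Text label.
#' @param source_scale Encoding the values had on disk: `"unit"` (already in
#'   \[0,1\]) or `"eight_bit"` / `"sixteen_bit"` (rescaled on read).
#' @return A `probability_mask` object.
#' @export
probability_mask <- function(probs, channel_name = "", source_scale = "unit") {
  stopifnot(is.matrix(probs), is.numeric(probs))
  if (length(probs) == 0) stop("probability grid is empty")
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("probability values must lie in [0, 1]")
  structure(list(probs = probs, channel_name = channel_name,
                 source_scale = source_scale),
            class = "probability_mask")
}

#' Read a raster file as an intensity image or probability mask
#'
#' Probability rasters stored at integer depth are rescaled to unit scale:
#' 8-bit values are divided by 255, 16-bit by 65535. Float rasters are taken
#' as-is and must already lie in \[0, 1\] in probability mode.
#'
#' @param path TIFF file path (uncompressed grayscale; multi-page allowed,
#'   `page` selects one).
#' @param expected `"intensity"` or `"probability"`.
#' @param channel_name Label attached to the result.
#' @param page Page index for multi-page files (default 1).
#' @return An [intensity_image] or [probability_mask].
#' @export
read_raster <- function(path, expected = c("intensity", "probability"),
                        channel_name = "", page = 1L) {
  expected <- match.arg(expected)
  pages <- read_tiff(path)
  if (page < 1 || page > length(pages))
    stop("page ", page, " out of range; file has ", length(pages), " page(s)")
  m <- pages[[page]]
  bits <- attr(m, "bits"); fmt <- attr(m, "sample_format")
  attributes(m) <- list(dim = dim(m))
  if (expected == "intensity") {
    return(intensity_image(m, channel_name = channel_name))
  }
  if (fmt == "uint" && bits == 8L) {
    probability_mask(m / 255, channel_name, source_scale = "eight_bit")
  } else if (fmt == "uint" && bits == 16L) {
    probability_mask(m / 65535, channel_name, source_scale = "sixteen_bit")
  } else {
    if (any(m < 0) || any(m > 1))
      stop("float probability raster has values outside [0, 1]: ", path)
    probability_mask(m, channel_name, source_scale = "unit")
  }
}

# ---------------------------------------------------------------------------
# ROIs

#' Region-of-interest specification
#'
#' Either a polygon outline (ordered vertices, `>= 3`, non-degenerate) or a
#' ready boolean mask. Polygon vertices are `(x = column, y = row)` pixel
#' coordinates with the origin at the top-left corner of the image.
#'
#' @param polygon Two-column numeric matrix of `(x, y)` vertices, or `NULL`.
#' @param mask Logical matrix, or `NULL`. Exactly one of `polygon`/`mask`.
#' @param name ROI label.
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(polygon = NULL, mask = NULL, name = "roi") {
  if (is.null(polygon) == is.null(mask))
    stop("provide exactly one of polygon or mask")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3)
      stop("polygon needs >= 3 (x, y) vertices")
    if (anyNA(polygon) || any(!is.finite(polygon)))
      stop("polygon vertices must be finite")
    if (abs(.polygon_area(polygon[, 1], polygon[, 2])) < 1e-9)
      stop("degenerate polygon (zero area)")
  } else {
    stopifnot(is.matrix(mask), is.logical(mask))
    if (!any(mask)) stop("ROI mask is empty")
  }
  structure(list(polygon = polygon, mask = mask, name = name),
            class = "roi_spec")
}

.polygon_area <- function(x, y) {
  n <- length(x); j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Even-odd point-in-polygon for vectors of points; points whose location lies
# exactly on a polygon edge count as inside.
.points_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # on-segment test
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    dot <- (px - xi) * (xj - xi) + (py - yi) * (yj - yi)
    len2 <- (xj - xi)^2 + (yj - yi)^2
    on_edge <- on_edge | (abs(cross) <= tol * max(1, sqrt(len2)) &
                            dot >= -tol & dot <= len2 + tol)
    crosses <- ((yi > py) != (yj > py))
    xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
    crosses <- crosses & (px < xint)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Rasterize an ROI to a boolean mask
#'
#' A pixel is included iff its centre `(col + 0.5, row + 0.5)` lies inside
#' the polygon under the even-odd rule; centres exactly on an edge are
#' included. Mask input of matching shape is returned unchanged.
#'
#' @param roi An [roi_spec].
#' @param shape Integer vector `c(rows, cols)`.
#' @return Logical matrix of dimension `shape`.
#' @export
roi_to_mask <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_spec"), length(shape) == 2, all(shape >= 1))
  if (!is.null(roi$mask)) {
    if (!all(dim(roi$mask) == shape))
      stop("ROI mask shape ", paste(dim(roi$mask), collapse = "x"),
           " does not match target ", paste(shape, collapse = "x"))
    return(roi$mask)
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  cx <- rep(seq_len(nc) - 0.5, each = nr)   # pixel-centre x per column
  cy <- rep(seq_len(nr) - 0.5, times = nc)  # pixel-centre y per row
  inside <- .points_in_polygon(cx, cy, roi$polygon[, 1], roi$polygon[, 2])
  m <- matrix(inside, nrow = nr, ncol = nc)
  if (!any(m)) stop("polygon covers no pixel centres (ROI outside grid?)")
  m
}

# --- ImageJ .roi binary format (minimal: polygon/freehand/traced/rect) ------

.be16 <- function(raw, off) {
  v <- as.integer(raw[off]) * 256L + as.integer(raw[off + 1])
  if (v >= 32768L) v - 65536L else v  # signed short
}

#' Read an ImageJ .roi file
#'
#' Supports polygon, freehand, traced and rectangle ROI types; returns the
#' outline as a polygon [roi_spec] in pixel coordinates.
#'
#' @param path Path to a `.roi` file.
#' @return An [roi_spec] with a polygon.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ .roi file: ", path)
  type <- as.integer(raw[7])
  top <- .be16(raw, 9); left <- .be16(raw, 11)
  bottom <- .be16(raw, 13); right <- .be16(raw, 15)
  n <- .be16(raw, 17)
  if (type == 1L) {  # rectangle
    poly <- cbind(x = c(left, right, right, left),
                  y = c(top, top, bottom, bottom))
    return(roi_spec(polygon = poly, name = sub("\\.roi$", "", basename(path))))
  }
  if (!type %in% c(0L, 7L, 8L))  # polygon, freehand, traced
    stop("unsupported ImageJ ROI type code: ", type)
  if (n < 3) stop("ImageJ ROI has fewer than 3 vertices")
  base <- 65L
  xs <- vapply(seq_len(n), function(i) .be16(raw, base + (i - 1L) * 2L), 0L)
  ys <- vapply(seq_len(n), function(i) .be16(raw, base + (n + i - 1L) * 2L), 0L)
  roi_spec(polygon = cbind(x = xs + left, y = ys + top),
           name = sub("\\.roi$", "", basename(path)))
}

.wbe16 <- function(v) {
  v <- as.integer(round(v)); v <- ifelse(v < 0, v + 65536L, v)
  as.raw(rbind(v %/% 256L, v %% 256L))
}

#' Write a polygon ROI as an ImageJ .roi file
#'
#' @param roi An [roi_spec] carrying a polygon.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  if (is.null(roi$polygon)) stop("only polygon ROIs can be written to .roi")
  xs <- round(roi$polygon[, 1]); ys <- round(roi$polygon[, 2])
  left <- min(xs); top <- min(ys)
  header <- raw(64)
  header[1:4] <- charToRaw("Iout")
  header[5:6] <- .wbe16(227)          # version
  header[7] <- as.raw(0L)             # polygon type
  header[9:10] <- .wbe16(top)
  header[11:12] <- .wbe16(left)
  header[13:14] <- .wbe16(max(ys))
  header[15:16] <- .wbe16(max(xs))
  header[17:18] <- .wbe16(length(xs))
  writeBin(c(header, .wbe16(xs - left), .wbe16(ys - top)), path)
  invisible(path)
}

#' Read a plain-text polygon ROI
#'
#' One `x,y` vertex per line, pixel coordinates, `#` comments allowed.
#'
#' @param path Path to the text file.
#' @return An [roi_spec] with a polygon.
#' @export
read_polygon_roi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) != 2)) stop("polygon file lines must be 'x,y': ", path)
  v <- do.call(rbind, lapply(parts, function(p) as.numeric(trimws(p))))
  roi_spec(polygon = cbind(x = v[, 1], y = v[, 2]),
           name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read an ROI file, dispatching on extension
#'
#' `.roi` files are parsed as ImageJ binary ROIs; anything else as the
#' plain-text `x,y`-per-line polygon format.
#'
#' @param path ROI file path.
#' @return An [roi_spec].
#' @export
read_roi <- function(path) {
  if (grepl("\\.roi$", path, ignore.case = TRUE)) read_imagej_roi(path)
  else read_polygon_roi(path)
}

# ---------------------------------------------------------------------------
# Result tables

#' Write a result table as CSV with reproducible formatting
#'
#' Columns keep the given order; doubles are printed with 17 significant
#' digits so re-reading reproduces each value exactly; rows are sorted by
#' `(image_id, signal)` when those columns are present (else by `fly_id`).
#' Writing the same records twice yields byte-identical files.
#'
#' @param records A data.frame (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  sort_cols <- intersect(c("image_id", "signal", "fly_id", "family"), names(df))
  if (nrow(df) > 1 && length(sort_cols) > 0)
    df <- df[do.call(order, df[sort_cols]), , drop = FALSE]
  fmt <- function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
      }, character(1))
      out
    } else if (is.logical(col)) {
      ifelse(is.na(col), "", ifelse(col, "TRUE", "FALSE"))
    } else {
      s <- as.character(col)
      s[is.na(s)] <- ""
      if (any(grepl("[,\"\n]", s))) stop("field values must not contain commas, quotes or newlines")
      s
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  lines <- paste(names(df), collapse = ",")
  if (nrow(df) > 0) {
    cells <- matrix(cells, nrow = nrow(df))
    lines <- c(lines, apply(cells, 1, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a result table written by [write_table]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a quantification record
#'
#' One row of the results schema: ROI-normalized area of one signal, with
#' optional colocalization fields against a partner signal.
#'
#' @param image_id,signal Identifiers.
#' @param roi_area_px ROI area in pixels (`> 0`).
#' @param signal_area_px Signal-in-ROI area in pixels.
#' @param partner_signal,overlap_area_px,overlap_percent Colocalization
#'   fields; `NA` for single-signal rows.
#' @param params_fingerprint Text fingerprint of the segmentation parameters.
#' @return One-row data.frame with `area_percent = 100 * signal / roi`.
#' @export
quant_record <- function(image_id, signal, roi_area_px, signal_area_px,
                         partner_signal = NA_character_,
                         overlap_area_px = NA_real_,
                         overlap_percent = NA_real_,
                         params_fingerprint = "") {
  if (roi_area_px <= 0) stop("roi_area_px must be > 0")
  data.frame(image_id = image_id, signal = signal,
             roi_area_px = as.double(roi_area_px),
             signal_area_px = as.double(signal_area_px),
             area_percent = 100 * signal_area_px / roi_area_px,
             partner_signal = partner_signal,
             overlap_area_px = as.double(overlap_area_px),
             overlap_percent = as.double(overlap_percent),
             params_fingerprint = params_fingerprint,
             stringsAsFactors = FALSE)
}
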