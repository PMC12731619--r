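# Probability-mask segmentation: threshold, label, size-filter.
#
# The signal thresholds mirror the published workflow: pixels are kept when
# their classifier probability exceeds the per-signal threshold (0.05 for the
# green TUNEL / amyloid channels, 0.1 for the azot reporter), connected
# components are labeled, and objects smaller than the per-signal minimum
# size (17 px TUNEL/azot, 18 px amyloid) are discarded as unlikely signal.

#' Segmentation parameters
#'
#' @param probability_threshold Probability cutoff in \[0, 1\]; pixels (or
#'   objects, see `probability_mode`) must exceed it strictly.
#' @param min_size_px Minimum admissible object area in pixels (`>= 1`);
#'   objects with area `>= min_size_px` survive.
#' @param connectivity Pixel adjacency, 4 or 8 (8 matches the ImageJ
#'   "Analyze Particles" default).
#' @param probability_mode `"pixel"`: threshold each pixel. `"object_mean"`:
#'   binarize at half the threshold, then drop objects whose mean probability
#'   does not exceed the threshold.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(probability_threshold = 0.05,
                                min_size_px = 17L,
                                connectivity = 8L,
                                probability_mode = c("pixel", "object_mean")) {
  probability_mode <- match.arg(probability_mode)
  if (probability_threshold < 0 || probability_threshold > 1)
    stop("probability_threshold must lie in [0, 1]")
  if (min_size_px < 1) stop("min_size_px must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(probability_threshold = probability_threshold,
                 min_size_px = as.integer(min_size_px),
                 connectivity = as.integer(connectivity),
                 probability_mode = probability_mode),
            class = "segmentation_params")
}

#' @export
format.segmentation_params <- function(x, ...) {
  sprintf("thr=%g;min=%d;conn=%d;mode=%s", x$probability_threshold,
          x$min_size_px, x$connectivity, x$probability_mode)
}

#' Binarize a probability mask
#'
#' A pixel is signal iff its probability is strictly greater than the
#' threshold; values exactly at the threshold are excluded.
#'
#' @param mask A [probability_mask] or numeric matrix in \[0, 1\].
#' @param thr Threshold in \[0, 1\].
#' @return Logical matrix of the same shape.
#' @export
binarize_probability <- function(mask, thr) {
  if (inherits(mask, "probability_mask")) mask <- mask$probs
  stopifnot(is.matrix(mask))
  if (thr < 0 || thr > 1) stop("threshold must lie in [0, 1]")
  mask > thr
}

.objects_table <- function(labels, probs = NULL) {
  k <- max(labels)
  if (k == 0) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mean_probability = numeric(0)))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab, nbins = k)
  # centroids in 0-based pixel indices (row, col)
  crow <- tapply(rows - 1L, lab, mean)
  ccol <- tapply(cols - 1L, lab, mean)
  mp <- if (is.null(probs)) rep(NA_real_, k) else
    as.numeric(tapply(probs[idx], lab, mean))
  data.frame(label = seq_len(k), area_px = area,
             centroid_row = as.numeric(crow), centroid_col = as.numeric(ccol),
             mean_probability = mp)
}

#' Label connected objects in a binary image
#'
#' Maximal connected components of true pixels get consecutive labels
#' 1..K assigned in raster (row-major) order of each component's first pixel,
#' so the output is deterministic.
#'
#' @param binary Logical matrix.
#' @param connectivity 4 or 8.
#' @param probs Optional probability matrix used to compute per-object mean
#'   probability.
#' @return A `labeled_object_map`: list with `labels` (integer matrix) and
#'   `objects` (data.frame of label, area_px, centroid, mean_probability).
#' @export
label_objects <- function(binary, connectivity = 8L, probs = NULL) {
  stopifnot(is.matrix(binary), is.logical(binary), length(binary) > 0)
  labels <- .cc_label(binary, as.integer(connectivity))
  structure(list(labels = labels, objects = .objects_table(labels, probs)),
            class = "labeled_object_map")
}

.relabel <- function(labels, keep, probs = NULL) {
  # keep: sorted vector of old labels to retain; renumber 1..K preserving order
  map <- integer(max(labels, 1L))
  map[keep] <- seq_along(keep)
  new <- labels
  pos <- labels > 0
  new[pos] <- ifelse(labels[pos] %in% keep, map[labels[pos]], 0L)
  structure(list(labels = new, objects = .objects_table(new, probs)),
            class = "labeled_object_map")
}

#' Remove objects below a minimum size
#'
#' Objects with `area_px < min_size_px` are erased from the label grid and the
#' object table; survivors are relabeled consecutively preserving order. An
#' object exactly at the minimum size is retained.
#'
#' @param objmap A `labeled_object_map`.
#' @param min_size_px Minimum admissible area in pixels.
#' @param probs Optional probability matrix for the rebuilt object table.
#' @return A filtered `labeled_object_map`.
#' @export
filter_min_size <- function(objmap, min_size_px, probs = NULL) {
  stopifnot(inherits(objmap, "labeled_object_map"), min_size_px >= 1)
  keep <- objmap$objects$label[objmap$objects$area_px >= min_size_px]
  .relabel(objmap$labels, keep, probs)
}

#' Segment a probability mask into signal objects
#'
#' Pixel mode: binarize at the probability threshold, label connected
#' components, then apply the minimum-size filter. Object-mean mode: binarize
#' at half the threshold, label, drop objects whose mean probability does not
#' exceed the threshold, then size-filter.
#'
#' @param mask A [probability_mask] (or numeric matrix in \[0, 1\]).
#' @param params A [segmentation_params].
#' @return A `labeled_object_map`.
#' @export
segment <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  probs <- if (inherits(mask, "probability_mask")) mask$probs else mask
  if (params$probability_mode == "pixel") {
    bin <- binarize_probability(probs, params$probability_threshold)
    om <- label_objects(bin, params$connectivity, probs = probs)
  } else {
    bin <- binarize_probability(probs, 0.5 * params$probability_threshold)
    om <- label_objects(bin, params$connectivity, probs = probs)
    keep <- om$objects$label[om$objects$mean_probability >
                               params$probability_threshold]
    om <- .relabel(om$labels, keep, probs = probs)
  }
  filter_min_size(om, params$min_size_px, probs = probs)
}

#' Intensity-threshold reference segmentation
#'
#' The "standard method" arm of the validation harness: the same
#' label-and-size-filter pipeline, but binarizing raw intensity
#' (`intensity > threshold`) instead of classifier probability, as an
#' ImageJ/Fiji-style manual thresholding would.
#'
#' @param image An [intensity_image] (or numeric matrix).
#' @param intensity_threshold Intensity cutoff (strict `>`).
#' @param min_size_px Minimum object area in pixels.
#' @param connectivity 4 or 8.
#' @return A `labeled_object_map`.
#' @export
intensity_segment_reference <- function(image, intensity_threshold,
                                        min_size_px = 1L, connectivity = 8L) {
  px <- if (inherits(image, "intensity_image")) image$pixels else image
  stopifnot(is.matrix(px))
  bin <- px > intensity_threshold
  filter_min_size(label_objects(bin, connectivity), min_size_px)
}
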