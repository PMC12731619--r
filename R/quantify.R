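# ROI-normalized area, binary colocalization, CTCF and method agreement.

.as_labels <- function(x) {
  if (inherits(x, "labeled_object_map")) x$labels
  else if (is.matrix(x)) x
  else stop("expected a labeled_object_map or matrix")
}

#' ROI-normalized signal area
#'
#' The published readout: area of the segmented signal inside the region of
#' interest, expressed as a percentage of ROI area.
#'
#' @param objmap A `labeled_object_map` (or logical/integer matrix).
#' @param roi Logical ROI matrix of matching shape.
#' @return A `signal_quant`: list with `roi_area_px`, `signal_area_px`,
#'   `area_percent`.
#' @export
area_fraction <- function(objmap, roi) {
  labels <- .as_labels(objmap)
  stopifnot(is.matrix(roi), all(dim(labels) == dim(roi)))
  roi_area <- sum(roi)
  if (roi_area == 0) stop("ROI is empty")
  signal_area <- sum(labels > 0 & roi)
  structure(list(roi_area_px = roi_area, signal_area_px = signal_area,
                 area_percent = 100 * signal_area / roi_area),
            class = "signal_quant")
}

#' Two-channel binary colocalization
#'
#' Overlap of two segmented signals within the ROI. The primary quantity is
#' the pairwise overlap area as a percentage of ROI area. Per-object counts
#' use the A channel's objects restricted to the ROI: in `"partial"` mode an
#' A object counts as colocalized iff it shares at least one ROI pixel with
#' B; in `"total"` mode iff all of its ROI pixels lie within B.
#'
#' @param objA,objB `labeled_object_map`s of matching shape.
#' @param roi Logical ROI matrix.
#' @param mode `"partial"` (default) or `"total"`.
#' @return A `coloc_quant`: list with `overlap_area_px`,
#'   `overlap_percent_of_roi`, `mode`, `n_A_objects_colocalized`,
#'   `n_A_objects_total`.
#' @export
colocalize <- function(objA, objB, roi, mode = c("partial", "total")) {
  mode <- match.arg(mode)
  A <- .as_labels(objA); B <- .as_labels(objB)
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(roi)))
  if (sum(roi) == 0) stop("ROI is empty")
  overlap <- sum(A > 0 & B > 0 & roi)
  a_in_roi <- A[roi]
  b_in_roi <- B[roi] > 0
  labs <- sort(unique(a_in_roi[a_in_roi > 0]))
  n_coloc <- 0L
  for (l in labs) {
    in_b <- b_in_roi[a_in_roi == l]
    hit <- if (mode == "partial") any(in_b) else all(in_b)
    n_coloc <- n_coloc + as.integer(hit)
  }
  structure(list(overlap_area_px = overlap,
                 overlap_percent_of_roi = 100 * overlap / sum(roi),
                 mode = mode,
                 n_A_objects_colocalized = n_coloc,
                 n_A_objects_total = length(labs)),
            class = "coloc_quant")
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - cell area x mean background intensity`,
#' the standard background-corrected brightness measure for a labeled cell
#' region against a nearby signal-free region.
#'
#' @param image An [intensity_image] (or numeric matrix).
#' @param cell_mask Logical matrix selecting the cell region.
#' @param background_mask Logical matrix selecting the background region;
#'   must be disjoint from `cell_mask`.
#' @return A `ctcf_result`: list with `integrated_density`, `cell_area_px`,
#'   `background_mean`, `ctcf`.
#' @export
ctcf <- function(image, cell_mask, background_mask) {
  px <- if (inherits(image, "intensity_image")) image$pixels else image
  stopifnot(is.matrix(px), all(dim(px) == dim(cell_mask)),
            all(dim(px) == dim(background_mask)))
  if (!any(cell_mask)) stop("cell mask is empty")
  if (!any(background_mask)) stop("background mask is empty")
  if (any(cell_mask & background_mask))
    stop("cell and background masks overlap")
  integrated <- sum(px[cell_mask])
  area <- sum(cell_mask)
  bg <- mean(px[background_mask])
  structure(list(integrated_density = integrated, cell_area_px = area,
                 background_mean = bg, ctcf = integrated - area * bg),
            class = "ctcf_result")
}

#' Agreement between a reference and an automated segmentation
#'
#' Pairs objects of the two maps by any-overlap bipartite matching on their
#' ROI-clipped pixels: a maximum-cardinality matching computed by augmenting
#' paths, seeded greedily in descending overlap-area order (ties broken by
#' reference label, then automated label), so the result is deterministic and
#' `n_matched` equals the true maximum number of one-to-one overlapping
#' pairs.
#'
#' @param reference,automated `labeled_object_map`s of matching shape.
#' @param roi Logical ROI matrix (default: everything).
#' @return A `method_agreement`: list with `n_objects_reference`,
#'   `n_objects_automated`, `n_matched`, `n_only_reference`,
#'   `n_only_automated`.
#' @export
method_agreement <- function(reference, automated, roi = NULL) {
  R <- .as_labels(reference); A <- .as_labels(automated)
  stopifnot(all(dim(R) == dim(A)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(R), ncol(R))
  stopifnot(all(dim(R) == dim(roi)))
  r <- R[roi]; a <- A[roi]
  # objects present inside the ROI
  rl <- sort(unique(r[r > 0])); al <- sort(unique(a[a > 0]))
  both <- r > 0 & a > 0
  pairs <- if (any(both)) {
    tab <- table(r[both], a[both])
    d <- as.data.frame(tab, stringsAsFactors = FALSE)
    d <- d[d$Freq > 0, , drop = FALSE]
    d$ref <- as.integer(d$Var1); d$auto <- as.integer(d$Var2)
    d[order(-d$Freq, d$ref, d$auto), c("ref", "auto", "Freq")]
  } else data.frame(ref = integer(0), auto = integer(0), Freq = integer(0))
  # adjacency in greedy (descending-overlap) order, then augmenting paths for
  # maximum cardinality
  adj <- split(pairs$auto, factor(pairs$ref, levels = rl))
  match_of_a <- new.env(parent = emptyenv())
  try_augment <- function(r_lab, visited) {
    for (a_lab in adj[[as.character(r_lab)]]) {
      key <- as.character(a_lab)
      if (key %in% visited$seen) next
      visited$seen <- c(visited$seen, key)
      cur <- match_of_a[[key]]
      if (is.null(cur) || try_augment(cur, visited)) {
        match_of_a[[key]] <- r_lab
        return(TRUE)
      }
    }
    FALSE
  }
  n_matched <- 0L
  for (r_lab in rl) {
    if (length(adj[[as.character(r_lab)]]) == 0) next
    visited <- new.env(); visited$seen <- character(0)
    if (try_augment(r_lab, visited)) n_matched <- n_matched + 1L
  }
  structure(list(n_objects_reference = length(rl),
                 n_objects_automated = length(al),
                 n_matched = n_matched,
                 n_only_reference = length(rl) - n_matched,
                 n_only_automated = length(al) - n_matched),
            class = "method_agreement")
}
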