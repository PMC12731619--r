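# Synthetic scenes, trajectories and group measurements with exact ground
# truth.
#
# Scenes emulate what the quantification pipeline actually consumes: two (or
# more) channels of disk-like stained objects in an optic-lobe-sized frame,
# with per-channel classifier probability maps. Disks are used because their
# rasterized pixel areas are exact and translation-invariant, which makes the
# engineered inter-channel overlap an exact pixel count rather than an
# expectation.

#' Synthetic scene recipe
#'
#' @param shape `c(rows, cols)` of the frame.
#' @param channels List of channel recipes, each a list with `name`,
#'   `n_objects`, `radius` (scalar or `c(min, max)` in px), `prob` (interior
#'   classifier probability), `intensity` (interior intensity, a.u.).
#' @param overlap_pair Indices of the two channels whose overlap is
#'   engineered (default `c(1, 2)` when two channels exist, else `NULL`).
#' @param overlap_fraction Target overlap fraction `f` in \[0, 1\]: each
#'   paired object aims at `round(f * min(pair areas))` shared pixels. On a
#'   pixel grid intermediate fractions are realized to the nearest attainable
#'   integer shift; the ground truth records the realized overlap.
#' @param blur_sigma Gaussian blur (px) applied to the probability maps.
#' @param noise_prob Background probability noise ceiling in \[0, 1):
#'   background pixels get iid Uniform(0, noise_prob) probabilities.
#' @param seed RNG seed; a fixed seed makes the whole scene deterministic.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(shape = c(128L, 128L),
                       channels = list(
                         list(name = "azot", n_objects = 10L, radius = 4,
                              prob = 1.0, intensity = 200),
                         list(name = "TUNEL", n_objects = 10L, radius = 4,
                              prob = 1.0, intensity = 180)),
                       overlap_pair = if (length(channels) >= 2) c(1L, 2L) else NULL,
                       overlap_fraction = 0,
                       blur_sigma = 0,
                       noise_prob = 0,
                       seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 8))
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  if (noise_prob < 0 || noise_prob >= 1)
    stop("noise_prob must lie in [0, 1)")
  for (ch in channels) {
    r <- ch$radius
    if (any(r <= 0)) stop("radii must be positive")
    if (2 * max(r) + 2 >= min(shape)) stop("objects do not fit inside the grid")
  }
  if (!is.null(overlap_pair)) stopifnot(length(overlap_pair) == 2,
                                        all(overlap_pair <= length(channels)))
  structure(list(shape = as.integer(shape), channels = channels,
                 overlap_pair = overlap_pair,
                 overlap_fraction = overlap_fraction,
                 blur_sigma = blur_sigma, noise_prob = noise_prob,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Pixel set of a disk centred on pixel (r0, c0), radius r (pixel units).
.disk_pixels <- function(shape, r0, c0, r) {
  rr <- max(1L, floor(r0 - r)):min(shape[1], ceiling(r0 + r))
  cc <- max(1L, floor(c0 - r)):min(shape[2], ceiling(c0 + r))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - r0)^2 + (g$col - c0)^2 <= r^2
  cbind(row = g$row[keep], col = g$col[keep])
}

.pix_index <- function(px, shape) (px[, "col"] - 1L) * shape[1] + px[, "row"]

# Indices of a pixel set dilated by its 8-neighbourhood (clipped to the
# grid). Used to keep same-channel objects at least one pixel apart so they
# never merge under 8-connectivity and the generated object count is exact.
.dilate_idx <- function(px, shape) {
  rows <- rep(px[, "row"], 9L) + rep(c(-1L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L),
                                     each = nrow(px))
  cols <- rep(px[, "col"], 9L) + rep(c(-1L, 0L, 1L, -1L, 0L, 1L, -1L, 0L, 1L),
                                     each = nrow(px))
  ok <- rows >= 1L & rows <= shape[1] & cols >= 1L & cols <= shape[2]
  unique((cols[ok] - 1L) * shape[1] + rows[ok])
}

#' Gaussian blur of a matrix
#'
#' Separable convolution with a discrete Gaussian kernel (half-width
#' `ceiling(3 sigma)`), edge-replicated boundaries.
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; `<= 0` returns `m` unchanged.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(mat) {  # along rows (dimension 1)
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      out <- out + k[j] * mat[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

.place_disk <- function(shape, r, occupied_idx, forbidden_idx, max_tries = 2000L) {
  margin <- ceiling(r) + 1L
  for (try in seq_len(max_tries)) {
    r0 <- sample(margin:(shape[1] - margin), 1)
    c0 <- sample(margin:(shape[2] - margin), 1)
    px <- .disk_pixels(shape, r0, c0, r)
    idx <- .pix_index(px, shape)
    # same-channel objects must not touch even diagonally (dilated check);
    # cross-channel contact is controlled separately via forbidden_idx
    if (!any(.dilate_idx(px, shape) %in% occupied_idx) &&
        !any(idx %in% forbidden_idx))
      return(list(center = c(r0, c0), pixels = px, idx = idx))
  }
  stop("disk placement failed after ", max_tries,
       " tries (scene too dense)")
}

# Candidate integer offsets (dr, dc) of a radius-rB disk from the centre of a
# radius-rA disk, ordered by closeness of the rasterized pixel overlap to
# `target`. Only the dr >= 0, dc >= dr octant is enumerated; sign and axis
# permutations are applied at placement time (they leave the overlap
# unchanged by symmetry of the rasterized disks).
.offsets_for_overlap <- function(rA, rB, target) {
  D <- ceiling(rA + rB) + 1L
  big <- 2L * (D + ceiling(max(rA, rB))) + 5L
  mid <- ceiling(big / 2)
  A <- .pix_index(.disk_pixels(c(big, big), mid, mid, rA), c(big, big))
  cand <- expand.grid(dr = 0:D, dc = 0:D)
  cand <- cand[cand$dc >= cand$dr, , drop = FALSE]
  cand$ov <- vapply(seq_len(nrow(cand)), function(i) {
    B <- .pix_index(.disk_pixels(c(big, big), mid + cand$dr[i],
                                 mid + cand$dc[i], rB), c(big, big))
    sum(B %in% A)
  }, numeric(1))
  # prefer exact target; break ties toward smaller displacement
  cand[order(abs(cand$ov - target), cand$dr^2 + cand$dc^2), , drop = FALSE]
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' Disks are placed by rejection sampling, non-overlapping within each
#' channel. For the designated channel pair, each object of the second
#' channel is placed at an integer offset from its partner in the first so
#' the shared pixel count is as close as possible to
#' `round(f * min(pair areas))`; all other inter-channel overlap is forbidden,
#' so the scene's total true overlap equals the sum of the engineered pair
#' overlaps. Ground truth is asserted pixel-identical to the rendered masks
#' at generation time.
#'
#' @param spec A [scene_spec].
#' @return A `scene`: list with `images` (list of [intensity_image]),
#'   `masks` (list of [probability_mask]), and `truth` (per-channel label
#'   matrices and object areas, `overlap_area_px` realized,
#'   `overlap_target_px`, `overlap_pair`, `seed`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  nch <- length(spec$channels)
  labels <- lapply(seq_len(nch), function(i) matrix(0L, shape[1], shape[2]))
  areas <- vector("list", nch)
  centers <- vector("list", nch)
  radii <- vector("list", nch)
  pair <- spec$overlap_pair
  f <- spec$overlap_fraction
  engineered <- !is.null(pair) && spec$channels[[pair[2]]]$n_objects > 0

  sample_radius <- function(ch) {
    r <- ch$radius
    if (length(r) == 1) rep(r, ch$n_objects)
    else stats::runif(ch$n_objects, r[1], r[2])
  }

  # place every channel except the paired second channel independently
  order_ch <- if (engineered) c(pair[1], setdiff(seq_len(nch), pair)) else seq_len(nch)
  for (i in order_ch) {
    ch <- spec$channels[[i]]
    radii[[i]] <- sample_radius(ch)
    occupied <- integer(0)
    cs <- matrix(0L, ch$n_objects, 2)
    ar <- integer(ch$n_objects)
    for (o in seq_len(ch$n_objects)) {
      pl <- .place_disk(shape, radii[[i]][o], occupied, integer(0))
      labels[[i]][pl$idx] <- o
      occupied <- c(occupied, pl$idx)
      cs[o, ] <- pl$center
      ar[o] <- length(pl$idx)
    }
    centers[[i]] <- cs
    areas[[i]] <- ar
  }

  overlap_target <- 0L
  if (engineered) {
    a <- pair[1]; b <- pair[2]
    chb <- spec$channels[[b]]
    radii[[b]] <- sample_radius(chb)
    n_paired <- min(spec$channels[[a]]$n_objects, chb$n_objects)
    occupied_b <- integer(0)
    a_all <- which(labels[[a]] > 0)
    cs <- matrix(0L, chb$n_objects, 2)
    ar <- integer(chb$n_objects)
    for (o in seq_len(chb$n_objects)) {
      rB <- radii[[b]][o]
      if (o <= n_paired && f > 0) {
        rA <- radii[[a]][o]
        side <- 2L * ceiling(rB) + 5L
        areaB <- nrow(.disk_pixels(c(side, side), ceiling(rB) + 2L,
                                   ceiling(rB) + 2L, rB))
        target <- round(f * min(areas[[a]][o], areaB))
        cand <- .offsets_for_overlap(rA, rB, target)
        ctrA <- centers[[a]][o, ]
        a_other <- setdiff(a_all, which(labels[[a]] == o))
        placed <- FALSE
        perms <- expand.grid(sr = c(1, -1), sc = c(1, -1), swap = c(FALSE, TRUE))
        for (ci in seq_len(nrow(cand))) {
          d <- c(cand$dr[ci], cand$dc[ci])
          for (k in sample(nrow(perms))) {
            dd <- if (perms$swap[k]) rev(d) else d
            ctr <- ctrA + dd * c(perms$sr[k], perms$sc[k])
            if (ctr[1] <= ceiling(rB) || ctr[1] > shape[1] - ceiling(rB) - 1 ||
                ctr[2] <= ceiling(rB) || ctr[2] > shape[2] - ceiling(rB) - 1) next
            px <- .disk_pixels(shape, ctr[1], ctr[2], rB)
            idx <- .pix_index(px, shape)
            if (any(.dilate_idx(px, shape) %in% occupied_b) ||
                any(idx %in% a_other)) next
            # only the partner may be hit; the realized overlap is recorded
            # in the ground truth from the rendered labels
            labels[[b]][idx] <- o
            occupied_b <- c(occupied_b, idx)
            cs[o, ] <- ctr; ar[o] <- length(idx)
            overlap_target <- overlap_target + target
            placed <- TRUE
            break
          }
          if (placed) break
        }
        if (!placed) stop("could not place paired object ", o,
                          " (scene too dense for the requested overlap)")
      } else {
        # unpaired or f == 0: forbid any contact with channel a
        pl <- .place_disk(shape, rB, occupied_b, a_all)
        labels[[b]][pl$idx] <- o
        occupied_b <- c(occupied_b, pl$idx)
        cs[o, ] <- pl$center
        ar[o] <- length(pl$idx)
      }
    }
    centers[[b]] <- cs
    areas[[b]] <- ar
  }

  # render probability masks and intensity images from the labels
  masks <- vector("list", nch); images <- vector("list", nch)
  for (i in seq_len(nch)) {
    ch <- spec$channels[[i]]
    fg <- labels[[i]] > 0
    probs <- matrix(0, shape[1], shape[2])
    if (spec$noise_prob > 0)
      probs[] <- stats::runif(length(probs), 0, spec$noise_prob)
    probs[fg] <- ch$prob
    # ground-truth labels are the render source; assert noise stays strictly
    # below the interior probability so the binary render equals the truth
    stopifnot(all(probs[fg] == ch$prob), all(probs[!fg] < ch$prob))
    if (spec$blur_sigma > 0) {
      probs <- gaussian_blur(probs, spec$blur_sigma)
      probs[probs < 0] <- 0
      probs[probs > 1] <- 1
    }
    masks[[i]] <- probability_mask(probs, channel_name = ch$name)
    img <- matrix(0, shape[1], shape[2])
    img[fg] <- ch$intensity
    images[[i]] <- intensity_image(img, channel_name = ch$name)
  }
  names(masks) <- names(images) <- vapply(spec$channels, `[[`, "", "name")

  overlap_area <- if (!is.null(pair))
    sum(labels[[pair[1]]] > 0 & labels[[pair[2]]] > 0) else NA_integer_
  list(images = images, masks = masks,
       truth = list(labels = labels, areas = areas,
                    overlap_area_px = overlap_area,
                    overlap_target_px = overlap_target,
                    overlap_pair = pair, seed = spec$seed))
}

#' Write a scene to disk as pipeline-ready fixtures
#'
#' Probability masks as float TIFFs, intensity images as 16-bit TIFFs, a
#' rectangular ROI covering the frame interior as an ImageJ `.roi` file, and
#' a ground-truth CSV.
#'
#' @param scene Output of [generate_scene].
#' @param dir Output directory (created if missing).
#' @param image_id Stem used in file names.
#' @return Named list of written paths, invisibly.
#' @export
write_scene_fixtures <- function(scene, dir, image_id = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(scene$masks)) {
    p <- file.path(dir, sprintf("%s_mask_%s.tif", image_id, nm))
    write_tiff(scene$masks[[nm]]$probs, p, sample_format = "float")
    paths[[paste0("mask_", nm)]] <- p
    q <- file.path(dir, sprintf("%s_intensity_%s.tif", image_id, nm))
    write_tiff(scene$images[[nm]]$pixels, q, bits = 16L)
    paths[[paste0("intensity_", nm)]] <- q
  }
  shape <- dim(scene$masks[[1]]$probs)
  roi <- roi_spec(polygon = cbind(x = c(1, shape[2] - 1, shape[2] - 1, 1),
                                  y = c(1, 1, shape[1] - 1, shape[1] - 1)),
                  name = paste0(image_id, "_roi"))
  rp <- file.path(dir, paste0(image_id, "_roi.roi"))
  write_imagej_roi(roi, rp)
  paths$roi <- rp
  tr <- data.frame(channel = names(scene$masks),
                   n_objects = vapply(scene$truth$areas, length, 0L),
                   total_area_px = vapply(scene$truth$areas, sum, 0))
  tp <- file.path(dir, paste0(image_id, "_truth.csv"))
  write_table(tr, tp)
  paths$truth <- tp
  invisible(paths)
}

#' Synthetic trajectory recipe
#'
#' Piecewise-constant-speed track. Segment lengths and immobile-run bounds
#' must be integer multiples of `dt_s` so the sampled interval speeds equal
#' the specified speeds exactly and the analytic activity value is exact.
#'
#' @param duration_s Total duration (default 300 s, the assay length).
#' @param dt_s Sampling interval (default 0.1 s).
#' @param segments data.frame with `length_s`, `speed_mm_s`, optional
#'   `heading` (radians; `NA` = drawn uniformly). Lengths must tile
#'   `duration_s`.
#' @param immobile_runs Optional data.frame with `start_s`, `length_s`:
#'   stretches whose speed is forced to 0.
#' @param seed RNG seed for the headings.
#' @param fly_id Identifier.
#' @return A `trajectory_spec` object.
#' @export
trajectory_spec <- function(duration_s = 300, dt_s = 0.1,
                            segments = data.frame(length_s = 300,
                                                  speed_mm_s = 3.0,
                                                  heading = NA_real_),
                            immobile_runs = NULL, seed = 1L, fly_id = "fly") {
  stopifnot(duration_s > 0, dt_s > 0)
  if (!"heading" %in% names(segments)) segments$heading <- NA_real_
  if (abs(sum(segments$length_s) - duration_s) > 1e-9)
    stop("segments must tile duration_s")
  mults <- c(segments$length_s,
             if (!is.null(immobile_runs)) c(immobile_runs$start_s,
                                            immobile_runs$length_s))
  if (any(abs(mults / dt_s - round(mults / dt_s)) > 1e-9))
    stop("segment lengths and immobile-run bounds must be multiples of dt_s")
  if (any(segments$speed_mm_s < 0)) stop("speeds must be >= 0")
  structure(list(duration_s = duration_s, dt_s = dt_s, segments = segments,
                 immobile_runs = immobile_runs, seed = as.integer(seed),
                 fly_id = fly_id),
            class = "trajectory_spec")
}

#' Generate a trajectory from its recipe
#'
#' @param spec A [trajectory_spec].
#' @return A `synthetic_trajectory`: list with `trajectory` (a
#'   [trajectory]), `interval_speed_mm_s` (one per sampling interval) and
#'   `dt_s`, from which the analytic activity for any threshold follows via
#'   [analytic_time_above].
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  n_int <- round(spec$duration_s / spec$dt_s)
  seg_n <- round(spec$segments$length_s / spec$dt_s)
  heading <- spec$segments$heading
  heading[is.na(heading)] <- stats::runif(sum(is.na(heading)), 0, 2 * pi)
  sp <- rep(spec$segments$speed_mm_s, seg_n)
  hd <- rep(heading, seg_n)
  if (!is.null(spec$immobile_runs)) {
    for (i in seq_len(nrow(spec$immobile_runs))) {
      a <- round(spec$immobile_runs$start_s[i] / spec$dt_s) + 1L
      b <- a + round(spec$immobile_runs$length_s[i] / spec$dt_s) - 1L
      if (a < 1 || b > n_int) stop("immobile run outside the track")
      sp[a:b] <- 0
    }
  }
  t <- (0:n_int) * spec$dt_s
  x <- c(0, cumsum(sp * spec$dt_s * cos(hd)))
  y <- c(0, cumsum(sp * spec$dt_s * sin(hd)))
  list(trajectory = trajectory(t, x, y, fly_id = spec$fly_id),
       interval_speed_mm_s = sp, dt_s = spec$dt_s)
}

#' Analytic activity time of a synthetic trajectory
#'
#' Ground-truth time above a speed threshold, computed from the recipe's
#' interval speeds rather than from the sampled coordinates.
#'
#' @param gen Output of [generate_trajectory].
#' @param threshold_mm_s Speed threshold.
#' @return Time above threshold in seconds.
#' @export
analytic_time_above <- function(gen, threshold_mm_s) {
  sum(gen$dt_s * (gen$interval_speed_mm_s > threshold_mm_s))
}

#' Write a trajectory as a CSV fixture
#'
#' @param traj A [trajectory] (or the output of [generate_trajectory]).
#' @param path Output CSV path (columns t, x, y).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "trajectory") && !is.null(traj$trajectory))
    traj <- traj$trajectory
  write_table(data.frame(t = traj$t, x = traj$x, y = traj$y), path)
}

#' Generate grouped measurements for statistical testing
#'
#' Independent normal draws with per-group location shifts; all shifts zero
#' gives an exchangeable null for type-I-error calibration.
#'
#' @param k Number of groups.
#' @param n_per_group Observations per group (scalar or length-k).
#' @param shift Per-group location offsets (scalar or length-k; default 0).
#' @param seed RNG seed.
#' @param sd Common standard deviation (default 1).
#' @return A [group_data].
#' @export
generate_groups <- function(k, n_per_group, shift = 0, seed = 1L, sd = 1) {
  stopifnot(k >= 2, all(n_per_group >= 1))
  n <- rep_len(n_per_group, k)
  mu <- rep_len(shift, k)
  set.seed(seed)
  g <- lapply(seq_len(k), function(i) stats::rnorm(n[i], mean = mu[i], sd = sd))
  names(g) <- paste0("group", seq_len(k))
  group_data(g)
}
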