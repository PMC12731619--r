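# Manifest-driven batch orchestration and the CLI backend.
#
# A run is described by a JSON config (schema below) plus CSV manifests, so
# every run is reproducible from text files:
#
# {
#   "seed": 1,
#   "signals": {
#     "azot":  {"probability_threshold": 0.10, "min_size_px": 17},
#     "TUNEL": {"probability_threshold": 0.05, "min_size_px": 17},
#     "hAb42": {"probability_threshold": 0.05, "min_size_px": 18}
#   },
#   "colocalization": [{"a": "azot", "b": "TUNEL", "mode": "partial"}],
#   "image_manifest": "images.csv",        # image_id, signal, mask_path,
#                                          # roi_path [, intensity_path,
#                                          # genotype, diet, timepoint]
#   "trajectory_manifest": "flies.csv",    # fly_id, path [, metadata...]
#   "locomotion": {"speed_threshold_mm_s": 2.7, "immobility_window_s": 60,
#                  "immobility_speed_eps_mm_s": 0.25,
#                  "assay_duration_s": 300},
#   "stats": {"value_column": "area_percent", "group_by": "genotype",
#             "family_by": ["signal"], "adjust": "bonferroni"}
# }
#
# The per-signal defaults are the published workflow's: probability threshold
# 0.1 for the azot reporter, 0.05 for the green channels (TUNEL, amyloid
# antibody); minimum object size 17 px (TUNEL, azot) and 18 px (amyloid).

#' Published default segmentation parameters per signal
#'
#' @return Named list of [segmentation_params].
#' @export
default_signal_params <- function() {
  list(azot  = segmentation_params(0.10, 17L),
       TUNEL = segmentation_params(0.05, 17L),
       hAb42 = segmentation_params(0.05, 18L))
}

.params_from_config <- function(x) {
  segmentation_params(
    probability_threshold = x$probability_threshold %||% 0.05,
    min_size_px = x$min_size_px %||% 17L,
    connectivity = x$connectivity %||% 8L,
    probability_mode = x$probability_mode %||% "pixel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration
#'
#' JSON file with the schema documented in this module; relative manifest
#' paths are resolved against the config file's directory.
#'
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p) || p == "") return(p)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  cfg$base_dir <- base
  for (f in c("image_manifest", "trajectory_manifest"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- resolve(cfg[[f]])
  sig <- list()
  for (nm in names(cfg$signals)) sig[[nm]] <- .params_from_config(cfg$signals[[nm]])
  cfg$signal_params <- if (length(sig) > 0) sig else default_signal_params()
  if (!is.null(cfg$colocalization) && !is.data.frame(cfg$colocalization))
    cfg$colocalization <- as.data.frame(cfg$colocalization,
                                        stringsAsFactors = FALSE)
  lp <- cfg$locomotion
  cfg$locomotion_params <- locomotion_params(
    speed_threshold_mm_s = lp$speed_threshold_mm_s %||% 2.7,
    immobility_window_s = lp$immobility_window_s %||% 60,
    immobility_speed_eps_mm_s = lp$immobility_speed_eps_mm_s %||% 0.25,
    assay_duration_s = lp$assay_duration_s %||% 300,
    median_filter = lp$median_filter %||% FALSE)
  structure(cfg, class = "run_config")
}

.resolve_rel <- function(p, base) {
  ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
}

.log <- function(...) message(sprintf(...))

#' Batch signal quantification
#'
#' For every image in the manifest: rasterize its ROI, segment each listed
#' signal's probability mask with that signal's parameters, compute the
#' ROI-normalized area, then every configured colocalization pair present in
#' the image. Per-image failures are logged and reported via the `failures`
#' attribute; the run continues.
#'
#' @param config A `run_config` (from [read_run_config]) or equivalent list.
#' @return data.frame in the results schema (one row per image x signal plus
#'   one per image x colocalization pair), with attribute `failures`.
#' @export
run_quantification <- function(config) {
  man <- utils::read.csv(config$image_manifest, stringsAsFactors = FALSE)
  need <- c("image_id", "signal", "mask_path", "roi_path")
  if (!all(need %in% names(man)))
    stop("image manifest needs columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(config$image_manifest))
  meta_cols <- setdiff(names(man), c(need, "intensity_path"))
  rows <- list(); failures <- list()
  for (id in unique(man$image_id)) {
    sub <- man[man$image_id == id, , drop = FALSE]
    res <- tryCatch({
      roi_file <- .resolve_rel(sub$roi_path[1], base)
      roi <- read_roi(roi_file)
      maps <- list(); roi_mask <- NULL
      img_rows <- list()
      for (i in seq_len(nrow(sub))) {
        sig <- sub$signal[i]
        pm <- read_raster(.resolve_rel(sub$mask_path[i], base), "probability",
                          channel_name = sig)
        if (is.null(roi_mask)) roi_mask <- roi_to_mask(roi, dim(pm$probs))
        params <- config$signal_params[[sig]] %||% segmentation_params()
        maps[[sig]] <- segment(pm, params)
        sq <- area_fraction(maps[[sig]], roi_mask)
        rec <- quant_record(id, sig, sq$roi_area_px, sq$signal_area_px,
                            params_fingerprint = format(params))
        img_rows[[length(img_rows) + 1L]] <- cbind(rec, sub[i, meta_cols, drop = FALSE])
      }
      cl <- config$colocalization
      if (!is.null(cl) && nrow(cl) > 0) {
        for (i in seq_len(nrow(cl))) {
          a <- cl$a[i]; b <- cl$b[i]
          mode <- if ("mode" %in% names(cl) && !is.na(cl$mode[i])) cl$mode[i] else "partial"
          if (!a %in% names(maps) || !b %in% names(maps)) next
          cq <- colocalize(maps[[a]], maps[[b]], roi_mask, mode = mode)
          rec <- quant_record(id, paste0(a, "+", b), sum(roi_mask),
                              cq$overlap_area_px,
                              partner_signal = b,
                              overlap_area_px = cq$overlap_area_px,
                              overlap_percent = cq$overlap_percent_of_roi,
                              params_fingerprint = mode)
          img_rows[[length(img_rows) + 1L]] <-
            cbind(rec, sub[1, meta_cols, drop = FALSE])
        }
      }
      do.call(rbind, img_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      .log("quantification failed for image %s: %s", id, conditionMessage(res))
      failures[[length(failures) + 1L]] <- data.frame(image_id = id,
                                                      error = conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    quant_record("x", "x", 1, 0)[0, ]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures) > 0) do.call(rbind, failures) else
    data.frame(image_id = character(0), error = character(0))
  out
}

#' Batch locomotion analysis
#'
#' One activity row per fly in the trajectory manifest. Flies excluded by
#' the immobility rule stay in the table with `excluded = TRUE` (downstream
#' statistics drop them); unreadable trajectory files are logged and marked
#' `failed = TRUE`.
#'
#' @param config A `run_config`.
#' @return data.frame with per-fly activity results and manifest metadata.
#' @export
run_locomotion <- function(config) {
  man <- utils::read.csv(config$trajectory_manifest, stringsAsFactors = FALSE)
  if (!all(c("fly_id", "path") %in% names(man)))
    stop("trajectory manifest needs columns: fly_id, path")
  base <- dirname(normalizePath(config$trajectory_manifest))
  meta_cols <- setdiff(names(man), c("fly_id", "path"))
  params <- config$locomotion_params %||% locomotion_params()
  rows <- list()
  for (i in seq_len(nrow(man))) {
    row <- tryCatch({
      traj <- read_trajectory(.resolve_rel(man$path[i], base),
                              fly_id = man$fly_id[i])
      act <- activity_above_threshold(traj, params)
      data.frame(fly_id = man$fly_id[i],
                 total_time_s = act$total_time_s,
                 time_above_s = act$time_above_s,
                 fraction_above = act$fraction_above,
                 excluded = act$excluded,
                 exclusion_reason = act$exclusion_reason,
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      .log("locomotion failed for fly %s: %s", man$fly_id[i],
           conditionMessage(e))
      data.frame(fly_id = man$fly_id[i], total_time_s = NA_real_,
                 time_above_s = NA_real_, fraction_above = NA_real_,
                 excluded = NA, exclusion_reason = conditionMessage(e),
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    rows[[i]] <- cbind(row, man[i, meta_cols, drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grouped statistics over a results table
#'
#' Splits the table into families (by `family_by` columns), groups each
#' family by `group_by`, and reports the Kruskal-Wallis omnibus test, Dunn's
#' pairwise post hoc comparisons and per-group median 95% CIs, with
#' significance stars at the published thresholds. Rows flagged
#' `excluded = TRUE` or `failed = TRUE` are dropped first. Families with
#' fewer than 2 non-empty groups (or degenerate, all-identical data) are
#' skipped with a warning.
#'
#' @param config A `run_config` (its `stats` entry supplies `value_column`,
#'   `group_by`, `family_by`, `adjust`).
#' @param table A results data.frame (quantification or locomotion output).
#' @return Tidy data.frame: one row per omnibus test, Dunn pair, and group
#'   median.
#' @export
run_stats <- function(config, table) {
  sc <- config$stats
  value_col <- sc$value_column %||% "area_percent"
  group_by <- sc$group_by %||% "genotype"
  family_by <- sc$family_by
  adjust <- sc$adjust %||% "bonferroni"
  df <- table
  if ("excluded" %in% names(df)) df <- df[!(df$excluded %in% TRUE), , drop = FALSE]
  if ("failed" %in% names(df)) df <- df[!(df$failed %in% TRUE), , drop = FALSE]
  if (!value_col %in% names(df)) stop("value column not in table: ", value_col)
  if (!group_by %in% names(df)) stop("group column not in table: ", group_by)
  fam_key <- if (is.null(family_by)) rep("all", nrow(df)) else
    do.call(paste, c(df[family_by], sep = "/"))
  out <- list()
  for (fam in unique(fam_key)) {
    sub <- df[fam_key == fam, , drop = FALSE]
    groups <- split(sub[[value_col]], sub[[group_by]])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) {
      warning("family '", fam, "' has < 2 groups; skipped")
      next
    }
    res <- tryCatch({
      kw <- kruskal_wallis(group_data(groups))
      dn <- dunn_posthoc(group_data(groups), adjust = adjust)
      omni <- data.frame(family = fam, test = "kruskal_wallis",
                         group1 = NA_character_, group2 = NA_character_,
                         n1 = NA_integer_, n2 = NA_integer_,
                         statistic = kw$H, df = kw$df, p_value = kw$p_value,
                         p_adjusted = NA_real_,
                         stars = significance_stars(kw$p_value),
                         median = NA_real_, ci_lower = NA_real_,
                         ci_upper = NA_real_, stringsAsFactors = FALSE)
      pair_rows <- data.frame(family = fam, test = "dunn",
                              group1 = dn$group1, group2 = dn$group2,
                              n1 = lengths(groups)[dn$group1],
                              n2 = lengths(groups)[dn$group2],
                              statistic = dn$z, df = NA_integer_,
                              p_value = dn$p_raw, p_adjusted = dn$p_adjusted,
                              stars = significance_stars(dn$p_adjusted),
                              median = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_, stringsAsFactors = FALSE)
      med_rows <- do.call(rbind, lapply(names(groups), function(g) {
        ci <- median_ci(groups[[g]], level = 0.95)
        data.frame(family = fam, test = "median_ci", group1 = g,
                   group2 = NA_character_, n1 = length(groups[[g]]),
                   n2 = NA_integer_, statistic = NA_real_, df = NA_integer_,
                   p_value = NA_real_, p_adjusted = NA_real_,
                   stars = NA_character_, median = ci$median,
                   ci_lower = ci$lower, ci_upper = ci$upper,
                   stringsAsFactors = FALSE)
      }))
      rbind(omni, pair_rows, med_rows)
    }, error = function(e) {
      warning("family '", fam, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(family = character(0), test = character(0))
  rownames(res) <- NULL
  res
}

#' Method-agreement validation harness
#'
#' For every manifest row carrying an `intensity_path`, segments the raw
#' intensity image at `intensity_threshold` (the Fiji-style reference arm)
#' and the probability mask with the configured signal parameters (the
#' automated arm), and reports the object-matching counts within the ROI.
#'
#' @param config A `run_config`. `config$validation$intensity_threshold`
#'   (default 50) sets the reference binarization cutoff.
#' @return data.frame: one row per image x signal with agreement counts.
#' @export
run_validation <- function(config) {
  man <- utils::read.csv(config$image_manifest, stringsAsFactors = FALSE)
  if (!"intensity_path" %in% names(man))
    stop("validation needs an intensity_path column in the image manifest")
  base <- dirname(normalizePath(config$image_manifest))
  thr <- config$validation$intensity_threshold %||% 50
  rows <- list()
  for (i in seq_len(nrow(man))) {
    if (is.na(man$intensity_path[i]) || man$intensity_path[i] == "") next
    sig <- man$signal[i]
    params <- config$signal_params[[sig]] %||% segmentation_params()
    img <- read_raster(.resolve_rel(man$intensity_path[i], base), "intensity")
    pm <- read_raster(.resolve_rel(man$mask_path[i], base), "probability")
    roi <- roi_to_mask(read_roi(.resolve_rel(man$roi_path[i], base)),
                       dim(pm$probs))
    ref <- intensity_segment_reference(img, thr, params$min_size_px,
                                       params$connectivity)
    auto <- segment(pm, params)
    ma <- method_agreement(ref, auto, roi)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = man$image_id[i], signal = sig,
      n_objects_reference = ma$n_objects_reference,
      n_objects_automated = ma$n_objects_automated,
      n_matched = ma$n_matched,
      n_only_reference = ma$n_only_reference,
      n_only_automated = ma$n_only_automated, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a self-contained fixture set with manifests and config
#'
#' Writes `n_images` synthetic two-channel scenes (TIFF masks + intensity
#' images + `.roi` files), `n_flies` trajectory CSVs (one fly carrying a 61 s
#' immobile run so the exclusion path is exercised), the two manifests, and a
#' ready-to-run JSON config. Everything is derived from `seed`, so two calls
#' with the same seed produce identical trees.
#'
#' @param dir Output directory.
#' @param n_images,n_flies Fixture counts.
#' @param overlap_fraction Engineered channel overlap.
#' @param seed Master seed.
#' @return Path of the written config file, invisibly.
#' @export
simulate_fixture_set <- function(dir, n_images = 3L, n_flies = 6L,
                                 overlap_fraction = 0.5, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_rows <- list()
  for (i in seq_len(n_images)) {
    id <- sprintf("img%02d", i)
    sc <- generate_scene(scene_spec(
      shape = c(96L, 96L),
      channels = list(
        list(name = "azot", n_objects = 6L, radius = c(3, 5), prob = 1, intensity = 200),
        list(name = "TUNEL", n_objects = 6L, radius = c(3, 5), prob = 1, intensity = 180)),
      overlap_fraction = overlap_fraction,
      seed = seed * 1000L + i))
    p <- write_scene_fixtures(sc, dir, image_id = id)
    geno <- if (i %% 2 == 0) "AD" else "healthy"
    for (nm in c("azot", "TUNEL")) {
      img_rows[[length(img_rows) + 1L]] <- data.frame(
        image_id = id, signal = nm,
        mask_path = basename(p[[paste0("mask_", nm)]]),
        roi_path = basename(p$roi),
        intensity_path = basename(p[[paste0("intensity_", nm)]]),
        genotype = geno, stringsAsFactors = FALSE)
    }
  }
  img_man <- file.path(dir, "images.csv")
  utils::write.csv(do.call(rbind, img_rows), img_man, row.names = FALSE)

  fly_rows <- list()
  for (i in seq_len(n_flies)) {
    fid <- sprintf("fly%02d", i)
    spd <- c(3.5, 1.0, 4.0, 0.6, 2.0, 5.0)[(i - 1) %% 6 + 1]
    runs <- if (i == 1) data.frame(start_s = 100, length_s = 61) else NULL
    ts <- trajectory_spec(duration_s = 300, dt_s = 0.1,
                          segments = data.frame(length_s = c(150, 150),
                                                speed_mm_s = c(spd, spd / 2),
                                                heading = NA_real_),
                          immobile_runs = runs, seed = seed * 500L + i,
                          fly_id = fid)
    gen <- generate_trajectory(ts)
    fp <- file.path(dir, paste0(fid, ".csv"))
    write_trajectory(gen, fp)
    fly_rows[[i]] <- data.frame(fly_id = fid, path = basename(fp),
                                genotype = if (i %% 2 == 0) "AD" else "healthy",
                                stringsAsFactors = FALSE)
  }
  fly_man <- file.path(dir, "flies.csv")
  utils::write.csv(do.call(rbind, fly_rows), fly_man, row.names = FALSE)

  cfg <- list(
    seed = seed,
    signals = list(azot = list(probability_threshold = 0.10, min_size_px = 17),
                   TUNEL = list(probability_threshold = 0.05, min_size_px = 17)),
    colocalization = list(list(a = "azot", b = "TUNEL", mode = "partial")),
    image_manifest = "images.csv",
    trajectory_manifest = "flies.csv",
    locomotion = list(speed_threshold_mm_s = 2.7, immobility_window_s = 60,
                      immobility_speed_eps_mm_s = 0.25, assay_duration_s = 300),
    stats = list(value_column = "area_percent", group_by = "genotype",
                 family_by = list("signal"), adjust = "bonferroni"),
    validation = list(intensity_threshold = 50))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(cfg_path)
}
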