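# Activity Speed Threshold metric and immobility QC from centroid tracks.
#
# The assay records a single fly walking an arena for 5 minutes; the activity
# score is the total time its speed exceeds 2.7 mm/s, and flies immobile for
# more than 1 minute are excluded.

#' Centroid trajectory
#'
#' @param t Timestamps in seconds, strictly increasing, length `>= 2`.
#' @param x,y Centroid coordinates in mm, finite.
#' @param fly_id Identifier.
#' @return A `trajectory` object (data.frame with attribute `fly_id`).
#' @export
trajectory <- function(t, x, y, fly_id = "fly") {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2) stop("trajectory needs >= 2 samples")
  if (anyNA(c(t, x, y)) || any(!is.finite(c(t, x, y))))
    stop("trajectory samples must be finite")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  structure(data.frame(t = t, x = x, y = y),
            fly_id = fly_id, class = c("trajectory", "data.frame"))
}

#' Locomotion analysis parameters
#'
#' @param speed_threshold_mm_s Activity speed threshold (default 2.7 mm/s).
#' @param immobility_window_s Longest tolerated immobile stretch (default
#'   60 s; strictly longer stretches exclude the fly).
#' @param immobility_speed_eps_mm_s Speed floor below which an interval
#'   counts as immobile (default 0.25 mm/s; real centroids jitter, so exact
#'   zero would never trigger).
#' @param assay_duration_s Nominal assay length (default 300 s).
#' @param median_filter Apply a centered 3-sample median filter to x and y
#'   before computing speeds (default off).
#' @return A `locomotion_params` object.
#' @export
locomotion_params <- function(speed_threshold_mm_s = 2.7,
                              immobility_window_s = 60,
                              immobility_speed_eps_mm_s = 0.25,
                              assay_duration_s = 300,
                              median_filter = FALSE) {
  vals <- c(speed_threshold_mm_s, immobility_window_s,
            immobility_speed_eps_mm_s, assay_duration_s)
  if (any(vals <= 0)) stop("all locomotion parameters must be positive")
  if (immobility_window_s > assay_duration_s)
    stop("immobility_window_s must not exceed assay_duration_s")
  structure(list(speed_threshold_mm_s = speed_threshold_mm_s,
                 immobility_window_s = immobility_window_s,
                 immobility_speed_eps_mm_s = immobility_speed_eps_mm_s,
                 assay_duration_s = assay_duration_s,
                 median_filter = isTRUE(median_filter)),
            class = "locomotion_params")
}

#' Centered 3-sample median filter of a trajectory
#'
#' Smooths x and y independently; endpoints are kept as-is.
#'
#' @param traj A [trajectory].
#' @return A smoothed [trajectory].
#' @export
smooth_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  med3 <- function(v) {
    n <- length(v)
    if (n < 3) return(v)
    out <- v
    out[2:(n - 1)] <- vapply(2:(n - 1), function(i) median(v[(i - 1):(i + 1)]),
                             numeric(1))
    out
  }
  trajectory(traj$t, med3(traj$x), med3(traj$y), fly_id = attr(traj, "fly_id"))
}

#' Per-interval speeds of a trajectory
#'
#' Speed over each consecutive sample pair: Euclidean displacement divided by
#' the (possibly nonuniform) time step.
#'
#' @param traj A [trajectory].
#' @return data.frame with one row per interval: `dt` (s), `speed` (mm/s).
#' @export
interval_speeds <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- diff(traj$t)
  if (any(dt == 0)) stop("duplicate timestamps")
  disp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  data.frame(dt = dt, speed = disp / dt)
}

#' Immobility quality-control check
#'
#' A fly is excluded iff some contiguous run of intervals, each with speed
#' below `immobility_speed_eps_mm_s`, spans strictly more than
#' `immobility_window_s` seconds.
#'
#' @param traj A [trajectory].
#' @param params A [locomotion_params].
#' @return list(`excluded` = logical, `reason` = text, `longest_immobile_s`).
#' @export
qc_immobility <- function(traj, params = locomotion_params()) {
  iv <- interval_speeds(traj)
  immobile <- iv$speed < params$immobility_speed_eps_mm_s
  longest <- 0
  run <- 0
  for (i in seq_along(immobile)) {
    run <- if (immobile[i]) run + iv$dt[i] else 0
    if (run > longest) longest <- run
  }
  excluded <- longest > params$immobility_window_s
  list(excluded = excluded,
       reason = if (excluded)
         sprintf("immobile for %.1f s (> %g s)", longest,
                 params$immobility_window_s) else "",
       longest_immobile_s = longest)
}

#' Activity above the speed threshold
#'
#' Total time the fly's interval speed is strictly above the threshold
#' (2.7 mm/s by default); an interval exactly at the threshold contributes
#' nothing. Also runs the immobility exclusion check.
#'
#' @param traj A [trajectory].
#' @param params A [locomotion_params].
#' @return An `activity_result`: list with `time_above_s`, `fraction_above`,
#'   `total_time_s`, `excluded`, `exclusion_reason`.
#' @export
activity_above_threshold <- function(traj, params = locomotion_params()) {
  stopifnot(inherits(params, "locomotion_params"))
  if (params$median_filter) traj <- smooth_trajectory(traj)
  iv <- interval_speeds(traj)
  total <- traj$t[nrow(traj)] - traj$t[1]
  above <- iv$speed > params$speed_threshold_mm_s
  time_above <- sum(iv$dt[above])
  qc <- qc_immobility(traj, params)
  structure(list(time_above_s = time_above,
                 fraction_above = time_above / total,
                 total_time_s = total,
                 excluded = qc$excluded,
                 exclusion_reason = qc$reason),
            class = "activity_result")
}

#' Read a trajectory from delimited text
#'
#' Expects a header with columns `t`, `x`, `y` (seconds, mm, mm).
#'
#' @param path CSV path.
#' @param fly_id Identifier (default: file name stem).
#' @return A [trajectory].
#' @export
read_trajectory <- function(path, fly_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns t,x,y: ", path)
  if (is.null(fly_id)) fly_id <- sub("\\.[^.]*$", "", basename(path))
  trajectory(df$t, df$x, df$y, fly_id = fly_id)
}
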