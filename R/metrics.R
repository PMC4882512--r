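#' Instantaneous speeds of a track
#'
#' Frame-to-frame Euclidean displacement on the projected 2D coordinates
#' divided by the frame interval.
#'
#' @param track Data frame with columns `x_um`, `y_um` ordered by frame
#'   (at least 2 points, no gaps -- apply [filter_complete()] first).
#' @param frame_interval Frame interval (s).
#' @return Numeric vector of speeds (um/s), length `nrow(track) - 1`.
#' @export
instantaneous_speeds <- function(track, frame_interval) {
  if (nrow(track) < 2)
    stop("track needs at least 2 points", call. = FALSE)
  sqrt(diff(track$x_um)^2 + diff(track$y_um)^2) / frame_interval
}

#' Mean speed of a track
#'
#' Arithmetic mean of the instantaneous speeds, equal to total path length
#' divided by total observation time.
#'
#' @inheritParams instantaneous_speeds
#' @return Mean speed (um/s).
#' @export
mean_speed <- function(track, frame_interval) {
  mean(instantaneous_speeds(track, frame_interval))
}

#' Detect saltatory events in a speed series
#'
#' A saltatory event is a maximal contiguous run of instantaneous speeds
#' strictly exceeding the saltatory threshold (0.1 um/s by default).
#'
#' @param speeds Numeric speed series (um/s), as from
#'   [instantaneous_speeds()].
#' @param thresholds A [motion_thresholds()] object.
#' @param frame_interval Frame interval (s).
#' @return Data frame with one row per event: `start_s` (time of the first
#'   supra-threshold displacement), `duration_s` (run length times the
#'   frame interval) and `peak_um_s`, ordered by start time.
#' @export
detect_saltatory_events <- function(speeds,
                                    thresholds = motion_thresholds(),
                                    frame_interval = 2) {
  if (!length(speeds)) stop("empty speed series", call. = FALSE)
  above <- speeds > thresholds$saltatory_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values)
  data.frame(
    start_s = (starts[ev] - 1) * frame_interval,
    duration_s = r$lengths[ev] * frame_interval,
    peak_um_s = vapply(ev, function(i)
      max(speeds[starts[i]:ends[i]]), numeric(1)))
}

#' Fast-mover classification
#'
#' A track is a fast mover iff its mean speed strictly exceeds the fast
#' threshold (0.14 um/s by default, the 90th percentile of the control
#' population); a track exactly at the threshold is not fast.
#'
#' @param mean_speeds Numeric vector of per-track mean speeds (um/s).
#' @param thresholds A [motion_thresholds()] object.
#' @return Logical vector.
#' @export
classify_fast <- function(mean_speeds, thresholds = motion_thresholds()) {
  mean_speeds > thresholds$fast_threshold
}

#' Calibrate the fast-mover threshold from a control population
#'
#' Returns the 90th percentile of control per-track mean speeds under the
#' package-wide check-loss midpoint quantile convention
#' ([check_quantile()]), as a data-driven alternative to the fixed 0.14
#' um/s default.
#'
#' @param control_speeds Per-track mean speeds of the control population
#'   (at least 10 values).
#' @param tau Quantile level (default 0.9: the fastest 10%).
#' @return Threshold speed (um/s).
#' @export
calibrate_fast_threshold <- function(control_speeds, tau = 0.9) {
  if (length(control_speeds) < 10)
    stop("need at least 10 control mean speeds", call. = FALSE)
  check_quantile(control_speeds, tau)
}

#' Direction of net movement along the process axis
#'
#' Classifies a track as anterograde (net displacement away from the soma
#' above `+epsilon`), retrograde (below `-epsilon`) or stationary. The
#' guard `epsilon` absorbs localization noise around zero net displacement.
#'
#' @param track Data frame with an `s_um` column (position on the process
#'   axis, 0 at the soma).
#' @param soma_s Position of the soma end on the axis (um); must lie within
#'   the span conventions of the axis (non-negative).
#' @param epsilon Stationary guard (um).
#' @return One of `"anterograde"`, `"retrograde"`, `"stationary"`.
#' @export
classify_direction <- function(track, soma_s = 0, epsilon = 0.2) {
  if (soma_s < 0) stop("soma position outside process", call. = FALSE)
  if (!"s_um" %in% names(track))
    stop("track lacks an s_um axis coordinate", call. = FALSE)
  # the axis is oriented away from the soma, so + is anterograde
  net <- track$s_um[nrow(track)] - track$s_um[1]
  if (net > epsilon) "anterograde"
  else if (net < -epsilon) "retrograde"
  else "stationary"
}

#' Count organelles within a window along the process
#'
#' Counts positions falling in the half-open window `[start, end)` on the
#' process axis (default 20--140 um from the soma).
#'
#' @param positions_s Positions on the process axis (um).
#' @param thresholds A [motion_thresholds()] object carrying
#'   `density_window`.
#' @return Integer count.
#' @export
count_in_window <- function(positions_s,
                            thresholds = motion_thresholds()) {
  w <- thresholds$density_window
  sum(positions_s >= w[1] & positions_s < w[2])
}

#' Per-track motion summaries
#'
#' Computes for every track of a (complete) track set: mean speed, path
#' length, signed net axial displacement, saltatory event count and
#' durations, fast-mover flag and direction.
#'
#' @param ts A `track_set` (complete tracks; see [filter_complete()]).
#' @param thresholds A [motion_thresholds()] object.
#' @return Data frame with one row per track: `track_id`,
#'   `mean_speed_um_s`, `path_length_um`, `net_displacement_um`,
#'   `n_events`, `mean_event_duration_s`, `is_fast`, `direction`.
#' @export
summarize_tracks <- function(ts, thresholds = motion_thresholds()) {
  dt <- ts$frame_interval
  rows <- lapply(split_tracks(ts), function(d) {
    sp <- instantaneous_speeds(d, dt)
    ev <- detect_saltatory_events(sp, thresholds, dt)
    has_s <- "s_um" %in% names(d)
    data.frame(
      track_id = d$track_id[1],
      mean_speed_um_s = mean(sp),
      path_length_um = sum(sp) * dt,
      net_displacement_um = if (has_s)
        d$s_um[nrow(d)] - d$s_um[1] else NA_real_,
      n_events = nrow(ev),
      mean_event_duration_s = if (nrow(ev)) mean(ev$duration_s) else 0,
      is_fast = mean(sp) > thresholds$fast_threshold,
      direction = if (has_s)
        classify_direction(d, epsilon = thresholds$direction_epsilon)
        else NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
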