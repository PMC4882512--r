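#' Simulate ground-truth organelle tracks
#'
#' Draws `n_tracks` organelles from the three-class motion model and returns
#' their observed positions at every frame. The process axis `s` runs from
#' the soma (`s = 0`) distally; observed 2D coordinates are `x = s` plus
#' localization noise and a transverse coordinate `y` that is pure
#' localization noise (the process is quasi-1D). Moving organelles are
#' started at a uniformly random position chosen so that the whole
#' (noise-free) excursion fits inside `[0, process_length]` -- excursions of
#' tens of um are short relative to 150--300 um processes, and hard clipping
#' would silently convert transport into immobility at the boundary.
#'
#' Randomness is organised as one deterministic substream per track derived
#' from the master seed, so adding tracks never perturbs earlier tracks.
#'
#' @param params A [motion_params()] object.
#' @param imaging An [imaging_params()] object (frame interval and count).
#' @param n_tracks Number of tracks to simulate (>= 1).
#' @param seed Integer master seed.
#' @param class_assignment `"balanced"` (default) interleaves classes (and
#'   the anterograde/retrograde direction of fast tracks) by a
#'   deterministic quota sequence so that every prefix of tracks carries
#'   the class fractions as exactly as integer counts allow -- recovered
#'   class fractions then measure the analysis pipeline rather than
#'   multinomial sampling luck. `"multinomial"` draws each class (and each
#'   direction) independently.
#' @return A `track_set` (see [track_set()]) with `provenance =
#'   "ground_truth"`; its `meta` component records the generative class,
#'   direction and per-run duty cycle of each track.
#' @export
simulate_tracks <- function(params, imaging, n_tracks, seed,
                            class_assignment = c("balanced",
                                                 "multinomial")) {
  validate_motion_params(params)
  class_assignment <- match.arg(class_assignment)
  if (n_tracks < 1) stop("n_tracks must be at least 1", call. = FALSE)
  n_frames <- imaging$n_frames
  dt <- imaging$frame_interval
  t_frames <- (seq_len(n_frames) - 1) * dt
  fracs <- c(fast = params$frac_fast, slow = params$frac_slow,
             immobile = params$frac_immobile)
  balanced <- NULL
  balanced_dir <- NULL
  if (class_assignment == "balanced") {
    balanced <- quota_classes(fracs, n_tracks)
    fast_idx <- which(balanced == "fast")
    dirs <- quota_classes(c(anterograde = params$p_anterograde,
                            retrograde = 1 - params$p_anterograde),
                          length(fast_idx))
    balanced_dir <- rep(NA_character_, n_tracks)
    balanced_dir[fast_idx] <- dirs
  }

  per_track <- vector("list", n_tracks)
  meta <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    with_track_seed(seed, k, {
      cls <- if (class_assignment == "balanced") balanced[k]
        else sample(names(fracs), 1, prob = fracs)
      sim <- switch(cls,
        immobile = sim_immobile(n_frames),
        slow = sim_slow(n_frames, params$slow_step_sd,
                        params$slow_step_sd_spread),
        fast = sim_fast(t_frames, params, forced_dir = balanced_dir[k]))
      # place so the noise-free excursion stays inside the process
      lo <- -min(sim$s); hi <- params$process_length - max(sim$s)
      s0 <- if (hi >= lo) stats::runif(1, lo, hi) else params$process_length / 2
      s_true <- pmin(pmax(sim$s + s0, 0), params$process_length)
      s_obs <- s_true + stats::rnorm(n_frames, 0, params$loc_noise_sd)
      y_obs <- stats::rnorm(n_frames, 0, params$loc_noise_sd)
      per_track[[k]] <- data.frame(
        track_id = k, frame = seq_len(n_frames) - 1L,
        s_um = s_obs, x_um = s_obs, y_um = y_obs)
      meta[[k]] <- data.frame(
        track_id = k, class = cls,
        direction = if (cls == "fast") sim$direction else "none",
        duty = sim$duty)
    })
  }
  track_set(do.call(rbind, per_track),
            frame_interval = dt, n_frames = n_frames,
            provenance = "ground_truth",
            meta = do.call(rbind, meta))
}

# Evaluate `expr` under a deterministic per-track RNG substream, restoring
# the caller's RNG state afterwards.
with_track_seed <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
  eval.parent(substitute(expr))
}

# Deterministic largest-deficit quota sequence: after any prefix of k
# tracks, each class count is within 1 of k times its fraction, and the
# sequence for k tracks is a prefix of the sequence for any larger n.
quota_classes <- function(fracs, n) {
  counts <- numeric(length(fracs))
  out <- character(n)
  for (k in seq_len(n)) {
    deficit <- k * fracs - counts
    i <- which.max(deficit)
    out[k] <- names(fracs)[i]
    counts[i] <- counts[i] + 1
  }
  out
}

sim_immobile <- function(n_frames) {
  list(s = rep(0, n_frames), duty = 0)
}

sim_slow <- function(n_frames, step_sd, spread = 0) {
  sd_i <- step_sd * exp(stats::rnorm(1, 0, spread))   # per-organelle motility
  list(s = c(0, cumsum(stats::rnorm(n_frames - 1, 0, sd_i))), duty = 0)
}

# Alternating exponential runs and pauses; per-run speed truncated normal
# (>= 0); a single direction per organelle.
sim_fast <- function(t_frames, params, forced_dir = NULL) {
  total <- max(t_frames)
  dir <- if (!is.null(forced_dir) && !is.na(forced_dir)) {
    if (forced_dir == "anterograde") 1 else -1
  } else if (stats::runif(1) < params$p_anterograde) 1 else -1
  duty_mean <- params$fast_run_duration_mean /
    (params$fast_run_duration_mean + params$fast_pause_duration_mean)
  in_run <- stats::runif(1) < duty_mean
  t_break <- 0; s_break <- 0
  breaks_t <- 0; breaks_s <- 0
  run_time <- 0
  while (t_break < total) {
    dur <- stats::rexp(1, 1 / (if (in_run) params$fast_run_duration_mean
                               else params$fast_pause_duration_mean))
    dur <- min(dur, total - t_break + 1e-9)
    v <- if (in_run) {
      sp <- stats::rnorm(1, params$fast_run_speed_mean,
                         params$fast_run_speed_sd)
      max(sp, 0) * dir
    } else 0
    if (in_run) run_time <- run_time + dur
    t_break <- t_break + dur
    s_break <- s_break + v * dur
    breaks_t <- c(breaks_t, t_break)
    breaks_s <- c(breaks_s, s_break)
    in_run <- !in_run
  }
  s <- stats::approx(breaks_t, breaks_s, xout = t_frames, rule = 2)$y
  list(s = s, direction = if (dir > 0) "anterograde" else "retrograde",
       duty = run_time / total)
}

#' Track-set container
#'
#' A `track_set` bundles a long-format table of track points with its
#' acquisition metadata. The table has columns `track_id`, `frame`
#' (0-based), `x_um`, `y_um` and optionally `s_um` (coordinate on the
#' process axis).
#'
#' @param tracks Data frame of track points.
#' @param frame_interval Frame interval (s).
#' @param n_frames Total number of frames in the movie.
#' @param provenance `"ground_truth"` or `"recovered"`.
#' @param meta Optional per-track metadata data frame (keyed by `track_id`).
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval, n_frames,
                      provenance = c("ground_truth", "recovered"),
                      meta = NULL) {
  provenance <- match.arg(provenance)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tracks)) {
    if (any(tracks$frame < 0) || any(tracks$frame > n_frames - 1))
      stop("frame indices must lie in [0, n_frames - 1]", call. = FALSE)
    ord <- order(tracks$track_id, tracks$frame)
    tracks <- tracks[ord, , drop = FALSE]
    rownames(tracks) <- NULL
    dup <- stats::ave(tracks$frame, tracks$track_id,
                      FUN = function(f) c(1, diff(f)))
    if (any(dup <= 0))
      stop("frames within a track must be strictly increasing",
           call. = FALSE)
  }
  structure(list(tracks = tracks,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 provenance = provenance,
                 meta = meta),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set (%s): %d tracks, %d frames @ %.3g s\n",
              x$provenance, length(unique(x$tracks$track_id)),
              x$n_frames, x$frame_interval))
  invisible(x)
}

#' Split a track-set into per-track data frames
#'
#' @param ts A `track_set`.
#' @return A named list of data frames, one per track, ordered by frame.
#' @export
split_tracks <- function(ts) {
  split(ts$tracks, ts$tracks$track_id)
}
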