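#' Detect, link, filter and summarise one movie
#'
#' The analysis applied to a real (or rendered) movie: per-frame
#' maximum-intensity projection and spot detection, optimal-assignment
#' linking, the completeness filter, and per-track motion summaries.
#'
#' @param movie A `movie` array with calibration attributes.
#' @param detection A [detection_params()] object.
#' @param linking A [linking_params()] object.
#' @param thresholds A [motion_thresholds()] object.
#' @param layout Optional lane layout (from [layout_tracks()]) used to
#'   recover process-axis coordinates for synthetic benchmarks.
#' @return List with `detections`, `tracks` (complete tracks only) and
#'   `summaries`.
#' @export
analyze_movie <- function(movie, detection = detection_params(),
                          linking = linking_params(),
                          thresholds = motion_thresholds(),
                          layout = NULL) {
  det <- detect_movie(movie, detection)
  ts <- link_tracks(det, linking, n_frames = dim(movie)[1],
                    frame_interval = attr(movie, "frame_interval_s"))
  ts <- filter_complete(ts, quiet = TRUE)
  if (!is.null(layout)) ts <- recover_s_coordinates(ts, layout)
  list(detections = det, tracks = ts,
       summaries = if (nrow(ts$tracks)) summarize_tracks(ts, thresholds)
                   else NULL)
}

#' Simulate a condition and recover it through the full imaging pipeline
#'
#' For each synthetic cell line: simulate ground-truth tracks, lay them
#' out in lanes, render fluorescence movies in chunks, then detect, link,
#' filter and summarise the recovered tracks. Lane bookkeeping maps each
#' recovered track back to its ground-truth organelle, so recovered and
#' generative classes can be compared directly.
#'
#' @param params A [motion_params()] object or preset name
#'   (see [condition_preset()]).
#' @param n_lines Number of synthetic cell lines.
#' @param tracks_per_line Organelles per line.
#' @param seed Master seed.
#' @param imaging,detection,linking,thresholds Parameter objects.
#' @param chunk_size Organelles rendered per movie (each in its own lane).
#' @param ground_truth_only Skip rendering/detection and summarise the
#'   ground-truth tracks directly (fast; used for generator-level checks).
#' @return List with `summaries` (per-track data frame incl. `line` and,
#'   where matched, the generative `true_class`/`true_direction`) and
#'   `params`.
#' @export
simulate_and_recover <- function(params, n_lines = 5,
                                 tracks_per_line = 400, seed = 1,
                                 imaging = imaging_params(),
                                 detection = detection_params(),
                                 linking = linking_params(),
                                 thresholds = motion_thresholds(),
                                 chunk_size = 24,
                                 ground_truth_only = FALSE) {
  if (is.character(params)) params <- condition_preset(params)
  all_sum <- vector("list", n_lines)
  for (line in seq_len(n_lines)) {
    line_seed <- (seed * 1009 + line * 9973) %% 2147483647
    ts <- simulate_tracks(params, imaging, tracks_per_line, line_seed)
    if (ground_truth_only) {
      sm <- summarize_tracks(ts, thresholds)
      sm$true_class <- ts$meta$class[match(sm$track_id,
                                           ts$meta$track_id)]
      sm$true_direction <- ts$meta$direction[match(sm$track_id,
                                                   ts$meta$track_id)]
    } else {
      sm <- recover_line(ts, params, imaging, detection, linking,
                         thresholds, chunk_size, line_seed)
    }
    sm$line <- sprintf("L%02d", line)
    all_sum[[line]] <- sm
  }
  out <- do.call(rbind, all_sum)
  rownames(out) <- NULL
  list(summaries = out, params = params)
}

# Render one line's tracks in chunks of lanes and recover them.
recover_line <- function(ts, params, imaging, detection, linking,
                         thresholds, chunk_size, seed) {
  tr <- ts$tracks
  ids <- unique(tr$track_id)
  spans <- vapply(split(tr$s_um, tr$track_id), function(s) diff(range(s)),
                  numeric(1))[as.character(ids)]
  ids <- ids[order(spans)]     # group similar excursions: compact fields
  chunks <- split(ids, ceiling(seq_along(ids) / chunk_size))
  lane_spacing <- max(3, 1.2 * linking$max_link_distance)
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    sub <- ts
    sub$tracks <- tr[tr$track_id %in% chunks[[ci]], , drop = FALSE]
    lay <- layout_tracks(sub, lane_spacing = lane_spacing)
    mov <- render_movie(lay$track_set, imaging,
                        seed = seed + ci,
                        width_um = lay$width_um,
                        height_um = lay$height_um)
    res <- analyze_movie(mov, detection, linking, thresholds,
                         layout = lay$layout)
    sm <- res$summaries
    if (is.null(sm)) next
    # map recovered tracks to ground truth via their lane
    rec_tr <- res$tracks$tracks
    med_y <- tapply(rec_tr$y_um, rec_tr$track_id, stats::median)
    lane_of <- vapply(med_y, function(y)
      which.min(abs(lay$layout$y_center_um - y)), integer(1))
    truth_id <- lay$layout$track_id[lane_of]
    idx <- match(sm$track_id, as.integer(names(med_y)))
    sm$truth_track_id <- truth_id[idx]
    mi <- match(sm$truth_track_id, ts$meta$track_id)
    sm$true_class <- ts$meta$class[mi]
    sm$true_direction <- ts$meta$direction[mi]
    out[[ci]] <- sm
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("no complete tracks recovered", call. = FALSE)
  res
}

#' Group-level statistics from per-track summaries
#'
#' Computes the population-level outputs of a two-group comparison:
#' per-line mean speeds and fast-mover percentages (the cell line is the
#' unit of analysis), the pooled speed percentiles, the quantile group
#' contrast, the line-level t statistic for mean speed, and the
#' anterograde/retrograde breakdown of fast movers.
#'
#' @param control,patient Per-track summary data frames with a `line`
#'   column, as from [simulate_and_recover()].
#' @param thresholds A [motion_thresholds()] object.
#' @param taus Quantile levels for the contrast.
#' @param n_boot,seed Bootstrap settings for the quantile contrast.
#' @return A list of tidy components (`per_line`, `percentiles`,
#'   `quantile_contrast`, `t_mean_speed`, `fast`, `direction`).
#' @export
group_statistics <- function(control, patient,
                             thresholds = motion_thresholds(),
                             taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                             n_boot = 1000, seed = 1) {
  per_line <- function(sm, group) {
    ms <- tapply(sm$mean_speed_um_s, sm$line, mean)
    data.frame(group = group, line = names(ms),
               mean_speed_um_s = as.numeric(ms),
               pct_fast = as.numeric(
                 tapply(sm$is_fast, sm$line, mean) * 100))
  }
  pl <- rbind(per_line(control, "control"), per_line(patient, "patient"))
  ctrl_lines <- pl[pl$group == "control", ]
  pat_lines <- pl[pl$group == "patient", ]
  dir_tab <- function(sm) {
    f <- sm[sm$is_fast & sm$direction != "stationary", ]
    c(anterograde = sum(f$direction == "anterograde"),
      retrograde = sum(f$direction == "retrograde"))
  }
  dirs <- rbind(control = dir_tab(control), patient = dir_tab(patient))
  list(per_line = pl,
       percentiles = data.frame(
         tau = taus,
         control = as.numeric(check_quantile(control$mean_speed_um_s,
                                             taus)),
         patient = as.numeric(check_quantile(patient$mean_speed_um_s,
                                             taus))),
       quantile_contrast = quantile_group_contrast(
         control$mean_speed_um_s, patient$mean_speed_um_s, taus,
         n_boot = n_boot, seed = seed),
       t_mean_speed = t_from_values(ctrl_lines$mean_speed_um_s,
                                    pat_lines$mean_speed_um_s),
       fast = list(
         control = percent_fast(control$mean_speed_um_s, control$line,
                                thresholds),
         patient = percent_fast(patient$mean_speed_um_s, patient$line,
                                thresholds)),
       direction = list(
         counts = dirs,
         anterograde_pct = dirs[, "anterograde"] /
           pmax(rowSums(dirs), 1) * 100))
}

#' Run the full synthetic two-group pipeline and write all artefacts
#'
#' Simulates a control and a patient group, pushes both through rendering,
#' detection, tracking and motion metrics, computes the group statistics
#' and writes every intermediate (tracks, summaries, statistics) plus a
#' JSON report to `out_dir`. Re-running with the same configuration
#' reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed, recorded in the report and used for every
#'   random stream.
#' @param n_lines,tracks_per_line Problem size per group.
#' @param presets Named character vector of condition presets.
#' @param imaging,detection,linking,thresholds Parameter objects.
#' @param ground_truth_only Skip rendering (fast smoke runs).
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1, n_lines = 5,
                         tracks_per_line = 50,
                         presets = c(control = "control",
                                     patient = "patient"),
                         imaging = imaging_params(),
                         detection = detection_params(),
                         linking = linking_params(),
                         thresholds = motion_thresholds(),
                         ground_truth_only = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  runs <- list()
  for (g in names(presets)) {
    runs[[g]] <- stage(paste0("simulate_recover:", g),
      simulate_and_recover(presets[[g]], n_lines, tracks_per_line,
                           seed = seed + match(g, names(presets)),
                           imaging = imaging, detection = detection,
                           linking = linking, thresholds = thresholds,
                           ground_truth_only = ground_truth_only))
    utils::write.csv(runs[[g]]$summaries,
                     file.path(out_dir, paste0("summaries_", g, ".csv")),
                     row.names = FALSE)
  }
  stats <- stage("group_statistics",
    group_statistics(runs[[1]]$summaries, runs[[2]]$summaries,
                     thresholds, seed = seed))
  utils::write.csv(stats$per_line,
                   file.path(out_dir, "per_line.csv"), row.names = FALSE)
  utils::write.csv(stats$quantile_contrast,
                   file.path(out_dir, "quantile_contrast.csv"),
                   row.names = FALSE)
  report <- list(
    seed = seed,
    n_lines = n_lines, tracks_per_line = tracks_per_line,
    presets = as.list(presets),
    thresholds = unclass(thresholds),
    linking = unclass(linking),
    n_tracks_complete = lapply(runs, function(r) nrow(r$summaries)),
    mean_speed_um_s = lapply(runs, function(r)
      mean(r$summaries$mean_speed_um_s)),
    pct_fast = lapply(runs, function(r)
      mean(r$summaries$is_fast) * 100),
    t_mean_speed = stats$t_mean_speed$statistic,
    anterograde_pct = as.list(stats$direction$anterograde_pct))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
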