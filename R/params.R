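#' Generative parameters for three-class saltatory transport
#'
#' Describes a population of organelles moving along a quasi-1D axon-like
#' process. Each organelle belongs to one of three motion classes: *fast*
#' (saltatory run-and-pause transport along microtubules), *slow*
#' (Brownian-like jitter with small net excursions) or *immobile*
#' (localization noise only). Fast organelles alternate exponentially
#' distributed runs at a per-run speed drawn from a truncated normal with
#' exponentially distributed pauses, moving anterogradely (away from the
#' soma) with probability `p_anterograde` (direction drawn once per
#' organelle).
#'
#' Default run/pause/speed values are a calibration chosen so that a control
#' population reproduces the regime reported for peroxisomes in axon-like
#' processes: population mean speed near 0.06 um/s and a 90th percentile
#' near the 0.14 um/s fast-mover threshold. They are exposed here, not
#' hard-coded.
#'
#' @param frac_fast,frac_slow,frac_immobile Class proportions; must sum to 1.
#' @param fast_run_speed_mean,fast_run_speed_sd Per-run speed distribution
#'   (um/s), truncated at zero.
#' @param fast_run_duration_mean Mean run duration (s).
#' @param fast_pause_duration_mean Mean pause duration (s).
#' @param slow_step_sd Median per-frame step standard deviation of slow
#'   organelles (um per frame).
#' @param slow_step_sd_spread Lognormal spread (sdlog) of the per-organelle
#'   step SD around `slow_step_sd`. Between-organelle heterogeneity of
#'   Brownian-like motility makes the per-track mean-speed distribution
#'   continuous, as observed in real populations; 0 gives identical slow
#'   organelles.
#' @param loc_noise_sd Localization noise added to every observed coordinate
#'   (um).
#' @param p_anterograde Probability that a fast organelle moves anterogradely.
#' @param process_length Length of the process (um); processes of
#'   150--300 um are typical.
#' @param soma_margin Distance from the soma end at which quantification
#'   windows start (um).
#' @return An object of class `motion_params`.
#' @seealso [condition_preset()], [simulate_tracks()]
#' @export
motion_params <- function(frac_fast = 0.10,
                          frac_slow = 0.63,
                          frac_immobile = 0.27,
                          fast_run_speed_mean = 0.52,
                          fast_run_speed_sd = 0.25,
                          fast_run_duration_mean = 5,
                          fast_pause_duration_mean = 7,
                          slow_step_sd = 0.1,
                          slow_step_sd_spread = 0.45,
                          loc_noise_sd = 0.02,
                          p_anterograde = 0.609,
                          process_length = 200,
                          soma_margin = 20) {
  p <- list(frac_fast = frac_fast, frac_slow = frac_slow,
            frac_immobile = frac_immobile,
            fast_run_speed_mean = fast_run_speed_mean,
            fast_run_speed_sd = fast_run_speed_sd,
            fast_run_duration_mean = fast_run_duration_mean,
            fast_pause_duration_mean = fast_pause_duration_mean,
            slow_step_sd = slow_step_sd,
            slow_step_sd_spread = slow_step_sd_spread,
            loc_noise_sd = loc_noise_sd,
            p_anterograde = p_anterograde,
            process_length = process_length,
            soma_margin = soma_margin)
  validate_motion_params(p)
  structure(p, class = "motion_params")
}

validate_motion_params <- function(p) {
  fr <- c(p$frac_fast, p$frac_slow, p$frac_immobile)
  if (any(fr < 0) || any(fr > 1))
    stop("class fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("frac_fast + frac_slow + frac_immobile must equal 1 (got ",
         format(sum(fr), digits = 12), ")", call. = FALSE)
  pos <- c(fast_run_speed_mean = p$fast_run_speed_mean,
           fast_run_duration_mean = p$fast_run_duration_mean,
           fast_pause_duration_mean = p$fast_pause_duration_mean,
           process_length = p$process_length)
  if (any(pos <= 0))
    stop("parameters must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  if (p$fast_run_speed_sd < 0 || p$slow_step_sd < 0 ||
      p$slow_step_sd_spread < 0 || p$loc_noise_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (p$p_anterograde < 0 || p$p_anterograde > 1)
    stop("p_anterograde must lie in [0, 1]", call. = FALSE)
  if (p$soma_margin < 0 || p$soma_margin >= p$process_length)
    stop("soma_margin must lie in [0, process_length)", call. = FALSE)
  invisible(p)
}

#' Motion-model presets for the experimental conditions
#'
#' Returns [motion_params()] for one of three conditions: healthy `"control"`
#' cells (10% fast movers, 60.9% of them anterograde), `"patient"` cells
#' carrying SPAST mutations (2.3% fast movers, 86.1% anterograde), and
#' `"patient_epoD"` -- patient cells treated with the microtubule-stabilising
#' drug epothilone D, which restores the fast-mover fraction to the control
#' level while the directional bias of the patient cells is retained.
#' The non-fast mass is split 70/30 between slow and immobile (a documented
#' free parameter; the split is not condition-specific).
#'
#' @param name One of `"control"`, `"patient"`, `"patient_epoD"`.
#' @param ... Overrides passed on to [motion_params()].
#' @return A `motion_params` object.
#' @export
condition_preset <- function(name = c("control", "patient", "patient_epoD"),
                             ...) {
  if (length(name) != 1L || !name %in% c("control", "patient", "patient_epoD"))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; expected one of control, patient, patient_epoD", call. = FALSE)
  frac_fast <- switch(name, control = 0.10, patient = 0.023,
                      patient_epoD = 0.10)
  p_antero <- switch(name, control = 0.609, patient = 0.861,
                     patient_epoD = 0.609)
  rest <- 1 - frac_fast
  args <- list(frac_fast = frac_fast,
               frac_slow = 0.7 * rest,
               frac_immobile = 0.3 * rest,
               p_anterograde = p_antero)
  over <- list(...)
  args[names(over)] <- over
  do.call(motion_params, args)
}

#' Imaging parameters for time-lapse acquisition and rendering
#'
#' Defaults follow the acquisition regime of the peroxisome experiments:
#' z-stacks every 2 s for 4 min (121 frames).
#'
#' @param frame_interval Time between frames (s).
#' @param duration Total observation time (s); `n_frames =
#'   floor(duration / frame_interval) + 1`.
#' @param pixel_size Physical pixel size (um/pixel).
#' @param n_z Number of z slices per time point.
#' @param z_spacing Spacing between z slices (um).
#' @param psf_sigma Lateral PSF standard deviation (um).
#' @param psf_sigma_z Axial PSF standard deviation (um), controls how a
#'   spot's photons spread across z slices.
#' @param photon_scale Expected photons per spot per time point.
#' @param background Background level (photons/pixel).
#' @param read_noise_sd Gaussian read noise (photons).
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(frame_interval = 2,
                           duration = 240,
                           pixel_size = 0.1,
                           n_z = 3,
                           z_spacing = 0.5,
                           psf_sigma = 0.15,
                           psf_sigma_z = 0.4,
                           photon_scale = 500,
                           background = 20,
                           read_noise_sd = 3) {
  if (frame_interval <= 0 || duration <= 0)
    stop("frame_interval and duration must be positive", call. = FALSE)
  n_frames <- floor(duration / frame_interval) + 1L
  if (n_frames < 2)
    stop("duration/frame_interval implies fewer than 2 frames", call. = FALSE)
  if (pixel_size <= 0 || psf_sigma <= 0 || psf_sigma_z <= 0 || z_spacing <= 0)
    stop("pixel_size, z_spacing and PSF widths must be positive",
         call. = FALSE)
  if (n_z < 1) stop("n_z must be at least 1", call. = FALSE)
  if (photon_scale < 0 || background < 0 || read_noise_sd < 0)
    stop("photon_scale, background, read_noise_sd must be non-negative",
         call. = FALSE)
  structure(list(frame_interval = frame_interval, duration = duration,
                 n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, n_z = as.integer(n_z),
                 z_spacing = z_spacing, psf_sigma = psf_sigma,
                 psf_sigma_z = psf_sigma_z, photon_scale = photon_scale,
                 background = background, read_noise_sd = read_noise_sd),
            class = "imaging_params")
}

#' Spot-detection parameters
#'
#' @param expected_diameter Expected spot diameter (um); 0.75 is the middle
#'   of the 0.5--1 um range typical of peroxisomes.
#' @param intensity_threshold Threshold on the band-pass (blob) response;
#'   `"auto"` uses median + k * MAD of the response.
#' @param auto_k Robust threshold multiplier used when
#'   `intensity_threshold = "auto"`.
#' @param min_separation Minimum separation between detections (um); closer
#'   detections are merged keeping the brighter one.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(expected_diameter = 0.75,
                             intensity_threshold = "auto",
                             auto_k = 5,
                             min_separation = 0.75) {
  if (expected_diameter <= 0)
    stop("expected_diameter must be positive", call. = FALSE)
  if (min_separation < 0)
    stop("min_separation must be non-negative", call. = FALSE)
  if (!identical(intensity_threshold, "auto") &&
      !(is.numeric(intensity_threshold) && length(intensity_threshold) == 1))
    stop("intensity_threshold must be 'auto' or a single number",
         call. = FALSE)
  structure(list(expected_diameter = expected_diameter,
                 intensity_threshold = intensity_threshold,
                 auto_k = auto_k,
                 min_separation = min_separation),
            class = "detection_params")
}

#' Track-linking parameters
#'
#' @param max_link_distance Maximum displacement allowed between consecutive
#'   frames (um per frame interval). The default 2.5 um per 2 s frame
#'   (1.25 um/s) is above the fastest plausible transport burst.
#' @param max_gap Maximum number of missed frames bridged by gap closing.
#'   Defaults to 0: the completeness filter discards gapped tracks anyway.
#' @return An object of class `linking_params`.
#' @export
linking_params <- function(max_link_distance = 2.5, max_gap = 0L) {
  if (max_link_distance <= 0)
    stop("max_link_distance must be positive", call. = FALSE)
  if (max_gap < 0) stop("max_gap must be non-negative", call. = FALSE)
  structure(list(max_link_distance = max_link_distance,
                 max_gap = as.integer(max_gap)),
            class = "linking_params")
}

#' Motion-metric thresholds
#'
#' @param saltatory_threshold Instantaneous speed above which a frame
#'   belongs to a saltatory event (um/s). A saltatory event is a maximal
#'   contiguous run of speeds strictly above this threshold.
#' @param fast_threshold Mean track speed above which (strictly) a track is
#'   a fast mover (um/s); 0.14 um/s is the 90th percentile of the control
#'   population.
#' @param density_window Half-open interval `[start, end)` on the process
#'   axis (um from the soma) within which organelles are counted.
#' @param direction_epsilon Net axial displacement (um) below which a track
#'   is labelled stationary rather than anterograde/retrograde.
#' @return An object of class `motion_thresholds`.
#' @export
motion_thresholds <- function(saltatory_threshold = 0.1,
                              fast_threshold = 0.14,
                              density_window = c(20, 140),
                              direction_epsilon = 0.2) {
  if (saltatory_threshold <= 0 || fast_threshold <= 0)
    stop("speed thresholds must be positive", call. = FALSE)
  if (length(density_window) != 2 || density_window[1] >= density_window[2])
    stop("density_window must be an increasing [start, end) pair",
         call. = FALSE)
  if (direction_epsilon < 0)
    stop("direction_epsilon must be non-negative", call. = FALSE)
  structure(list(saltatory_threshold = saltatory_threshold,
                 fast_threshold = fast_threshold,
                 density_window = as.numeric(density_window),
                 direction_epsilon = direction_epsilon),
            class = "motion_thresholds")
}

#' Parameters for synthetic multi-channel cell fields
#'
#' Describes a field of well-separated round cells used as ground truth for
#' the per-cell cytoplasmic fluorescence quantification: a nucleus channel
#' (discs), a cell-mask channel (larger discs containing each nucleus) and a
#' marker channel whose cytoplasmic level is a per-cell constant drawn from
#' `normal(marker_mean_per_condition[condition], marker_cell_sd)`.
#'
#' @param n_cells Number of cells to place.
#' @param nucleus_radius,cell_radius Disc radii (um); nucleus < cell.
#' @param marker_mean_per_condition Named numeric vector mapping condition
#'   label to mean cytoplasmic marker intensity (a.u.).
#' @param marker_cell_sd Between-cell SD of the marker level (a.u.).
#' @param background Marker background added everywhere (a.u.).
#' @param pixel_noise_sd Per-pixel Gaussian noise on every channel (a.u.).
#' @param field_size_px Field side length (pixels, square field).
#' @param pixel_size Physical pixel size (um).
#' @return An object of class `cell_field_params`.
#' @export
cell_field_params <- function(n_cells = 20,
                              nucleus_radius = 5,
                              cell_radius = 12,
                              marker_mean_per_condition =
                                c(baseline = 50, H2O2 = 70,
                                  `EpoD+H2O2` = 55),
                              marker_cell_sd = 5,
                              background = 10,
                              pixel_noise_sd = 2,
                              field_size_px = 512,
                              pixel_size = 0.5) {
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius", call. = FALSE)
  if (any(marker_mean_per_condition < 0) || background < 0 ||
      marker_cell_sd < 0 || pixel_noise_sd < 0)
    stop("intensities must be non-negative", call. = FALSE)
  if (is.null(names(marker_mean_per_condition)))
    stop("marker_mean_per_condition must be a named vector", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be non-negative", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells),
                 nucleus_radius = nucleus_radius,
                 cell_radius = cell_radius,
                 marker_mean_per_condition = marker_mean_per_condition,
                 marker_cell_sd = marker_cell_sd,
                 background = background,
                 pixel_noise_sd = pixel_noise_sd,
                 field_size_px = as.integer(field_size_px),
                 pixel_size = pixel_size),
            class = "cell_field_params")
}

#' @export
print.motion_params <- function(x, ...) {
  cat("Motion model parameters\n")
  cat(sprintf("  class fractions: fast %.3f / slow %.3f / immobile %.3f\n",
              x$frac_fast, x$frac_slow, x$frac_immobile))
  cat(sprintf("  fast runs: %.2f +/- %.2f um/s, run %.1f s, pause %.1f s\n",
              x$fast_run_speed_mean, x$fast_run_speed_sd,
              x$fast_run_duration_mean, x$fast_pause_duration_mean))
  cat(sprintf("  slow step sd %.3f um/frame, loc noise %.3f um\n",
              x$slow_step_sd, x$loc_noise_sd))
  cat(sprintf("  p(anterograde) %.3f, process %.0f um (soma margin %.0f um)\n",
              x$p_anterograde, x$process_length, x$soma_margin))
  invisible(x)
}

#' @export
print.imaging_params <- function(x, ...) {
  cat(sprintf(
    "Imaging: %d frames @ %.3g s, %d z @ %.3g um, pixel %.3g um\n",
    x$n_frames, x$frame_interval, x$n_z, x$z_spacing, x$pixel_size))
  invisible(x)
}
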