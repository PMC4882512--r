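#' Lay tracks out in parallel lanes for rendering
#'
#' Arranges each track of a simulated `track_set` in its own transverse
#' lane, emulating a field of view containing several parallel quasi-1D
#' processes. Each track is translated along the axis so that its excursion
#' starts near the left margin; the per-lane axial offset and lane centre
#' are recorded so that axial (`s`) coordinates can be recovered from
#' tracked image coordinates with [recover_s_coordinates()].
#'
#' @param ts A `track_set` whose tracks carry `s_um` coordinates.
#' @param lane_spacing Distance between lane centres (um). Keep it larger
#'   than the linker's `max_link_distance` so lanes cannot interact.
#' @param margin Margin between the field border and any spot (um).
#' @return A list with `track_set` (coordinates moved into the field),
#'   `layout` (data frame: `track_id`, `lane`, `x_offset_um`,
#'   `y_center_um`) and the field extent `width_um`, `height_um`.
#' @export
layout_tracks <- function(ts, lane_spacing = 3, margin = 2) {
  tr <- ts$tracks
  ids <- unique(tr$track_id)
  spans <- vapply(split(tr$s_um, tr$track_id), function(s)
    diff(range(s)), numeric(1))[as.character(ids)]
  mins <- vapply(split(tr$s_um, tr$track_id), min,
                 numeric(1))[as.character(ids)]
  lane <- seq_along(ids)
  y_center <- margin + (lane - 0.5) * lane_spacing
  # shift each track's minimum to the left margin
  x_offset <- mins - margin          # s = x + offset
  idx <- match(tr$track_id, ids)
  tr$x_um <- tr$s_um - x_offset[idx]
  tr$y_um <- tr$y_um + y_center[idx]
  width <- max(tr$x_um) + margin
  height <- margin + length(ids) * lane_spacing + margin
  out <- ts
  out$tracks <- tr
  list(track_set = out,
       layout = data.frame(track_id = ids, lane = lane,
                           x_offset_um = x_offset,
                           y_center_um = y_center),
       width_um = width, height_um = height)
}

#' Recover process-axis coordinates from tracked image coordinates
#'
#' Maps each recovered track back to the lane of the synthetic layout via
#' its median `y` position and undoes the per-lane axial offset.
#'
#' @param ts A recovered `track_set` (image coordinates).
#' @param layout The `layout` data frame from [layout_tracks()].
#' @return The `track_set` with an `s_um` column added.
#' @export
recover_s_coordinates <- function(ts, layout) {
  tr <- ts$tracks
  med_y <- tapply(tr$y_um, tr$track_id, stats::median)
  lane_of <- vapply(med_y, function(y)
    which.min(abs(layout$y_center_um - y)), integer(1))
  off <- layout$x_offset_um[lane_of]
  names(off) <- names(med_y)
  tr$s_um <- tr$x_um + off[as.character(tr$track_id)]
  out <- ts
  out$tracks <- tr
  out
}

#' Render a synthetic fluorescence movie from tracks
#'
#' Renders each organelle as a lateral Gaussian of width `psf_sigma` whose
#' photons are distributed across z slices with axial Gaussian weights, on
#' a constant background, with Poisson shot noise and Gaussian read noise.
#' The per-spot photon budget (`photon_scale`) is conserved across frames:
#' the discrete kernel is normalised to sum to the photon count, so the
#' expected total signal of a spot is identical in every frame.
#'
#' @param ts A `track_set` with image coordinates `x_um`, `y_um`.
#' @param imaging An [imaging_params()] object.
#' @param seed Integer seed for the noise streams.
#' @param width_um,height_um Field of view (um); defaults enclose the
#'   tracks with a 2 um margin.
#' @param noise Set `FALSE` to return the noiseless expected image.
#' @return A `movie` object: array of dimension `(frame, z, row, col)` of
#'   photon counts plus calibration attributes.
#' @export
render_movie <- function(ts, imaging, seed = 1, width_um = NULL,
                         height_um = NULL, noise = TRUE) {
  tr <- ts$tracks
  px <- imaging$pixel_size
  if (is.null(width_um)) width_um <- if (nrow(tr)) max(tr$x_um) + 2 else 10
  if (is.null(height_um)) height_um <- if (nrow(tr)) max(tr$y_um) + 2 else 10
  W <- max(2L, as.integer(ceiling(width_um / px)))
  H <- max(2L, as.integer(ceiling(height_um / px)))
  if (nrow(tr)) {
    bad <- tr$x_um < 0 | tr$y_um < 0 |
      tr$x_um > (W - 1) * px | tr$y_um > (H - 1) * px
    if (any(bad))
      stop("track(s) ", paste(unique(tr$track_id[bad]), collapse = ", "),
           " fall outside the field of view", call. = FALSE)
  }
  n_f <- ts$n_frames; n_z <- imaging$n_z
  sig_px <- imaging$psf_sigma / px
  half <- max(2L, as.integer(ceiling(4 * sig_px)))
  # axial weights: one z position per track (centre slice), normalised
  z_centers <- (seq_len(n_z) - (n_z + 1) / 2) * imaging$z_spacing
  wz <- exp(-z_centers^2 / (2 * imaging$psf_sigma_z^2))
  wz <- wz / sum(wz)

  mov <- array(imaging$background, dim = c(n_f, n_z, H, W))
  if (nrow(tr)) {
    col0 <- tr$x_um / px + 1   # fractional 1-based pixel coordinates
    row0 <- tr$y_um / px + 1
    for (i in seq_len(nrow(tr))) {
      f <- tr$frame[i] + 1L
      rc <- round(row0[i]); cc <- round(col0[i])
      rs <- max(1L, rc - half):min(H, rc + half)
      cs <- max(1L, cc - half):min(W, cc + half)
      kr <- exp(-(rs - row0[i])^2 / (2 * sig_px^2))
      kc <- exp(-(cs - col0[i])^2 / (2 * sig_px^2))
      ker <- outer(kr, kc)
      ker <- ker * (imaging$photon_scale / sum(ker))
      for (z in seq_len(n_z))
        mov[f, z, rs, cs] <- mov[f, z, rs, cs] + wz[z] * ker
    }
  }
  if (noise) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed %% 2147483647)
    n <- length(mov)
    mov[] <- stats::rpois(n, lambda = as.vector(mov)) +
      stats::rnorm(n, 0, imaging$read_noise_sd)
  }
  structure(mov, class = "movie",
            pixel_size_um = imaging$pixel_size,
            frame_interval_s = imaging$frame_interval,
            n_z = n_z)
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("movie: %d frames x %d z x %d x %d px (pixel %.3g um, dt %.3g s)\n",
              d[1], d[2], d[3], d[4], attr(x, "pixel_size_um"),
              attr(x, "frame_interval_s")))
  invisible(x)
}

#' Render a synthetic multi-channel cell field
#'
#' Places round cells without nucleus overlap (and away from the field
#' edge, since edge-touching cells are excluded downstream) and renders
#' three channels: nuclei (discs), cell mask (larger discs) and a marker
#' whose cytoplasmic level is a per-cell constant drawn from the condition's
#' normal distribution, plus background and per-pixel Gaussian noise.
#'
#' @param params A [cell_field_params()] object.
#' @param condition Condition label; must name an entry of
#'   `params$marker_mean_per_condition`.
#' @param seed Integer seed.
#' @param max_retries Placement retries before giving up.
#' @return A list with channel matrices `nucleus`, `cell`, `marker`
#'   (rows = y), the ground `truth` data frame (`cell_id`, `x_um`, `y_um`,
#'   `marker_level`) and `pixel_size`.
#' @export
render_cell_field <- function(params, condition, seed = 1,
                              max_retries = 2000) {
  if (!condition %in% names(params$marker_mean_per_condition))
    stop("unknown condition '", condition, "'; expected one of ",
         paste(names(params$marker_mean_per_condition), collapse = ", "),
         call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% 2147483647)

  px <- params$pixel_size
  n_px <- params$field_size_px
  rad_px <- params$cell_radius / px
  # centres: no cell-disc overlap (implies no nucleus overlap), inside field
  centres <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centres) < params$n_cells) {
    cand <- stats::runif(2, rad_px + 2, n_px - rad_px - 1)
    ok <- !nrow(centres) ||
      all(sqrt(colSums((t(centres) - cand)^2)) >= 2 * rad_px + 2)
    if (ok) centres <- rbind(centres, cand)
    tries <- tries + 1
    if (tries > max_retries)
      stop("could not place ", params$n_cells,
           " cells without overlap after ", max_retries, " retries",
           call. = FALSE)
  }

  nuc <- matrix(0, n_px, n_px)
  cell <- matrix(0, n_px, n_px)
  marker <- matrix(params$background, n_px, n_px)
  mu <- params$marker_mean_per_condition[[condition]]
  levels <- if (params$n_cells)
    pmax(stats::rnorm(params$n_cells, mu, params$marker_cell_sd), 0)
    else numeric(0)
  rr <- row(nuc); cc <- col(nuc)
  for (i in seq_len(params$n_cells)) {
    d2 <- (rr - centres[i, 1])^2 + (cc - centres[i, 2])^2
    in_cell <- d2 <= rad_px^2
    in_nuc <- d2 <= (params$nucleus_radius / px)^2
    nuc[in_nuc] <- 100
    cell[in_cell] <- 100
    marker[in_cell & !in_nuc] <- marker[in_cell & !in_nuc] + levels[i]
  }
  if (params$pixel_noise_sd > 0) {
    marker <- marker + stats::rnorm(length(marker), 0, params$pixel_noise_sd)
    nuc <- nuc + stats::rnorm(length(nuc), 0, params$pixel_noise_sd)
    cell <- cell + stats::rnorm(length(cell), 0, params$pixel_noise_sd)
  }
  truth <- data.frame(
    cell_id = seq_len(params$n_cells),
    x_um = if (params$n_cells) (centres[, 2] - 1) * px else numeric(0),
    y_um = if (params$n_cells) (centres[, 1] - 1) * px else numeric(0),
    marker_level = levels)
  list(nucleus = nuc, cell = cell, marker = marker, truth = truth,
       pixel_size = px)
}
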