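#' Write a movie as a multi-page TIFF with a JSON calibration sidecar
#'
#' Pages are ordered frame-major (all z of frame 0, then frame 1, ...).
#' Data are stored as 32-bit float samples, so the write/read round trip
#' is lossless at that bit depth. The sidecar `<path>.json` records
#' `pixel_size_um`, `frame_interval_s` and `n_z`.
#'
#' @param movie A `movie` array (frame, z, row, col) from [render_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie)
  # 32-bit float TIFF samples must lie in [0, 1]: shift by an integer
  # offset and divide by a power of two (recorded in the sidecar), so the
  # transform is exact and the round trip is lossless at float32 depth
  offset <- floor(min(movie, 0))
  rng <- max(movie) - offset
  scale <- 2^ceiling(log2(max(rng, 1)))
  pages <- vector("list", d[1] * d[2])
  k <- 1
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- matrix((movie[f, z, , ] - offset) / scale, d[3], d[4])
    k <- k + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = attr(movie, "pixel_size_um"),
         frame_interval_s = attr(movie, "frame_interval_s"),
         n_z = dim(movie)[2],
         intensity_offset = offset, intensity_scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a movie TIFF and its calibration sidecar
#'
#' @param path TIFF path written by [write_movie()] (or any multi-page
#'   TIFF with a matching sidecar).
#' @return A `movie` array of dimension `(frame, z, row, col)` with
#'   calibration attributes.
#' @export
read_movie <- function(path) {
  if (!file.exists(path))
    stop("movie file not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing calibration sidecar ", sc,
         " (expected keys pixel_size_um, frame_interval_s, n_z)",
         call. = FALSE)
  cal <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "frame_interval_s", "n_z"))
    if (is.null(cal[[key]]))
      stop("calibration sidecar lacks key '", key, "'", call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("could not read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  n_z <- as.integer(cal$n_z)
  if (length(pages) %% n_z != 0)
    stop("page count ", length(pages), " is not a multiple of n_z = ",
         n_z, call. = FALSE)
  n_f <- length(pages) %/% n_z
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  offset <- if (is.null(cal$intensity_offset)) 0 else cal$intensity_offset
  scale <- if (is.null(cal$intensity_scale)) 1 else cal$intensity_scale
  mov <- array(0, dim = c(n_f, n_z, H, W))
  k <- 1
  for (f in seq_len(n_f)) for (z in seq_len(n_z)) {
    mov[f, z, , ] <- pages[[k]] * scale + offset
    k <- k + 1
  }
  structure(mov, class = "movie",
            pixel_size_um = cal$pixel_size_um,
            frame_interval_s = cal$frame_interval_s,
            n_z = n_z)
}

#' Write/read track tables as CSV
#'
#' The CSV schema (`track_id, frame, s_um, x_um, y_um`, plus any
#' ground-truth metadata columns) is shared between the simulator's
#' ground-truth output and recovered tracks, so the two are directly
#' comparable.
#'
#' @param ts A `track_set`.
#' @param path Output CSV path.
#' @return `path` invisibly / a `track_set`.
#' @export
write_tracks_csv <- function(ts, path) {
  tr <- ts$tracks
  if (!is.null(ts$meta)) {
    idx <- match(tr$track_id, ts$meta$track_id)
    extra <- ts$meta[idx, setdiff(names(ts$meta), "track_id"),
                     drop = FALSE]
    tr <- cbind(tr, extra)
  }
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param frame_interval,n_frames,provenance Metadata for the returned
#'   `track_set` (`n_frames` defaults to `max(frame) + 1`).
#' @export
read_tracks_csv <- function(path, frame_interval = 2, n_frames = NULL,
                            provenance = "recovered") {
  tr <- utils::read.csv(path)
  if (is.null(n_frames)) n_frames <- max(tr$frame) + 1L
  meta <- NULL
  meta_cols <- intersect(c("class", "direction", "duty"), names(tr))
  if (length(meta_cols)) {
    first <- !duplicated(tr$track_id)
    meta <- tr[first, c("track_id", meta_cols), drop = FALSE]
    rownames(meta) <- NULL
    tr <- tr[, setdiff(names(tr), meta_cols), drop = FALSE]
  }
  track_set(tr, frame_interval, n_frames, provenance, meta = meta)
}

#' Write per-frame detections as CSV
#'
#' Schema: `frame, x_um, y_um, intensity, est_diameter_um`.
#'
#' @param detections Data frame from [detect_movie()].
#' @param path Output CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  utils::read.csv(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised top-level blocks: `seed`, `preset` (or `motion`),
#' `imaging`, `detection`, `linking`, `thresholds`, `out_dir`. Every block
#' is passed as arguments to the corresponding constructor, so defaults
#' apply to anything omitted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of validated parameter objects.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- list(
    seed = if (!is.null(raw$seed)) as.integer(raw$seed) else 1L,
    out_dir = raw$out_dir,
    preset = raw$preset,
    imaging = do.call(imaging_params, as.list(raw$imaging)),
    detection = do.call(detection_params, as.list(raw$detection)),
    linking = do.call(linking_params, as.list(raw$linking)),
    thresholds = do.call(motion_thresholds, as.list(raw$thresholds)))
  if (!is.null(raw$motion))
    cfg$motion <- do.call(motion_params, as.list(raw$motion))
  cfg
}
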