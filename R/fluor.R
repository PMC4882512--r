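#' Segment nuclei from a nucleus-channel image
#'
#' Otsu threshold on the normalised channel, connected-component labelling
#' and a minimum-area filter. Touching nuclei are merged (an optional
#' watershed split can be applied by the caller; merging is the documented
#' default behaviour).
#'
#' @param img Nucleus channel matrix (rows = y).
#' @param min_area_px Minimum object area in pixels.
#' @param threshold `"otsu"` or a numeric threshold on the raw intensity.
#' @return Integer label matrix (0 = background), labels renumbered
#'   consecutively in scan order.
#' @export
segment_nuclei <- function(img, min_area_px = 20, threshold = "otsu") {
  if (!length(img)) stop("empty image", call. = FALSE)
  thr <- if (identical(threshold, "otsu")) {
    t0 <- otsu_threshold(img)
    # contrast guard: on a foreground-free (noise-only) channel Otsu
    # bisects the noise; require the threshold to clear the noise floor
    if (t0 <= stats::median(img) + 3 * stats::mad(img))
      return(matrix(0L, nrow(img), ncol(img)))
    t0
  } else threshold
  mask <- img > thr
  if (!any(mask))
    return(matrix(0L, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# Otsu threshold on raw intensities (maximises between-class variance).
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  x <- (img - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(t(x)), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

#' Per-cell cytoplasm masks from a cell-mask channel
#'
#' The thresholded cell area is partitioned among nuclei by seeded region
#' growing (Voronoi propagation on the cell-mask intensity landscape);
#' each cell's cytoplasm is its territory minus its nucleus -- the region
#' between the nucleus and the cell edge. Cells whose territory touches
#' the image border are excluded (standard high-content practice), and
#' nuclei that fall outside the thresholded cell area are dropped with a
#' warning.
#'
#' @param cell_img Cell-mask channel matrix.
#' @param nuclei Integer nucleus label matrix from [segment_nuclei()].
#' @param threshold `"otsu"` or numeric threshold for the cell area.
#' @param exclude_border Drop cells touching the field edge.
#' @return Integer label matrix of cytoplasm regions (same labels as
#'   `nuclei`; dropped cells absent).
#' @export
cytoplasm_regions <- function(cell_img, nuclei, threshold = "otsu",
                              exclude_border = TRUE) {
  thr <- if (identical(threshold, "otsu")) otsu_threshold(cell_img)
         else threshold
  mask <- cell_img > thr
  n_nuc <- max(nuclei)
  if (n_nuc == 0) return(matrix(0L, nrow(cell_img), ncol(cell_img)))
  inside <- vapply(seq_len(n_nuc), function(i)
    any(mask[nuclei == i]), logical(1))
  if (any(!inside))
    warning(sum(!inside), " nucleus/nuclei outside the cell area dropped",
            call. = FALSE)
  seeds <- nuclei
  seeds[!mask & seeds > 0] <- 0L   # seeds restricted to the cell area
  prop <- EBImage::propagate(EBImage::Image(t(cell_img)),
                             seeds = EBImage::Image(t(seeds)),
                             mask = EBImage::Image(t(mask)))
  terr <- t(EBImage::imageData(prop))
  drop <- which(!inside)
  if (exclude_border) {
    border_labels <- unique(c(terr[1, ], terr[nrow(terr), ],
                              terr[, 1], terr[, ncol(terr)]))
    drop <- union(drop, border_labels[border_labels > 0])
  }
  terr[terr %in% drop] <- 0L
  terr[nuclei > 0] <- 0L           # cytoplasm = territory minus nucleus
  storage.mode(terr) <- "integer"
  terr
}

#' Mean marker fluorescence per cell cytoplasm
#'
#' Mean of the marker channel inside each cytoplasm mask, with physical
#' areas. A minimum-cell-count gate (1000 cells in real screens; relax for
#' small synthetic fields) controls whether the per-field aggregate is
#' reported.
#'
#' @param marker_img Marker channel matrix.
#' @param masks Cytoplasm label matrix from [cytoplasm_regions()].
#' @param pixel_size Physical pixel size (um).
#' @param line_id,condition Labels attached to every record.
#' @param min_cells Minimum number of cells required for the aggregate.
#' @return A list with `records` (data frame: `cell_id`, `line_id`,
#'   `condition`, `cytoplasm_area_um2`, `marker_mean`), `aggregate` (mean
#'   across cells, or `NA` when gated) and `status`
#'   (`"ok"`/`"too_few_cells"`).
#' @export
marker_means <- function(marker_img, masks, pixel_size = 1,
                         line_id = NA_character_,
                         condition = NA_character_,
                         min_cells = 1) {
  labs <- sort(unique(masks[masks > 0]))   # labels need not be consecutive
  means <- vapply(labs, function(l) mean(marker_img[masks == l]),
                  numeric(1))
  areas <- vapply(labs, function(l) sum(masks == l), numeric(1)) *
    pixel_size^2
  records <- data.frame(cell_id = labs,
                        line_id = rep(line_id, length(labs)),
                        condition = rep(condition, length(labs)),
                        cytoplasm_area_um2 = areas,
                        marker_mean = means)
  if (nrow(records) < min_cells)
    list(records = records, aggregate = NA_real_,
         status = "too_few_cells")
  else
    list(records = records, aggregate = mean(records$marker_mean),
         status = "ok")
}

#' Quantify a synthetic or real 3-channel field end to end
#'
#' Convenience wrapper: nuclei segmentation, cytoplasm partition, marker
#' quantification.
#'
#' @param field List with `nucleus`, `cell`, `marker` matrices and
#'   `pixel_size`, e.g. from [render_cell_field()].
#' @inheritParams marker_means
#' @param min_nucleus_area_px Passed to [segment_nuclei()].
#' @return As [marker_means()].
#' @export
quantify_field <- function(field, line_id = NA_character_,
                           condition = NA_character_, min_cells = 1,
                           min_nucleus_area_px = 20) {
  nuc <- segment_nuclei(field$nucleus, min_area_px = min_nucleus_area_px)
  cyto <- cytoplasm_regions(field$cell, nuc)
  marker_means(field$marker, cyto, pixel_size = field$pixel_size,
               line_id = line_id, condition = condition,
               min_cells = min_cells)
}
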