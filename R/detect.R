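#' Maximum-intensity projection of a z-stack
#'
#' Collapses a 3D z-stack to a single 2D image by taking, at every pixel,
#' the maximum across z. Identity for a single slice.
#'
#' @param stack Either an array of dimension `(n_z, H, W)` or a matrix
#'   (already 2D, returned as is).
#' @return An `H x W` matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || any(d == 0))
    stop("stack must be a non-empty (n_z, H, W) array or a matrix",
         call. = FALSE)
  if (d[1] == 1L) return(array(stack[1, , ], dim = d[2:3]))
  out <- stack[1, , ]
  for (z in 2:d[1]) out <- pmax(out, stack[z, , ])
  out
}

# Laplacian-of-Gaussian kernel (negated, so bright blobs give positive
# peaks), zero-mean so constant images give zero response.
log_kernel <- function(sigma_px) {
  half <- max(2L, as.integer(ceiling(4 * sigma_px)))
  x <- -half:half
  g2 <- outer(x, x, function(r, c) exp(-(r^2 + c^2) / (2 * sigma_px^2)))
  r2 <- outer(x, x, function(r, c) r^2 + c^2)
  k <- -(r2 / sigma_px^4 - 2 / sigma_px^2) * g2
  k - mean(k)
}

# Precompute the FFT of a kernel for images of a given size: images are
# replicate-padded by the kernel half-width, then zero-extended to highly
# composite FFT sizes (the zero margin is at least one half-width from any
# retained pixel, so it cannot influence the result).
conv_plan <- function(dims, kernel) {
  kh <- (nrow(kernel) - 1L) / 2L
  if (dims[1] < nrow(kernel) || dims[2] < ncol(kernel))
    stop("image (", dims[1], "x", dims[2],
         ") is smaller than the filter support (", nrow(kernel), ")",
         call. = FALSE)
  H <- stats::nextn(dims[1] + 2L * kh, c(2, 3, 5))
  W <- stats::nextn(dims[2] + 2L * kh, c(2, 3, 5))
  kf <- matrix(0, H, W)
  kf[1:nrow(kernel), 1:ncol(kernel)] <- kernel
  # circular shift so the kernel centre sits at (1,1)
  kf <- kf[c((kh + 1):H, 1:kh), c((kh + 1):W, 1:kh)]
  list(kh = kh, dims = dims, H = H, W = W, Kf = stats::fft(kf))
}

conv_apply <- function(img, plan) {
  kh <- plan$kh
  p <- matrix(0, plan$H, plan$W)
  ri <- seq_len(nrow(img) + 2 * kh)
  ci <- seq_len(ncol(img) + 2 * kh)
  src_r <- pmin(pmax(ri - kh, 1L), nrow(img))
  src_c <- pmin(pmax(ci - kh, 1L), ncol(img))
  p[ri, ci] <- img[src_r, src_c]
  out <- Re(stats::fft(stats::fft(p) * plan$Kf, inverse = TRUE)) /
    (plan$H * plan$W)
  out[(kh + 1):(nrow(img) + kh), (kh + 1):(ncol(img) + kh)]
}

# 2D convolution with replicate-padding boundary, via FFT.
convolve_2d <- function(img, kernel) {
  conv_apply(img, conv_plan(dim(img), kernel))
}

#' Detect spots in a single image
#'
#' Band-pass blob detection: the image is filtered with a
#' Laplacian-of-Gaussian kernel at scale `sigma = expected_diameter /
#' (2 sqrt(2))` (the matched scale for a blob of that diameter), the
#' response is thresholded (robust auto threshold: median + k * MAD by
#' default), 8-neighbourhood local maxima are kept, maxima closer than
#' `min_separation` are merged keeping the stronger one (ties broken by
#' row, then column order), and centroids are refined to subpixel precision
#' by a background-subtracted intensity-weighted mean over a window of one
#' expected diameter.
#'
#' @param img Image matrix (rows = y, columns = x). For a z-stack, apply
#'   [max_project()] first.
#' @param params A [detection_params()] object.
#' @param pixel_size Physical pixel size (um).
#' @return Data frame with columns `x_um`, `y_um`, `intensity` (filtered
#'   response at the peak) and `est_diameter_um`, sorted by descending
#'   intensity. Physical coordinates are measured from the centre of the
#'   top-left pixel.
#' @export
detect_spots <- function(img, params = detection_params(),
                         pixel_size = 0.1) {
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  sigma_px <- params$expected_diameter / (2 * sqrt(2)) / pixel_size
  resp <- convolve_2d(img, log_kernel(sigma_px))
  detect_spots_from_response(img, resp, params, pixel_size)
}

detect_spots_from_response <- function(img, resp, params, pixel_size) {
  thr <- if (identical(params$intensity_threshold, "auto")) {
    med <- stats::median(resp)
    # robust scale, floored at a small fraction of the response range so
    # that near-noiseless images (MAD ~ 0) do not admit every ripple
    scale <- max(stats::mad(resp), 0.02 * (max(resp) - med))
    med + params$auto_k * scale
  } else params$intensity_threshold
  H <- nrow(resp); W <- ncol(resp)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), est_diameter_um = numeric(0))
  if (H < 3 || W < 3) return(empty)
  inner <- resp[2:(H - 1), 2:(W - 1)]
  is_max <- inner > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- resp[2:(H - 1) + dr, 2:(W - 1) + dc]
    # strict on earlier neighbours in (row, col) scan order, >= on later:
    # deterministic plateau tie-break keeping the first pixel
    is_max <- is_max & if (dr < 0 || (dr == 0 && dc < 0)) inner > nb
                       else inner >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  vals <- resp[cbind(rows, cols)]
  ord <- order(-vals, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; vals <- vals[ord]
  # merge within min_separation, keeping the stronger (earlier) one
  min_sep_px <- params$min_separation / pixel_size
  keep <- rep(TRUE, length(rows))
  if (min_sep_px > 0 && length(rows) > 1) {
    for (i in 2:length(rows)) {
      prev <- which(keep[1:(i - 1)])
      if (length(prev) &&
          any((rows[prev] - rows[i])^2 + (cols[prev] - cols[i])^2 <
              min_sep_px^2))
        keep[i] <- FALSE
    }
  }
  rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
  # centroid window spans about one expected diameter
  half <- max(1L, as.integer(ceiling(
    params$expected_diameter / (2 * pixel_size))))
  cen <- vapply(seq_along(rows), function(i) {
    rs <- max(1L, rows[i] - half):min(H, rows[i] + half)
    cs <- max(1L, cols[i] - half):min(W, cols[i] + half)
    w <- img[rs, cs, drop = FALSE]
    border <- c(w[1, ], w[nrow(w), ], w[, 1], w[, ncol(w)])
    w <- pmax(w - stats::median(border), 0)
    tot <- sum(w)
    if (tot <= 0) return(c(rows[i], cols[i], params$expected_diameter))
    r_c <- sum(rowSums(w) * rs) / tot
    c_c <- sum(colSums(w) * cs) / tot
    var_r <- sum(rowSums(w) * (rs - r_c)^2) / tot
    var_c <- sum(colSums(w) * (cs - c_c)^2) / tot
    diam <- 2.355 * sqrt(max((var_r + var_c) / 2, 1e-12)) * pixel_size
    c(r_c, c_c, diam)
  }, numeric(3))
  data.frame(x_um = (cen[2, ] - 1) * pixel_size,
             y_um = (cen[1, ] - 1) * pixel_size,
             intensity = vals,
             est_diameter_um = cen[3, ])
}

#' Detect spots in every frame of a movie
#'
#' Applies [max_project()] and [detect_spots()] per time point. The LoG
#' response is computed once per frame with a kernel shared across frames.
#'
#' @param movie A `movie` array (frame, z, row, col), e.g. from
#'   [render_movie()] or [read_movie()].
#' @param params A [detection_params()] object.
#' @return Data frame with columns `frame` (0-based), `x_um`, `y_um`,
#'   `intensity`, `est_diameter_um`.
#' @export
detect_movie <- function(movie, params = detection_params()) {
  px <- attr(movie, "pixel_size_um")
  if (is.null(px)) stop("movie lacks pixel size calibration", call. = FALSE)
  d <- dim(movie)
  sigma_px <- params$expected_diameter / (2 * sqrt(2)) / px
  ker <- log_kernel(sigma_px)
  plan <- conv_plan(d[3:4], ker)
  out <- vector("list", d[1])
  for (f in seq_len(d[1])) {
    proj <- if (d[2] == 1L) matrix(movie[f, 1L, , ], d[3], d[4])
            else max_project(array(movie[f, , , ], dim = d[2:4]))
    resp <- conv_apply(proj, plan)
    det <- detect_spots_from_response(proj, resp, params, px)
    if (nrow(det)) det <- cbind(frame = f - 1L, det)
    out[[f]] <- det
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      est_diameter_um = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
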