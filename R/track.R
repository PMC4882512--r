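#' Link per-frame detections into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment: between each
#' consecutive pair of frames the assignment maximises the number of links
#' whose displacement is within `max_link_distance` and, among those,
#' minimises the total squared displacement (solved exactly with the
#' Hungarian algorithm on a cost matrix with birth/death slots). Unmatched
#' detections start new tracks; the result is independent of detection
#' order within a frame. With `max_gap > 0`, a terminated track may be
#' resumed within `max_gap` missed frames and the gap is closed by linear
#' interpolation.
#'
#' @param detections Data frame with columns `frame` (0-based), `x_um`,
#'   `y_um` (extra columns are ignored).
#' @param params A [linking_params()] object.
#' @param n_frames Total frames in the movie (defaults to
#'   `max(frame) + 1`).
#' @param frame_interval Frame interval in seconds (carried into the
#'   result).
#' @return A `track_set` with `provenance = "recovered"`.
#' @export
link_tracks <- function(detections, params = linking_params(),
                        n_frames = NULL, frame_interval = 2) {
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) + 1L else 0L
  if (!nrow(detections))
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     frame_interval, max(n_frames, 1L), "recovered"))
  gate2 <- params$max_link_distance^2
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  frames_present <- as.integer(names(by_frame))

  # active track state: id, last frame, last x, y
  next_id <- 1L
  track_of <- integer(nrow(detections))   # track id per detection row
  active <- data.frame(id = integer(0), frame = integer(0),
                       x = numeric(0), y = numeric(0))
  for (f in 0:(n_frames - 1L)) {
    ri <- by_frame[[as.character(f)]]
    if (is.null(ri)) ri <- integer(0)
    cur <- detections[ri, , drop = FALSE]
    live <- active[f - active$frame <= params$max_gap + 1L, , drop = FALSE]
    if (nrow(live) && nrow(cur)) {
      # gate scaled by the number of frames bridged
      span <- f - live$frame
      d2 <- outer(live$x, cur$x_um, "-")^2 + outer(live$y, cur$y_um, "-")^2
      allowed <- d2 <= gate2 * span^2
      m <- assign_links(d2, allowed)
    } else m <- rep(NA_integer_, nrow(live))
    matched_cur <- rep(FALSE, nrow(cur))
    if (nrow(live)) for (i in seq_len(nrow(live))) {
      j <- m[i]
      if (!is.na(j)) {
        track_of[ri[j]] <- live$id[i]
        matched_cur[j] <- TRUE
        k <- which(active$id == live$id[i])
        active$frame[k] <- f; active$x[k] <- cur$x_um[j]
        active$y[k] <- cur$y_um[j]
      }
    }
    if (any(!matched_cur)) {
      new_j <- which(!matched_cur)
      ids <- next_id + seq_along(new_j) - 1L
      next_id <- next_id + length(new_j)
      track_of[ri[new_j]] <- ids
      active <- rbind(active, data.frame(id = ids, frame = f,
                                         x = cur$x_um[new_j],
                                         y = cur$y_um[new_j]))
    }
    active <- active[f - active$frame <= params$max_gap, , drop = FALSE]
  }
  tr <- data.frame(track_id = track_of, frame = detections$frame,
                   x_um = detections$x_um, y_um = detections$y_um)
  tr <- tr[order(tr$track_id, tr$frame), ]
  if (params$max_gap > 0) tr <- close_gaps(tr)
  track_set(tr, frame_interval, n_frames, "recovered")
}

# linear interpolation across missed frames within a track
close_gaps <- function(tr) {
  out <- lapply(split(tr, tr$track_id), function(d) {
    full <- min(d$frame):max(d$frame)
    if (length(full) == nrow(d)) return(d)
    data.frame(track_id = d$track_id[1], frame = full,
               x_um = stats::approx(d$frame, d$x_um, full)$y,
               y_um = stats::approx(d$frame, d$y_um, full)$y)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Optimal gated assignment between rows (previous) and columns (current).
# Maximises the number of allowed links, then minimises total cost among
# maximum-cardinality assignments. Returns, per row, the matched column or
# NA. Decomposes into connected components of the gating graph before
# calling the Hungarian solver.
assign_links <- function(cost, allowed) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  res <- rep(NA_integer_, n1)
  if (!n1 || !n2) return(res)
  # connected components over the bipartite gating graph
  comp_r <- integer(n1); comp_c <- integer(n2); nc <- 0L
  for (r in seq_len(n1)) {
    if (comp_r[r]) next
    nc <- nc + 1L
    qr <- r
    while (length(qr)) {
      rr <- qr[1]; qr <- qr[-1]
      if (comp_r[rr]) next
      comp_r[rr] <- nc
      cs <- which(allowed[rr, ] & comp_c == 0L)
      comp_c[cs] <- nc
      for (ccol in cs) {
        nr <- which(allowed[, ccol] & comp_r == 0L)
        qr <- c(qr, nr)
      }
    }
  }
  for (k in seq_len(nc)) {
    rs <- which(comp_r == k); cs <- which(comp_c == k)
    if (!length(cs)) next
    if (length(rs) == 1L && length(cs) == 1L) {
      res[rs] <- cs
      next
    }
    sub <- matrix(Inf, length(rs), length(cs))
    sub[] <- cost[rs, cs]
    sub[!allowed[rs, cs, drop = FALSE]] <- NA
    m <- hungarian_gated(sub)
    res[rs] <- cs[m]
  }
  res
}

# Gated rectangular assignment: NA cells are forbidden. Maximise matches,
# then minimise summed cost, via Hungarian on a padded square matrix where
# every real link's cost is shifted down by a constant large enough that
# links always dominate births/deaths.
hungarian_gated <- function(cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  finite <- !is.na(cost)
  if (!any(finite)) return(rep(NA_integer_, n1))
  K <- (max(cost[finite]) + 1) * (n1 + n2 + 1)
  BIG <- K * (n1 + n2 + 1)
  s <- n1 + n2
  m <- matrix(BIG, s, s)
  m[1:n1, 1:n2][finite] <- cost[finite] - K
  for (i in seq_len(n1)) m[i, n2 + i] <- 0       # death of row i
  for (j in seq_len(n2)) m[n1 + j, j] <- 0       # birth of column j
  m[(n1 + 1):s, (n2 + 1):s] <- 0
  sol <- hungarian(m)
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && finite[i, j]) out[i] <- j
  }
  out
}

# Hungarian algorithm (Kuhn-Munkres with potentials, shortest augmenting
# path). cost: square numeric matrix, all finite. Returns the column
# assigned to each row of the minimum-cost perfect matching.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n); v <- numeric(n + 1)     # v[j+1], j = 0..n (0 virtual)
  p <- integer(n + 1)                      # p[j+1]: row matched to column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)                    # minv[j], j = 1..n
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1])
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      k <- free_j[which.min(minv[free_j])]
      delta <- minv[k]
      uj <- which(used)
      for (idx in uj) {
        jj <- idx - 1L
        u[p[idx]] <- u[p[idx]] + delta
        v[idx] <- v[idx] - delta
      }
      minv[free_j] <- minv[free_j] - delta
      j0 <- k
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  out[p[-1]] <- seq_len(n)
  out
}

#' Keep only tracks spanning the whole observation period
#'
#' Organelles not tracked for the entire observation period (first frame 0
#' through frame `n_frames - 1`, with no gaps) are removed, mirroring the
#' standard completeness filter applied before per-track speed analysis.
#'
#' @param ts A `track_set`.
#' @param n_frames Number of frames defining completeness (defaults to the
#'   track set's own `n_frames`).
#' @param quiet Suppress the log message.
#' @return The filtered `track_set`; the number of removed tracks is
#'   reported via `message()` and stored in attribute `n_removed`.
#' @export
filter_complete <- function(ts, n_frames = ts$n_frames, quiet = FALSE) {
  tr <- ts$tracks
  by_id <- split(tr$frame, tr$track_id)
  ok <- vapply(by_id, function(f)
    length(f) == n_frames && f[1] == 0L && f[length(f)] == n_frames - 1L,
    logical(1))
  keep <- names(by_id)[ok]
  n_removed <- sum(!ok)
  out <- ts
  out$tracks <- tr[tr$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out$tracks) <- NULL
  if (!is.null(ts$meta))
    out$meta <- ts$meta[ts$meta$track_id %in% as.integer(keep), ,
                        drop = FALSE]
  if (!quiet)
    message(n_removed, " of ", length(by_id),
            " tracks removed by the completeness filter")
  attr(out, "n_removed") <- n_removed
  out
}
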