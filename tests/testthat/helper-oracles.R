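# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration, direct formulas) and share no code with
# the package internals they check.

# All maximum-cardinality gated matchings, minimum total squared distance.
# prev, cur: data frames with x_um, y_um. Returns integer vector: per prev
# row the matched cur row or NA.
enumerate_assignment <- function(prev, cur, gate) {
  n1 <- nrow(prev); n2 <- nrow(cur)
  d2 <- outer(prev$x_um, cur$x_um, "-")^2 +
    outer(prev$y_um, cur$y_um, "-")^2
  allowed <- d2 <= gate^2
  best <- list(links = -1, cost = Inf, match = rep(NA_integer_, n1))
  recurse <- function(i, used, match, links, cost) {
    if (i > n1) {
      if (links > best$links ||
          (links == best$links && cost < best$cost)) {
        best <<- list(links = links, cost = cost, match = match)
      }
      return(invisible())
    }
    recurse(i + 1, used, match, links, cost)   # leave row i unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE; match[i] <- j
        recurse(i + 1, used, match, links + 1, cost + d2[i, j])
        used[j] <- FALSE; match[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, n2), rep(NA_integer_, n1), 0L, 0)
  best
}

# Direct run-length scan for saltatory events.
scan_events <- function(speeds, threshold) {
  n_events <- 0L; durations <- integer(0)
  run <- 0L
  for (s in speeds) {
    if (s > threshold) run <- run + 1L
    else if (run > 0L) {
      n_events <- n_events + 1L
      durations <- c(durations, run)
      run <- 0L
    }
  }
  if (run > 0L) {
    n_events <- n_events + 1L
    durations <- c(durations, run)
  }
  list(n = n_events, durations = durations)
}

# Asymmetric check loss of candidate q for level tau.
check_loss <- function(x, q, tau) {
  r <- x - q
  sum(r * (tau - (r < 0)))
}

# Minimal achievable check loss over a dense candidate set.
min_check_loss <- function(x, tau) {
  xs <- sort(unique(x))
  cand <- sort(c(xs, (xs[-1] + xs[-length(xs)]) / 2))
  min(vapply(cand, function(q) check_loss(x, q, tau), numeric(1)))
}

# A simple straight-line track data frame.
straight_track <- function(x, y = rep(0, length(x)), id = 1L) {
  data.frame(track_id = id, frame = seq_along(x) - 1L, x_um = x, y_um = y,
             s_um = x)
}
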