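test_that("a single detection per frame links into one track", {
  det <- data.frame(frame = 0:9, x_um = seq(0, 1.8, by = 0.2), y_um = 0)
  ts <- link_tracks(det, linking_params())
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(nrow(ts$tracks), 10)
})

test_that("parallel distant spots never swap identities", {
  det <- rbind(
    data.frame(frame = 0:19, x_um = seq(0, 3.8, by = 0.2), y_um = 0),
    data.frame(frame = 0:19, x_um = seq(0, 3.8, by = 0.2), y_um = 10))
  ts <- link_tracks(det, linking_params())
  expect_equal(length(unique(ts$tracks$track_id)), 2)
  for (d in split_tracks(ts))
    expect_equal(diff(range(d$y_um)), 0)
})

test_that("gating prevents swaps when tracks cross in y", {
  # two spots converge in y but each stays within the gate of its own
  # previous position and outside the other's
  f <- 0:10
  det <- rbind(
    data.frame(frame = f, x_um = 0.2 * f, y_um = 5 - 0.2 * f),
    data.frame(frame = f, x_um = 8 - 0.2 * f, y_um = 0.2 * f))
  ts <- link_tracks(det, linking_params(max_link_distance = 1))
  expect_equal(length(unique(ts$tracks$track_id)), 2)
  d1 <- split_tracks(ts)[[1]]
  expect_equal(diff(d1$x_um), rep(0.2, 10), tolerance = 1e-9)
})

test_that("optimal linker agrees with exhaustive enumeration", {
  set.seed(31)
  gate <- 2
  for (rep in 1:200) {
    n1 <- sample(0:5, 1); n2 <- sample(0:5, 1)
    prev <- data.frame(x_um = runif(n1, 0, 6), y_um = runif(n1, 0, 6))
    cur <- data.frame(x_um = runif(n2, 0, 6), y_um = runif(n2, 0, 6))
    got <- saltatrack:::assign_links(
      outer(prev$x_um, cur$x_um, "-")^2 +
        outer(prev$y_um, cur$y_um, "-")^2,
      (outer(prev$x_um, cur$x_um, "-")^2 +
         outer(prev$y_um, cur$y_um, "-")^2) <= gate^2)
    oracle <- enumerate_assignment(prev, cur, gate)
    expect_equal(sum(!is.na(got)), oracle$links)
    if (oracle$links > 0) {
      d2 <- outer(prev$x_um, cur$x_um, "-")^2 +
        outer(prev$y_um, cur$y_um, "-")^2
      got_cost <- sum(d2[cbind(which(!is.na(got)), got[!is.na(got)])])
      expect_equal(got_cost, oracle$cost, tolerance = 1e-9)
    }
  }
})

test_that("linking is invariant to detection order within frames", {
  set.seed(8)
  det <- data.frame(frame = rep(0:5, each = 3),
                    x_um = rep(c(0, 5, 10), 6) + rnorm(18, 0, 0.1),
                    y_um = rep(c(0, 1, 2), 6))
  shuffled <- det[sample(nrow(det)), ]
  a <- link_tracks(det, linking_params())
  b <- link_tracks(shuffled, linking_params())
  key <- function(ts) {
    d <- ts$tracks[order(ts$tracks$frame, ts$tracks$x_um), ]
    # compare the partition of points into tracks, not the id labels
    unname(split(paste(d$frame, round(d$x_um, 6)), d$track_id)[
      order(vapply(split(d$x_um, d$track_id), min, numeric(1)))])
  }
  expect_equal(key(a), key(b))
})

test_that("the completeness filter keeps exactly the full-length tracks", {
  n_frames <- 10
  full <- lapply(1:4, function(i)
    data.frame(track_id = i, frame = 0:9, x_um = i, y_um = 0))
  partial <- list(
    data.frame(track_id = 5, frame = 0:8, x_um = 5, y_um = 0),
    data.frame(track_id = 6, frame = 1:9, x_um = 6, y_um = 0),
    data.frame(track_id = 7, frame = c(0:3, 5:9), x_um = 7, y_um = 0))
  extra <- lapply(8:10, function(i)
    data.frame(track_id = i, frame = 2:6, x_um = i, y_um = 0))
  ts <- track_set(do.call(rbind, c(full, partial, extra)),
                  2, n_frames, "recovered")
  expect_message(out <- filter_complete(ts), "6 of 10")
  expect_setequal(unique(out$tracks$track_id), 1:4)
  # all-complete input passes through unchanged
  ts2 <- track_set(do.call(rbind, full), 2, n_frames, "recovered")
  out2 <- filter_complete(ts2, quiet = TRUE)
  expect_equal(out2$tracks, ts2$tracks)
})

test_that("recovered tracks match ground truth on well-separated movies", {
  p <- motion_params(frac_fast = 0.3, frac_slow = 0.5, frac_immobile = 0.2,
                     loc_noise_sd = 0)
  im <- imaging_params(duration = 40, n_z = 1, background = 5)
  ts <- simulate_tracks(p, im, 10, seed = 21)
  lay <- layout_tracks(ts, lane_spacing = 6)
  mov <- render_movie(lay$track_set, im, width_um = lay$width_um,
                      height_um = lay$height_um, noise = FALSE)
  res <- analyze_movie(mov, detection_params(),
                       linking_params(), motion_thresholds(),
                       layout = lay$layout)
  rec <- res$tracks$tracks
  expect_equal(length(unique(rec$track_id)), 10)
  # zero identity swaps: every recovered track stays in one lane, and the
  # positional RMSE against its lane's ground truth is sub-half-pixel
  for (d in split(rec, rec$track_id)) {
    lane_y <- lay$layout$y_center_um[
      which.min(abs(lay$layout$y_center_um - stats::median(d$y_um)))]
    truth_id <- lay$layout$track_id[lay$layout$y_center_um == lane_y]
    g <- lay$track_set$tracks[lay$track_set$tracks$track_id == truth_id, ]
    expect_true(all(abs(d$y_um - lane_y) < 3))
    rmse <- sqrt(mean((d$x_um - g$x_um)^2 + (d$y_um - g$y_um)^2))
    expect_lt(rmse, 0.5 * im$pixel_size)
  }
})
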