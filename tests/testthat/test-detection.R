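render_single_spot <- function(x_um, y_um, width_um = 6, height_um = 6,
                               imaging = imaging_params(duration = 2,
                                                        n_z = 1,
                                                        background = 2)) {
  ts <- track_set(data.frame(track_id = 1L, frame = 0L,
                             x_um = x_um, y_um = y_um),
                  frame_interval = 2, n_frames = 1, "ground_truth")
  mov <- render_movie(ts, imaging, width_um = width_um,
                      height_um = height_um, noise = FALSE)
  max_project(array(mov[1, , , ], dim = dim(mov)[2:4]))
}

test_that("max projection is the elementwise maximum across z", {
  set.seed(1)
  stack <- array(runif(4 * 10 * 12), dim = c(4, 10, 12))
  proj <- max_project(stack)
  for (z in 1:4) expect_true(all(proj >= stack[z, , ]))
  brute <- apply(stack, c(2, 3), max)
  expect_equal(proj, brute)
  # single-slice identity
  one <- array(stack[1, , ], dim = c(1, 10, 12))
  expect_equal(max_project(one), stack[1, , ])
  # disjoint bright pixels from different slices both survive
  s2 <- array(0, dim = c(2, 5, 5)); s2[1, 2, 2] <- 9; s2[2, 4, 4] <- 7
  p2 <- max_project(s2)
  expect_equal(p2[2, 2], 9)
  expect_equal(p2[4, 4], 7)
  expect_error(max_project(array(0, dim = c(0, 2, 2))), "non-empty")
})

test_that("a blank frame yields no detections", {
  det <- detect_spots(matrix(5, 40, 40), detection_params(),
                      pixel_size = 0.1)
  expect_equal(nrow(det), 0)
})

test_that("a rendered noiseless spot is recovered within half a pixel", {
  truth <- c(x = 2.83, y = 3.17)
  img <- render_single_spot(truth["x"], truth["y"])
  det <- detect_spots(img, detection_params(intensity_threshold = 1),
                      pixel_size = 0.1)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - truth["x"]), 0.05)
  expect_lt(abs(det$y_um - truth["y"]), 0.05)
})

test_that("two spots separated by five diameters give two detections", {
  im <- imaging_params(duration = 2, n_z = 1, background = 2)
  ts <- track_set(data.frame(track_id = 1:2, frame = 0L,
                             x_um = c(1.5, 1.5 + 5 * 0.75),
                             y_um = c(2, 2)),
                  frame_interval = 2, n_frames = 1, "ground_truth")
  mov <- render_movie(ts, im, width_um = 8, height_um = 4, noise = FALSE)
  proj <- max_project(array(mov[1, , , ], dim = dim(mov)[2:4]))
  det <- detect_spots(proj, detection_params(intensity_threshold = 1),
                      pixel_size = 0.1)
  expect_equal(nrow(det), 2)
})

test_that("detection count is non-increasing in the threshold", {
  set.seed(7)
  img <- matrix(rnorm(60 * 60, 10, 1), 60, 60)
  img[20, 20] <- 60; img[40, 45] <- 45; img[10, 50] <- 30
  counts <- vapply(c(0.5, 2, 5, 20, 60), function(th)
    nrow(detect_spots(img, detection_params(intensity_threshold = th),
                      pixel_size = 0.1)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("whole-pixel translation shifts detections equivariantly", {
  img <- render_single_spot(2.41, 2.87, width_um = 10, height_um = 10)
  shifted <- img
  shifted[] <- 2
  shifted[(1 + 7):nrow(img), (1 + 4):ncol(img)] <-
    img[1:(nrow(img) - 7), 1:(ncol(img) - 4)]
  p <- detection_params(intensity_threshold = 1)
  d0 <- detect_spots(img, p, pixel_size = 0.1)
  d1 <- detect_spots(shifted, p, pixel_size = 0.1)
  expect_equal(d1$x_um - d0$x_um, 4 * 0.1, tolerance = 1e-6)
  expect_equal(d1$y_um - d0$y_um, 7 * 0.1, tolerance = 1e-6)
})

test_that("frames smaller than the filter support raise an error", {
  expect_error(detect_spots(matrix(0, 3, 3), detection_params(),
                            pixel_size = 0.1), "filter support")
})

test_that("noiseless movies are detected with perfect recall and precision", {
  p <- motion_params(frac_fast = 0, frac_slow = 1, frac_immobile = 0,
                     loc_noise_sd = 0)
  im <- imaging_params(duration = 20, n_z = 2, background = 5)
  ts <- simulate_tracks(p, im, 8, seed = 6)
  lay <- layout_tracks(ts, lane_spacing = 3)
  mov <- render_movie(lay$track_set, im, width_um = lay$width_um,
                      height_um = lay$height_um, noise = FALSE)
  det <- detect_movie(mov, detection_params())
  # exactly one detection per ground-truth point, each within 0.5 px
  expect_equal(nrow(det), nrow(lay$track_set$tracks))
  for (f in unique(det$frame)) {
    d <- det[det$frame == f, ]
    g <- lay$track_set$tracks[lay$track_set$tracks$frame == f, ]
    dist <- sqrt(outer(d$x_um, g$x_um, "-")^2 +
                   outer(d$y_um, g$y_um, "-")^2)
    expect_true(all(apply(dist, 2, min) < 0.5 * im$pixel_size))
  }
})
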