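disc_image <- function(size, centres, radius, value = 100, bg = 0) {
  img <- matrix(bg, size, size)
  rr <- row(img); cc <- col(img)
  for (i in seq_len(nrow(centres)))
    img[(rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= radius^2] <-
      value
  img
}

test_that("a blank nucleus channel yields zero nuclei", {
  lab <- segment_nuclei(matrix(3, 64, 64))
  expect_equal(max(lab), 0)
})

test_that("disjoint nuclei are labelled with centroids within one pixel", {
  centres <- rbind(c(15, 15), c(15, 45), c(45, 30))
  img <- disc_image(64, centres, radius = 6, bg = 2)
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 3)
  for (i in 1:3) {
    pix <- which(lab == i, arr.ind = TRUE)
    cen <- colMeans(pix)
    d <- sqrt(rowSums((t(centres) - cen)^2))
    expect_lt(min(sqrt(colSums((t(centres) - cen)^2))), 1)
  }
})

test_that("touching nuclei merge into one label by default", {
  centres <- rbind(c(20, 20), c(20, 32))   # discs of r = 6 touch/overlap
  img <- disc_image(64, centres, radius = 6, bg = 2)
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 1)
})

test_that("cytoplasm of a nested disc pair is the annulus", {
  nuc <- disc_image(101, rbind(c(51, 51)), radius = 10, bg = 1)
  cell <- disc_image(101, rbind(c(51, 51)), radius = 30, bg = 1)
  nl <- segment_nuclei(nuc)
  cyto <- cytoplasm_regions(cell, nl)
  area <- sum(cyto == 1)
  expect_equal(area, pi * (30^2 - 10^2), tolerance = 0.05)
  # no cytoplasm pixel inside the nucleus, all inside the cell disc
  expect_equal(sum(cyto > 0 & nl > 0), 0)
})

test_that("well-separated cells give disjoint masks containing one nucleus
           each, and border-touching cells are dropped", {
  nuc_c <- rbind(c(30, 30), c(30, 90), c(90, 60), c(120, 5))
  cell_c <- nuc_c
  nuc <- disc_image(128, nuc_c, radius = 5, bg = 1)
  cell <- disc_image(128, cell_c, radius = 14, bg = 1)
  nl <- segment_nuclei(nuc)
  cyto <- cytoplasm_regions(cell, nl)
  labs <- setdiff(unique(as.vector(cyto)), 0)
  expect_equal(length(labs), 3)   # the cell at (120, 5) touches the border
  for (l in labs) {
    nuc_in <- unique(nl[cyto == l])
    expect_equal(sum(nuc_in > 0), 0)   # cytoplasm excludes nuclei
    # the territory around each cytoplasm ring encloses exactly label l
  }
  # disjointness: total labelled area is the sum of per-label areas
  expect_equal(sum(cyto > 0), sum(vapply(labs, function(l)
    sum(cyto == l), numeric(1))))
})

test_that("marker means recover constant and generative intensities", {
  nuc <- disc_image(101, rbind(c(51, 51)), radius = 10, bg = 1)
  cell <- disc_image(101, rbind(c(51, 51)), radius = 30, bg = 1)
  nl <- segment_nuclei(nuc)
  cyto <- cytoplasm_regions(cell, nl)
  flat <- matrix(42, 101, 101)
  r <- marker_means(flat, cyto, pixel_size = 0.5)
  expect_equal(r$records$marker_mean, 42)
  expect_equal(r$records$cytoplasm_area_um2, sum(cyto == 1) * 0.25)
  expect_equal(r$aggregate, 42)
  gated <- marker_means(flat, cyto, min_cells = 1000)
  expect_equal(gated$status, "too_few_cells")
  expect_true(is.na(gated$aggregate))
})

test_that("a noise-free field recovers exact per-cell marker levels and an
           empty field passes through", {
  p <- cell_field_params(n_cells = 6, marker_cell_sd = 0,
                         background = 0, pixel_noise_sd = 0,
                         field_size_px = 256)
  fld <- render_cell_field(p, "baseline", seed = 2)
  r <- quantify_field(fld)
  expect_equal(nrow(r$records), 6)
  expect_equal(r$records$marker_mean, rep(50, 6), tolerance = 1e-9)
  p0 <- cell_field_params(n_cells = 0)
  fld0 <- render_cell_field(p0, "baseline", seed = 1)
  r0 <- quantify_field(fld0)
  expect_equal(nrow(r0$records), 0)
})

test_that("a two-condition difference is recovered within noise", {
  p <- cell_field_params(n_cells = 8, marker_cell_sd = 2,
                         marker_mean_per_condition = c(lo = 50, hi = 70),
                         pixel_noise_sd = 2, field_size_px = 320)
  flo <- render_cell_field(p, "lo", seed = 5)
  fhi <- render_cell_field(p, "hi", seed = 6)
  rlo <- quantify_field(flo, condition = "lo")
  rhi <- quantify_field(fhi, condition = "hi")
  diff_rec <- rhi$aggregate - rlo$aggregate
  sem <- sqrt(stats::var(rhi$records$marker_mean) / nrow(rhi$records) +
                stats::var(rlo$records$marker_mean) / nrow(rlo$records))
  expect_lt(abs(diff_rec - 20), 3 * sem + 1)
})

test_that("unplaceable fields raise an explicit error", {
  p <- cell_field_params(n_cells = 50, cell_radius = 30,
                         field_size_px = 128)
  expect_error(render_cell_field(p, "baseline", seed = 1),
               "without overlap")
})

test_that("unknown fluorescence conditions are rejected", {
  p <- cell_field_params(n_cells = 1)
  expect_error(render_cell_field(p, "mystery", seed = 1),
               "unknown condition")
})
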