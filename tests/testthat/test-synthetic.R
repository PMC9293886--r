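test_that("brightfield rendering puts the ridge on the cell boundary", {
  sc <- synthetic_scene(cells = data.frame(center_r = 40, center_c = 40,
                                           a = 20, b = 20, theta = 0),
                        dim = c(80, 80), noise_sd = 0, seed = 1)
  bf <- make_brightfield(sc, ridge_amplitude = 0.5, background = 0.3)
  # on the circle: elevated; at center and far away: background
  expect_gt(bf$image[40, 60], 0.7)
  expect_lt(abs(bf$image[40, 40] - 0.3), 1e-3)
  expect_lt(abs(bf$image[5, 5] - 0.3), 1e-6)
  # mask is the filled circle
  expect_true(bf$mask[40, 40] == 1)
  expect_true(bf$mask[40, 59] == 1)
  expect_true(bf$mask[40, 61] == 0)
})

test_that("equal seeds give bit-identical images, for both modalities", {
  sc <- random_scene(n_cells = 3, foci_lambda = 2, noise_sd = 0.05, seed = 11)
  expect_identical(make_brightfield(sc)$image, make_brightfield(sc)$image)
  expect_identical(make_fluorescence(sc, 4)$stack, make_fluorescence(sc, 4)$stack)
  sc2 <- random_scene(n_cells = 3, foci_lambda = 2, noise_sd = 0.05, seed = 12)
  expect_false(identical(make_brightfield(sc)$image, make_brightfield(sc2)$image))
})

test_that("ground-truth mask has one connected component per cell", {
  sc <- random_scene(n_cells = 5, foci_lambda = 0, noise_sd = 0, seed = 4)
  bf <- make_brightfield(sc)
  # flood-fill oracle for component counting
  ncomp <- max(EBImage::bwlabel((bf$mask > 0) * 1))
  expect_equal(ncomp, 5)
})

test_that("overlapping cells are rejected", {
  sc <- synthetic_scene(cells = data.frame(center_r = c(40, 45),
                                           center_c = c(40, 45),
                                           a = 15, b = 15, theta = 0),
                        dim = c(80, 80), seed = 1)
  expect_error(make_brightfield(sc), "overlap")
})

test_that("fluorescence peak reaches background + amplitude (noiseless)", {
  rg <- single_focus_region(sigma = 3, amplitude = 0.4)
  sc_bg <- 0.25
  expect_lt(abs(max(rg$raw) - (sc_bg + 0.4)), 1e-6)
  # multi-slice stacks preserve the peak through the max projection
  ctr <- 46
  sc <- synthetic_scene(cells = data.frame(center_r = ctr, center_c = ctr,
                                           a = 38, b = 38, theta = 0),
                        foci = data.frame(cell = 1, center_r = ctr,
                                          center_c = ctr, sigma = 3,
                                          amplitude = 0.4, label = 1),
                        dim = c(90, 90), noise_sd = 0, seed = 5)
  fl <- make_fluorescence(sc, z_slices = 10)
  expect_lt(abs(max(max_project(fl$stack)) - (0.25 + 0.4)), 1e-6)
})

test_that("empty scene projects to flat background inside the cell", {
  sc <- synthetic_scene(cells = data.frame(center_r = 30, center_c = 30,
                                           a = 20, b = 20, theta = 0),
                        dim = c(60, 60), noise_sd = 0, seed = 2)
  fl <- make_fluorescence(sc, z_slices = 3)
  proj <- max_project(fl$stack)
  expect_true(all(abs(proj[fl$truth$cells == 1] - 0.25) < 1e-9))
})

test_that("recorded truth radius is the analytic curvature maximum sqrt(3) sigma", {
  # oracle: numerically maximize d2/dr2 exp(-r^2 / 2 sigma^2)
  for (sigma in c(2, 3.5, 5)) {
    d2 <- function(r) {
      h <- 1e-4
      f <- function(r) exp(-r^2 / (2 * sigma^2))
      (f(r + h) - 2 * f(r) + f(r - h)) / h^2
    }
    r_star <- stats::optimize(d2, c(sigma, 4 * sigma), maximum = TRUE)$maximum
    expect_lt(abs(r_star - sqrt(3) * sigma), 1e-3)
    sc <- synthetic_scene(cells = data.frame(center_r = 40, center_c = 40,
                                             a = 30, b = 30, theta = 0),
                          foci = data.frame(cell = 1, center_r = 40,
                                            center_c = 40, sigma = sigma,
                                            amplitude = 0.5, label = 1),
                          dim = c(80, 80), noise_sd = 0, seed = 1)
    tr <- make_fluorescence(sc, 1)$truth$foci$truth_radius
    expect_lt(abs(tr - sqrt(3) * sigma), 1e-6)
  }
})

test_that("foci only add intensity (noiseless conservation) and validation fires", {
  base_cells <- data.frame(center_r = 40, center_c = 40, a = 30, b = 30, theta = 0)
  sc0 <- synthetic_scene(base_cells, dim = c(80, 80), noise_sd = 0, seed = 9)
  sc1 <- synthetic_scene(base_cells,
                         foci = data.frame(cell = 1, center_r = 35, center_c = 44,
                                           sigma = 2.5, amplitude = 0.3, label = 1),
                         dim = c(80, 80), noise_sd = 0, seed = 9)
  p0 <- max_project(make_fluorescence(sc0, 3)$stack)
  p1 <- max_project(make_fluorescence(sc1, 3)$stack)
  expect_true(all(p1 - p0 > -1e-12))
  expect_error(synthetic_scene(base_cells,
                               foci = data.frame(cell = 1, center_r = 40,
                                                 center_c = 75, sigma = 2,
                                                 amplitude = 0.3, label = 1),
                               dim = c(80, 80)), "outside")
  expect_error(synthetic_scene(base_cells,
                               foci = data.frame(cell = 1, center_r = 40,
                                                 center_c = 42, sigma = -1,
                                                 amplitude = 0.3, label = 1),
                               dim = c(80, 80)), "sigma")
})

test_that("write_scene round-trips images and truth as plain files", {
  dir <- withr::local_tempdir()
  sc <- random_scene(n_cells = 2, foci_lambda = 1, noise_sd = 0.02, seed = 21)
  paths <- write_scene(sc, dir, z_slices = 3)
  expect_true(all(file.exists(unlist(paths))))
  tr <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(tr$pixel_size_nm, 40.7)
  stack <- tiff::readTIFF(paths$stack, all = TRUE)
  expect_length(stack, 3)
})
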