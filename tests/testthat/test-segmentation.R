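# Ring fixture: one circular cell rendered through the brightfield model.
ring_fixture <- function(radius = 20, dim = 80, noise_sd = 0, seed = 1) {
  sc <- synthetic_scene(cells = data.frame(center_r = dim / 2, center_c = dim / 2,
                                           a = radius, b = radius, theta = 0),
                        dim = c(dim, dim), noise_sd = noise_sd, seed = seed)
  make_brightfield(sc)
}

test_that("ridge detection covers the ring and ignores flat regions", {
  bf <- ring_fixture()
  ridges <- detect_ridges(bf$image)
  # the detected ridge stays within a band around the true circle
  idx <- which(ridges, arr.ind = TRUE)
  d <- abs(sqrt((idx[, 1] - 40)^2 + (idx[, 2] - 40)^2) - 20)
  expect_gt(nrow(idx), 50)
  expect_lt(max(d), 4)  # dilation by the filter scale
  # no response in the flat interior
  expect_false(any(ridges[30:50, 30:50][sqrt(outer((30:50 - 40)^2, (30:50 - 40)^2, "+")) < 10]))
})

test_that("constant images and dominating thresholds give empty ridge masks", {
  expect_warning(r <- detect_ridges(matrix(1, 20, 20)), "constant")
  expect_false(any(r))
  bf <- ring_fixture()
  r2 <- detect_ridges(bf$image, threshold = 1 + 1e-9)
  expect_false(any(r2))
})

test_that("mask cleaning filters by size, solidity and eccentricity", {
  m <- matrix(FALSE, 40, 40); m[5:6, 5:6] <- TRUE  # 4-px blob
  expect_false(any(clean_mask(m, min_size = 10)))
  # solid disc passes a tight solidity bound
  disc <- matrix(FALSE, 40, 40)
  disc[(row(disc) - 20)^2 + (col(disc) - 20)^2 <= 64] <- TRUE
  expect_true(any(clean_mask(disc, min_size = 10, solidity_bounds = c(0.9, 1))))
  # three blobs, one elongated: eccentricity bound keeps exactly two
  m3 <- matrix(FALSE, 60, 60)
  m3[(row(m3) - 12)^2 + (col(m3) - 12)^2 <= 25] <- TRUE
  m3[(row(m3) - 40)^2 + (col(m3) - 40)^2 <= 25] <- TRUE
  m3[10:12, 30:55] <- TRUE  # long thin bar
  cleaned <- clean_mask(m3, min_size = 10, eccentricity_bounds = c(0, 0.8))
  expect_equal(max(EBImage::bwlabel(cleaned * 1)), 2)
  # oracle: per-blob moments from EBImage agree with the decision
  lab <- EBImage::bwlabel(m3 * 1)
  fm <- EBImage::computeFeatures.moment(lab)
  ecc <- fm[, "m.eccentricity"]
  expect_equal(sum(ecc <= 0.8), 2)
})

test_that("thinning yields a 1-px skeleton on the ideal circle and keeps degenerate inputs", {
  ann <- matrix(FALSE, 60, 60)
  d <- sqrt((row(ann) - 30)^2 + (col(ann) - 30)^2)
  ann[d >= 18.5 & d <= 21.5] <- TRUE
  sk <- skeletonize_outlines(ann)
  expect_true(all(ann[sk]))            # subset of input
  idx <- which(sk, arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 30)^2 + (idx[, 2] - 30)^2)
  expect_lt(max(abs(rad - 20)), 1.6)   # within ~1 px of the ideal circle
  expect_false(any(skeletonize_outlines(matrix(FALSE, 5, 5))))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(skeletonize_outlines(single), single)
})

test_that("center scoring finds circle centers and rejects open arcs", {
  circ <- matrix(FALSE, 50, 50)
  d <- sqrt((row(circ) - 25)^2 + (col(circ) - 25)^2)
  circ[abs(d - 12) < 0.7] <- TRUE
  csm <- score_cell_centers(circ, r_min = 5, r_max = 20, stride = 1)
  expect_gt(length(csm$minima), 0)
  best <- csm$minima[[1]]
  expect_lt(sqrt(sum((best$point - c(25, 25))^2)), 2.5)
  # the error floor is the quantization of the ~1.4 px wide rasterized ring
  expect_lt(best$error, 0.25)
  # half circle: angular coverage excludes every candidate
  half <- circ & (col(circ) >= 25)
  csm2 <- score_cell_centers(half, r_min = 5, r_max = 20,
                             angular_coverage_min = 0.75, stride = 1)
  expect_length(csm2$minima, 0)
})

test_that("two tangent circles give exactly two center minima at the centers", {
  sk <- matrix(FALSE, 60, 110)
  d1 <- sqrt((row(sk) - 30)^2 + (col(sk) - 30)^2)
  d2 <- sqrt((row(sk) - 30)^2 + (col(sk) - 80)^2)
  sk[abs(d1 - 14) < 0.7 | abs(d2 - 14) < 0.7] <- TRUE
  csm <- score_cell_centers(sk, r_min = 6, r_max = 18, stride = 1)
  expect_length(csm$minima, 2)
  ctrs <- t(vapply(csm$minima, `[[`, numeric(2), "point"))
  found <- c(min(sqrt((ctrs[, 1] - 30)^2 + (ctrs[, 2] - 30)^2)),
             min(sqrt((ctrs[, 1] - 30)^2 + (ctrs[, 2] - 80)^2)))
  expect_lt(max(found), 3)
})

test_that("boundary snapping is a fixed point on the ring and recovers shrunken ellipses", {
  bf <- ring_fixture(radius = 20)
  on_ring <- snap_boundary(list(center = c(40, 40), axes = c(20, 20), theta = 0),
                           bf$image)
  rad <- sqrt(rowSums(sweep(on_ring$polygon, 2, c(40, 40))^2))
  expect_lt(max(abs(rad - 20)), 0.75)
  shrunk <- snap_boundary(list(center = c(40, 40), axes = c(18, 18), theta = 0),
                          bf$image)
  rad2 <- sqrt(rowSums(sweep(shrunk$polygon, 2, c(40, 40))^2))
  expect_lt(mean(abs(rad2 - 20)), 1)
  expect_false(shrunk$rejected)
  flat <- snap_boundary(list(center = c(40, 40), axes = c(18, 18), theta = 0),
                        matrix(0.5, 80, 80))
  expect_true(flat$rejected)
})

test_that("full segmentation recovers separated cells with IoU >= 0.9 deterministically", {
  sc <- random_scene(n_cells = 5, foci_lambda = 0, noise_sd = 0, seed = 3)
  bf <- make_brightfield(sc)
  p <- segmentation_params(r_min_nm = 10 * 40.7, r_max_nm = 26 * 40.7)
  ols <- segment_cells(bf$image, p)
  expect_length(ols, 5)
  ious <- vapply(ols, function(ol) {
    max(vapply(1:5, function(k) mask_iou(bf$mask == k, ol$mask), numeric(1)))
  }, numeric(1))
  expect_true(all(ious >= 0.9))
  # masks stay in bounds and overlap below tolerance
  for (i in seq_along(ols)) {
    expect_equal(dim(ols[[i]]$mask), dim(bf$image))
    for (j in seq_len(i - 1)) {
      ov <- sum(ols[[i]]$mask & ols[[j]]$mask) /
        min(sum(ols[[i]]$mask), sum(ols[[j]]$mask))
      expect_lt(ov, 0.2)
    }
  }
  # determinism: identical reruns
  ols2 <- segment_cells(bf$image, p)
  expect_identical(lapply(ols, `[[`, "polygon"), lapply(ols2, `[[`, "polygon"))
  # empty image: empty result
  expect_warning(none <- segment_cells(matrix(0.5, 64, 64), p), "constant")
  expect_length(none, 0)
})

test_that("externally produced masks bypass segmentation", {
  sc <- random_scene(n_cells = 3, foci_lambda = 0, noise_sd = 0, seed = 8)
  bf <- make_brightfield(sc)
  ols <- outlines_from_mask(bf$mask)
  expect_length(ols, 3)
  for (k in 1:3) expect_gt(mask_iou(bf$mask == k, ols[[k]]$mask), 0.99)
})
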