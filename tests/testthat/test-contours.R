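# Gaussian with half-height radius R has sigma = R / sqrt(2 log 2); contours
# of the normalized fixture at level 0.5 then lie on the circle of radius R.

test_that("loops are closed, sub-pixel, and match analytic circle perimeters", {
  R <- 8
  sigma <- R / sqrt(2 * log(2))
  rg <- single_focus_region(sigma = sigma, amplitude = 0.5)
  loops <- extract_loops(rg, 64)
  expect_gt(length(loops), 10)
  for (lp in loops) {
    expect_true(puncta:::is_closed_polygon(lp$vertices))
    expect_gt(lp$area, 0)
  }
  # the loop at level ~0.5 has perimeter ~ 2 pi R
  lv <- vapply(loops, `[[`, numeric(1), "level")
  lp <- loops[[which.min(abs(lv - 0.5))]]
  expect_lt(abs(lp$length - 2 * pi * R) / (2 * pi * R), 0.02)
})

test_that("a single bright pixel produces a closed loop around it", {
  mask <- matrix(TRUE, 15, 15)
  img <- matrix(0, 15, 15); img[8, 8] <- 1
  ol <- outlines_from_mask(mask)
  ol[[1]]$mask <- mask
  rg <- cell_region(img, ol[[1]])
  loops <- extract_loops(rg, 8)
  expect_gt(length(loops), 0)
  expect_true(all(vapply(loops, function(lp)
    puncta:::point_in_polygon(c(8, 8), lp$vertices), logical(1))))
})

test_that("extracted loops are pairwise nested or disjoint (never crossing)", {
  for (seed in 1:6) {
    reg <- two_focus_region(d = 10 + seed, seed = seed)$region
    loops <- extract_loops(reg, 32)
    n <- length(loops)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      a <- loops[[i]]$vertices; b <- loops[[j]]$vertices
      b_in_a <- puncta:::points_in_polygon(b[-nrow(b), , drop = FALSE], a)
      expect_true(all(b_in_a) || !any(b_in_a))
    }
  }
})

test_that("candidate construction finds exactly K planted foci (K = 0, 1, 2, 5)", {
  for (K in c(0, 1, 2, 5)) {
    rg <- k_focus_region(K)
    loops <- extract_loops(rg, 64)
    cands <- build_candidates(loops, L_min = 5, L_max = 70)
    expect_length(cands, K)
    for (cd in cands) {
      expect_lt(cd$outer$level, cd$inner$level)
      expect_gte(cd$inner$length, 5)
      expect_lte(cd$outer$length, 70)
      expect_true(puncta:::point_in_polygon(
        puncta:::loop_inner_point(cd$inner), cd$outer$vertices))
    }
  }
})

test_that("nearby peaks sharing an outer contour become separate candidates", {
  reg <- two_focus_region(d = 9)$region
  loops <- extract_loops(reg, 64)
  cands <- build_candidates(loops, L_min = 5, L_max = 70)
  expect_length(cands, 2)
  # both candidates share the same (longest qualifying) outer loop
  expect_equal(cands[[1]]$outer$level, cands[[2]]$outer$level)
  expect_equal(cands[[1]]$outer$area, cands[[2]]$outer$area)
})

test_that("length bounds dominate: all loops longer than L_max yield nothing", {
  rg <- k_focus_region(1)
  loops <- extract_loops(rg, 32)
  expect_length(build_candidates(loops, L_min = 1, L_max = 2), 0)
})

test_that("area function matches analytic level-set areas for cone and Gaussian", {
  # cone: I(r) = 1 - r/R  =>  a(I) = pi R^2 (1 - I)^2
  ctr <- 46; R <- 12
  sc <- synthetic_scene(cells = data.frame(center_r = ctr, center_c = ctr,
                                           a = 38, b = 38, theta = 0),
                        foci = data.frame(cell = 1, center_r = ctr, center_c = ctr,
                                          sigma = R / 3, amplitude = 0.6, label = 1),
                        dim = c(90, 90), noise_sd = 0, profile = "cone", seed = 1)
  fl <- make_fluorescence(sc, 1)
  rg <- cell_region(max_project(fl$stack), outlines_from_mask(fl$truth$cells)[[1]])
  loops <- extract_loops(rg, 64)
  cands <- build_candidates(loops, 5, 90)
  expect_length(cands, 1)
  af <- area_function(cands[[1]], rg, 32)
  expect_true(all(diff(af$area) <= 1e-9))          # monotone non-increasing
  probe <- af[af$I > 0.15 & af$I < 0.7, ]
  probe <- probe[round(seq(1, nrow(probe), length.out = 5)), ]
  expect_lt(max(abs(probe$area - pi * R^2 * (1 - probe$I)^2) /
                  (pi * R^2 * (1 - probe$I)^2)), 0.03)
  # Gaussian: a(I) = 2 pi sigma^2 ln(peak / I)
  sigma <- 3
  rg2 <- single_focus_region(sigma = sigma, amplitude = 0.5)
  loops2 <- extract_loops(rg2, 64)
  cands2 <- build_candidates(loops2, 5, 70)
  af2 <- area_function(cands2[[1]], rg2, 32)
  # keep contour radii >= ~3 px so polygonization error stays small
  probe2 <- af2[af2$I > 0.2 & af2$I < 0.6, ]
  probe2 <- probe2[round(seq(1, nrow(probe2), length.out = 5)), ]
  ana <- 2 * pi * sigma^2 * log(1 / probe2$I)
  expect_lt(max(abs(probe2$area - ana) / ana), 0.05)
})

test_that("curvature-maximum radius recovers sqrt(3) sigma within 10%", {
  for (sigma in c(2, 3, 4, 5)) {
    rg <- single_focus_region(sigma = sigma, amplitude = 0.5,
                              dim = if (sigma > 3) 120L else 90L,
                              cell_radius = if (sigma > 3) 52 else 38)
    det <- detect_foci(rg, L_min_nm = 4 * 40.7, L_max_nm = 75 * 40.7)
    expect_length(det$foci, 1)
    r_eq <- sqrt(det$foci[[1]]$area / pi)
    expect_lt(abs(r_eq - sqrt(3) * sigma) / (sqrt(3) * sigma), 0.10)
  }
})

test_that("I_opt is stable under +/-20% changes of the length bounds", {
  rg <- single_focus_region(sigma = 3, amplitude = 0.5)
  loops <- extract_loops(rg, 64)
  lopt <- function(lmin, lmax) {
    cand <- build_candidates(loops, lmin, lmax)[[1]]
    optimal_intensity(area_function(cand, rg, 32))$I_opt
  }
  base <- lopt(5, 60)
  grid_step <- 1 / 65
  expect_lt(abs(lopt(4, 48) - base), 2 * grid_step + 1e-9)
  expect_lt(abs(lopt(6, 72) - base), 2 * grid_step + 1e-9)
})

test_that("optimal_intensity falls back to the midpoint for tiny samples", {
  af <- data.frame(I = c(0.2, 0.4, 0.6), area = c(30, 20, 10))
  expect_warning(oi <- optimal_intensity(af), "fewer than 5")
  expect_true(oi$fallback)
  expect_equal(oi$I_opt, 0.4)
})

test_that("two-peak fixtures merge or split exactly as the saddle level predicts", {
  for (d in c(6.5, 7, 9, 12)) {
    fix <- two_focus_region(d = d, sigma = 3)
    rg <- fix$region
    # analytic saddle of the normalized two-Gaussian profile at the midpoint
    prof <- function(x) exp(-(x - d / 2)^2 / 18) + exp(-(x + d / 2)^2 / 18)
    peak_x <- stats::optimize(prof, c(0, d), maximum = TRUE)$maximum
    saddle_norm <- prof(0) / prof(peak_x)
    loops <- extract_loops(rg, 64)
    cands <- build_candidates(loops, 4, 70)
    expect_length(cands, 2)
    I_opt <- optimal_intensity(area_function(cands[[1]], rg, 32))$I_opt
    foci <- finalize_foci(cands, rg)
    if (I_opt < saddle_norm - 0.02) {
      expect_length(foci, 1)
    } else if (I_opt > saddle_norm + 0.02) {
      expect_length(foci, 2)
    }
  }
})

test_that("area_scale = 1 is the identity; other factors scale areas", {
  rg <- single_focus_region(sigma = 3, amplitude = 0.5)
  loops <- extract_loops(rg, 64)
  cands <- build_candidates(loops, 5, 70)
  f1 <- finalize_foci(cands, rg, area_scale = 1)
  f1b <- finalize_foci(cands, rg)
  expect_identical(f1[[1]]$contour$vertices, f1b[[1]]$contour$vertices)
  f2 <- finalize_foci(cands, rg, area_scale = 1.5)
  expect_equal(f2[[1]]$area / f1[[1]]$area, 1.5, tolerance = 1e-9)
})

test_that("final outlines within a cell are pairwise disjoint on random fixtures", {
  bad <- 0
  for (seed in 1:12) {
    sc <- random_scene(n_cells = 1, foci_lambda = 3, noise_sd = 0.01,
                       seed = 100 + seed)
    fl <- make_fluorescence(sc, 3)
    ols <- outlines_from_mask(fl$truth$cells)
    if (!length(ols)) next
    rg <- cell_region(max_project(fl$stack), ols[[1]])
    det <- detect_foci(rg, L_min_nm = 4 * 40.7, L_max_nm = 70 * 40.7)
    foci <- det$foci
    for (i in seq_along(foci)) for (j in seq_along(foci)) {
      if (i >= j) next
      ov <- puncta:::polygon_overlap_area(foci[[i]]$contour$vertices,
                                          foci[[j]]$contour$vertices)
      if (ov > 1e-6) bad <- bad + 1
    }
  }
  expect_equal(bad, 0)
})
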