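# Shared synthetic fixtures, built in code at test time.

# One circular cell with a single Gaussian focus of given sigma at center.
single_focus_region <- function(sigma = 3, amplitude = 0.5, noise_sd = 0,
                                dim = 90L, cell_radius = 38, seed = 1L) {
  ctr <- dim %/% 2 + 1
  sc <- synthetic_scene(
    cells = data.frame(center_r = ctr, center_c = ctr, a = cell_radius,
                       b = cell_radius, theta = 0),
    foci = data.frame(cell = 1, center_r = ctr, center_c = ctr,
                      sigma = sigma, amplitude = amplitude, label = 1),
    dim = c(dim, dim), noise_sd = noise_sd, seed = seed)
  fl <- make_fluorescence(sc, z_slices = 1)
  cell_region(max_project(fl$stack), outlines_from_mask(fl$truth$cells)[[1]],
              pixel_size = 40.7)
}

# Two Gaussian peaks (sigma fixed) separated by d px inside one cell.
two_focus_region <- function(d, sigma = 3, amplitude = 0.5, dim = 90L,
                             seed = 1L) {
  ctr <- dim %/% 2 + 1
  sc <- synthetic_scene(
    cells = data.frame(center_r = ctr, center_c = ctr, a = 38, b = 38,
                       theta = 0),
    foci = data.frame(cell = 1, center_r = c(ctr, ctr),
                      center_c = c(ctr - d / 2, ctr + d / 2),
                      sigma = sigma, amplitude = amplitude, label = 1),
    dim = c(dim, dim), noise_sd = 0, seed = seed)
  fl <- make_fluorescence(sc, z_slices = 1)
  list(region = cell_region(max_project(fl$stack),
                            outlines_from_mask(fl$truth$cells)[[1]]),
       scene = sc)
}

# A cell with K planted foci, well separated, all satisfying default bounds.
k_focus_region <- function(K, dim = 140L, sigma = 3, amplitude = 0.5,
                           seed = 1L) {
  ctr <- dim %/% 2 + 1
  foci <- NULL
  if (K > 0) {
    ang <- 2 * pi * (seq_len(K) - 1) / max(K, 1)
    rad <- if (K == 1) 0 else 0.55 * 60
    foci <- data.frame(cell = 1, center_r = ctr + rad * cos(ang),
                       center_c = ctr + rad * sin(ang),
                       sigma = sigma, amplitude = amplitude, label = 1)
  }
  sc <- synthetic_scene(
    cells = data.frame(center_r = ctr, center_c = ctr, a = 66, b = 66,
                       theta = 0),
    foci = foci, dim = c(dim, dim), noise_sd = 0, seed = seed)
  fl <- make_fluorescence(sc, z_slices = 1)
  cell_region(max_project(fl$stack), outlines_from_mask(fl$truth$cells)[[1]])
}

# Feature matrix of a synthetic labeled dataset: n candidates, 8-feature
# geometry-free stand-in columns, labels by a noiseless rule on f8. A small
# separation margin around the rule boundary makes the classes separable
# with finite samples (no candidate sits arbitrarily close to the rule).
rule_labeled_dataset <- function(n = 240, seed = 1L, margin = 0.06) {
  set.seed(seed)
  N <- ceiling(n * 1.8)
  x <- cbind(f1_max = runif(N), f1_min = runif(N, 0, 0.3),
             f1_mean = runif(N, 0.2, 0.8), f2_area = runif(N, 5, 80),
             f2_eccentricity = runif(N), f2_solidity = runif(N, 0.7, 1),
             f3_rel_size = runif(N, 0, 0.2), f4_ratio_pred = runif(N),
             f5_ratio_outer = runif(N, 0, 0.5), f6_abs_diff = runif(N),
             f7_center_dist = runif(N), f8_brightness_index = runif(N))
  x <- x[abs(x[, "f8_brightness_index"] - 0.5) > margin, , drop = FALSE][1:n, ]
  list(x = x, labels = as.integer(x[, "f8_brightness_index"] > 0.5))
}

# IoU between two logical masks.
mask_iou <- function(a, b) sum(a & b) / sum(a | b)
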