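# Seeded synthetic microscopy fixtures: elliptical cells with ridge-like
# brightfield edges, cytoplasmic fluorescence with dark vacuoles, and radial
# foci of known sigma/amplitude with per-focus ground truth. These images
# stand in for microscope data in all tests.

#' Describe a synthetic microscopy scene
#'
#' A scene lists elliptical cells, foci placed inside them, optional vacuole
#' discs, and global intensity parameters. The same scene renders both a
#' brightfield image ([make_brightfield()]) and a fluorescence z-stack
#' ([make_fluorescence()]), bit-identically for equal seeds.
#'
#' @param cells data.frame with columns `center_r`, `center_c` (px),
#'   `a`, `b` (semi-axes, px), `theta` (orientation, rad).
#' @param foci data.frame with columns `cell` (index into `cells`),
#'   `center_r`, `center_c` (px), `sigma` (px), `amplitude` (peak intensity
#'   above the cytoplasmic background, same units as `background_level`),
#'   `label` (ground-truth class, 0 or 1).
#' @param dim image dimension `c(rows, cols)`.
#' @param background_level cytoplasmic fluorescence intensity inside cells.
#' @param vacuoles data.frame with `center_r`, `center_c`, `radius` (px);
#'   vacuole discs carry almost no cytoplasmic signal.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param noise_model `"gaussian"` (additive) or `"poisson"`.
#' @param pixel_size physical pixel size in nm/px (default 40.7).
#' @param profile radial focus profile: `"gaussian"` (`A exp(-r^2/2 sigma^2)`,
#'   the reference model with an inflection point and a curvature maximum at
#'   `sqrt(3) sigma`) or `"cone"` (linear decay to zero at `3 sigma`, a profile
#'   without an inflection point, for edge-case tests).
#' @param seed integer seed controlling all rendered noise.
#' @return an object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(cells, foci = NULL, dim = c(192L, 192L),
                            background_level = 0.25, vacuoles = NULL,
                            noise_sd = 0, noise_model = c("gaussian", "poisson"),
                            pixel_size = 40.7, profile = c("gaussian", "cone"),
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  profile <- match.arg(profile)
  cells <- as.data.frame(cells)
  stopifnot(all(c("center_r", "center_c", "a", "b") %in% names(cells)))
  if (is.null(cells$theta)) cells$theta <- 0
  if (is.null(foci)) {
    foci <- data.frame(cell = integer(0), center_r = numeric(0),
                       center_c = numeric(0), sigma = numeric(0),
                       amplitude = numeric(0), label = integer(0))
  }
  foci <- as.data.frame(foci)
  if (nrow(foci)) {
    stopifnot(all(c("cell", "center_r", "center_c", "sigma", "amplitude") %in% names(foci)))
    if (is.null(foci$label)) foci$label <- 1L
    if (any(foci$sigma <= 0)) stop("focus sigma must be > 0")
    if (any(foci$amplitude < 0)) stop("focus amplitude must be >= 0")
    for (i in seq_len(nrow(foci))) {
      cl <- cells[foci$cell[i], ]
      dr <- foci$center_r[i] - cl$center_r
      dc <- foci$center_c[i] - cl$center_c
      u <- (dr * cos(cl$theta) + dc * sin(cl$theta)) / cl$a
      v <- (-dr * sin(cl$theta) + dc * cos(cl$theta)) / cl$b
      if (u^2 + v^2 >= 1)
        stop("focus ", i, " lies outside its cell's ellipse")
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(vacuoles))
    vacuoles <- data.frame(center_r = numeric(0), center_c = numeric(0), radius = numeric(0))
  structure(list(cells = cells, foci = foci, vacuoles = as.data.frame(vacuoles),
                 dim = as.integer(dim), background_level = background_level,
                 noise_sd = noise_sd, noise_model = noise_model,
                 pixel_size = pixel_size, profile = profile,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d px, %d cell(s), %d focus/foci, seed %d\n",
              x$dim[1], x$dim[2], nrow(x$cells), nrow(x$foci), x$seed))
  invisible(x)
}

# Normalized elliptical radius (rho = 1 on the boundary) and its gradient
# magnitude, for every pixel of an image, for one cell.
ellipse_rho <- function(dim, cell) {
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dr <- rr - cell$center_r; dc <- cc - cell$center_c
  ct <- cos(cell$theta); st <- sin(cell$theta)
  u <- (dr * ct + dc * st) / cell$a
  v <- (-dr * st + dc * ct) / cell$b
  rho <- sqrt(u^2 + v^2)
  gnorm <- sqrt((u * ct / cell$a - v * st / cell$b)^2 +
                (u * st / cell$a + v * ct / cell$b)^2) / pmax(rho, 1e-9)
  list(rho = rho, gnorm = pmax(gnorm, 1e-9))
}

add_noise <- function(img, scene, stream_offset) {
  if (scene$noise_sd <= 0 && scene$noise_model == "gaussian") return(img)
  with_seed(scene$seed + stream_offset, {
    if (scene$noise_model == "gaussian") {
      img + matrix(rnorm(length(img), 0, scene$noise_sd), nrow(img))
    } else {
      # Poisson shot noise: noise_sd sets the scale at the background level
      scale <- max(scene$background_level, 1e-6) / max(scene$noise_sd, 1e-6)^2
      matrix(stats::rpois(length(img), pmax(img, 0) * scale) / scale, nrow(img))
    }
  })
}

#' Render the brightfield image of a scene
#'
#' Each cell produces a bright ridge along its ellipse boundary over a flat
#' background; the ground-truth cell masks are returned alongside. Cell
#' boundary extraction consumes exactly this kind of image.
#'
#' @param scene a [synthetic_scene()].
#' @param ridge_amplitude ridge height above the background.
#' @param ridge_width Gaussian width of the ridge across the boundary (px).
#' @param background flat brightfield background intensity.
#' @param overlap_tol maximum tolerated overlap between any two cell masks
#'   (px); beyond it the scene is rejected, since the segmenter is not
#'   specified for merged cells.
#' @return list with `image` (numeric matrix) and `mask` (integer matrix,
#'   0 = background, k = cell k).
#' @export
make_brightfield <- function(scene, ridge_amplitude = 0.5, ridge_width = 1.5,
                             background = 0.3, overlap_tol = 0) {
  stopifnot(inherits(scene, "synthetic_scene"))
  img <- matrix(background, scene$dim[1], scene$dim[2])
  mask <- matrix(0L, scene$dim[1], scene$dim[2])
  masks <- vector("list", nrow(scene$cells))
  for (i in seq_len(nrow(scene$cells))) {
    er <- ellipse_rho(scene$dim, scene$cells[i, ])
    d <- (er$rho - 1) / er$gnorm  # approximate signed distance to boundary
    img <- img + ridge_amplitude * exp(-d^2 / (2 * ridge_width^2))
    masks[[i]] <- er$rho <= 1
  }
  for (i in seq_len(nrow(scene$cells))) {
    if (i > 1) {
      prev <- Reduce(`|`, masks[seq_len(i - 1)])
      if (sum(prev & masks[[i]]) > overlap_tol)
        stop("cells overlap beyond tolerance; the segmenter is not specified for merged cells")
    }
    mask[masks[[i]]] <- i
  }
  img <- add_noise(img, scene, stream_offset = 0L)
  list(image = img, mask = mask)
}

focus_profile <- function(r2, sigma, amplitude, profile) {
  if (profile == "gaussian") {
    amplitude * exp(-r2 / (2 * sigma^2))
  } else {
    amplitude * pmax(0, 1 - sqrt(r2) / (3 * sigma))
  }
}

#' Render the fluorescence z-stack of a scene
#'
#' Cell interiors carry the cytoplasmic `background_level`, vacuole discs are
#' nearly dark, and each focus adds a radially symmetric profile split across
#' slices by a Gaussian z-weight (max weight 1, so the max-projection peak
#' reaches `background_level + amplitude`). Per-slice noise is seeded.
#'
#' The returned ground truth records, per focus, the analytic
#' curvature-maximum boundary radius `sqrt(3) * sigma` for Gaussian profiles
#' (the radius where the second derivative of `exp(-r^2 / 2 sigma^2)` is
#' maximal); the cone profile has no curvature maximum and records `NA`.
#'
#' @param scene a [synthetic_scene()].
#' @param z_slices number of slices (>= 1).
#' @param sigma_z Gaussian width of the focus z-profile, in slices.
#' @return list with `stack` (rows x cols x z array), `truth` (list with
#'   `cells` mask matrix, `foci` data.frame incl. `truth_radius`, and
#'   `pixel_size`).
#' @export
make_fluorescence <- function(scene, z_slices = 10L, sigma_z = 1.5) {
  stopifnot(inherits(scene, "synthetic_scene"), z_slices >= 1)
  dim <- scene$dim
  base <- matrix(0, dim[1], dim[2])
  mask <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(scene$cells))) {
    er <- ellipse_rho(dim, scene$cells[i, ])
    inside <- er$rho <= 1
    base[inside] <- scene$background_level
    mask[inside] <- i
  }
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  for (v in seq_len(nrow(scene$vacuoles))) {
    vc <- scene$vacuoles[v, ]
    disc <- (rr - vc$center_r)^2 + (cc - vc$center_c)^2 <= vc$radius^2
    base[disc & mask > 0] <- scene$background_level * 0.05
  }
  z_centers <- with_seed(scene$seed + 1L,
                         runif(nrow(scene$foci), 1, z_slices))
  foci_imgs <- vector("list", nrow(scene$foci))
  for (f in seq_len(nrow(scene$foci))) {
    fo <- scene$foci[f, ]
    r2 <- (rr - fo$center_r)^2 + (cc - fo$center_c)^2
    foci_imgs[[f]] <- focus_profile(r2, fo$sigma, fo$amplitude, scene$profile)
  }
  stack <- array(0, c(dim[1], dim[2], z_slices))
  for (z in seq_len(z_slices)) {
    sl <- base
    for (f in seq_len(nrow(scene$foci))) {
      w <- if (z_slices == 1) 1 else exp(-(z - z_centers[f])^2 / (2 * sigma_z^2))
      sl <- sl + w * foci_imgs[[f]]
    }
    stack[, , z] <- sl
  }
  # ensure the z-profile attains weight 1 somewhere: rescale per focus
  if (nrow(scene$foci) && z_slices > 1) {
    for (f in seq_len(nrow(scene$foci))) {
      wmax <- max(exp(-((1:z_slices) - z_centers[f])^2 / (2 * sigma_z^2)))
      if (wmax < 1) {
        corr <- (1 - wmax) # add the missing fraction at the best slice
        zbest <- which.max(exp(-((1:z_slices) - z_centers[f])^2 / (2 * sigma_z^2)))
        stack[, , zbest] <- stack[, , zbest] + corr * foci_imgs[[f]]
      }
    }
  }
  for (z in seq_len(z_slices))
    stack[, , z] <- add_noise(stack[, , z], scene, stream_offset = 100L + z)
  truth_radius <- if (scene$profile == "gaussian")
    sqrt(3) * scene$foci$sigma else rep(NA_real_, nrow(scene$foci))
  truth <- list(cells = mask,
                foci = cbind(scene$foci, truth_radius = truth_radius),
                pixel_size = scene$pixel_size)
  list(stack = stack, truth = truth)
}

#' Generate a random multi-cell scene
#'
#' Places `n_cells` non-overlapping elliptical cells on a grid with jitter,
#' and seeds each with a random number of foci. Amplitudes span dim-to-bright
#' regimes (peak 0.6x to 2.4x the cytoplasmic background) so that both the
#' threshold pipeline and the SVM pipeline face ambiguous and unambiguous
#' candidates.
#'
#' @param n_cells number of cells.
#' @param foci_lambda Poisson mean of the per-cell focus count.
#' @param dim image dimension; enlarged automatically if the grid needs room.
#' @param noise_sd additive noise level.
#' @param seed integer seed.
#' @param ... passed to [synthetic_scene()].
#' @return a [synthetic_scene()].
#' @export
random_scene <- function(n_cells = 5L, foci_lambda = 2, dim = NULL,
                         noise_sd = 0.01, seed = 1L, ...) {
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  cellpitch <- 56
  if (is.null(dim)) dim <- c(nrow_grid, ncol_grid) * cellpitch + 16L
  with_seed(seed, {
    cells <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      gr <- (i - 1) %/% ncol_grid; gc <- (i - 1) %% ncol_grid
      data.frame(center_r = 8 + cellpitch * (gr + 0.5) + runif(1, -4, 4),
                 center_c = 8 + cellpitch * (gc + 0.5) + runif(1, -4, 4),
                 a = runif(1, 16, 22), b = runif(1, 13, 18),
                 theta = runif(1, 0, pi))
    }))
    foci <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      k <- stats::rpois(1, foci_lambda)
      if (k == 0) return(NULL)
      cl <- cells[i, ]
      out <- vector("list", k)
      for (j in seq_len(k)) {
        repeat {
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.55)
          dr <- rad * cl$a * cos(ang); dc <- rad * cl$b * sin(ang)
          r <- cl$center_r + dr * cos(cl$theta) - dc * sin(cl$theta)
          c <- cl$center_c + dr * sin(cl$theta) + dc * cos(cl$theta)
          u <- ((r - cl$center_r) * cos(cl$theta) + (c - cl$center_c) * sin(cl$theta)) / cl$a
          v <- (-(r - cl$center_r) * sin(cl$theta) + (c - cl$center_c) * cos(cl$theta)) / cl$b
          if (u^2 + v^2 < 0.64) break
        }
        amp <- runif(1, 0.15, 0.6)
        out[[j]] <- data.frame(cell = i, center_r = r, center_c = c,
                               sigma = runif(1, 2, 4), amplitude = amp,
                               label = as.integer(amp > 0.25))
      }
      do.call(rbind, out)
    }))
    vac <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      if (runif(1) > 0.5) return(NULL)
      cl <- cells[i, ]
      data.frame(center_r = cl$center_r + runif(1, -4, 4),
                 center_c = cl$center_c + runif(1, -4, 4),
                 radius = runif(1, 3, 6))
    }))
    synthetic_scene(cells, foci, dim = dim, noise_sd = noise_sd,
                    vacuoles = vac, seed = seed, ...)
  })
}

#' Write a scene's rendered images and ground truth to disk
#'
#' Writes the brightfield image and label mask as TIFF, the fluorescence
#' stack as a multi-page TIFF, and the ground truth (cells, foci, labels,
#' pixel size) as JSON. Coordinates in the JSON are 0-based (row, col).
#'
#' @param scene a [synthetic_scene()].
#' @param dir output directory (created if needed).
#' @param z_slices slices for the fluorescence stack.
#' @return invisibly, the list of written paths.
#' @export
write_scene <- function(scene, dir, z_slices = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bf <- make_brightfield(scene)
  fl <- make_fluorescence(scene, z_slices = z_slices)
  clamp <- function(x) pmin(pmax(x, 0), 1)
  paths <- list(
    brightfield = file.path(dir, "brightfield.tif"),
    mask = file.path(dir, "mask.tif"),
    stack = file.path(dir, "stack.tif"),
    truth = file.path(dir, "truth.json"))
  tiff::writeTIFF(clamp(bf$image), paths$brightfield)
  tiff::writeTIFF(bf$mask / 65535, paths$mask, bits.per.sample = 16L)
  tiff::writeTIFF(lapply(seq_len(dim(fl$stack)[3]),
                         function(z) clamp(fl$stack[, , z])), paths$stack)
  truth <- list(
    cells = lapply(seq_len(nrow(scene$cells)), function(i) {
      cl <- scene$cells[i, ]
      list(center = c(cl$center_r - 1, cl$center_c - 1),
           semi_axes = c(cl$a, cl$b), theta = cl$theta)
    }),
    foci = if (nrow(fl$truth$foci)) {
      f <- fl$truth$foci
      lapply(seq_len(nrow(f)), function(i)
        list(cell = f$cell[i] - 1L,
             center = c(f$center_r[i] - 1, f$center_c[i] - 1),
             sigma = f$sigma[i], amplitude = f$amplitude[i],
             label = f$label[i], truth_radius_px = f$truth_radius[i],
             truth_radius_nm = f$truth_radius[i] * scene$pixel_size))
    } else list(),
    pixel_size_nm = scene$pixel_size, seed = scene$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
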