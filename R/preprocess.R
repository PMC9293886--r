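# Fluorescence preprocessing: z-stack max-projection, non-local-means
# denoising, and extraction of per-cell normalized sub-images.

#' Maximum-intensity projection of a z-stack
#'
#' @param stack a rows x cols x z numeric array, or a list of equally sized
#'   matrices.
#' @return a 2-D matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    dims <- vapply(stack, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all slices must have the same shape")
    return(Reduce(pmax, stack))
  }
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3)
  out <- stack[, , 1]
  for (z in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , z])
  out
}

#' Non-local means denoising
#'
#' Classic pixelwise NLM: each output pixel is a weighted average of pixels
#' in a search window, weighted by the similarity of their surrounding
#' patches, `w = exp(-d2 / h^2)` with `d2` the mean squared patch difference
#' and `h = strength * range(image)`. Patch sums are computed for all window
#' offsets at once via integral images, so the cost is
#' `O(pixels * window^2)`.
#'
#' @param image 2-D numeric matrix.
#' @param patch_size odd patch edge length (px).
#' @param patch_distance search radius (px).
#' @param strength filter strength relative to the image intensity range;
#'   `0` returns the input unchanged.
#' @return denoised matrix of the same shape.
#' @export
denoise_nlm <- function(image, patch_size = 5L, patch_distance = 6L,
                        strength = 0.1) {
  stopifnot(is.matrix(image))
  if (patch_size < 1 || patch_distance < 1) stop("patch sizes must be positive")
  if (strength <= 0) return(image)
  rng <- diff(range(image))
  if (rng == 0) return(image)
  h2 <- (strength * rng)^2
  ph <- patch_size %/% 2L
  np <- (2 * ph + 1)^2
  box_sum <- function(m, h) {
    # sum over a (2h+1)^2 box, replicate-padded, via cumulative sums
    nr <- nrow(m); nc <- ncol(m)
    p <- m[c(rep(1, h), 1:nr, rep(nr, h)), c(rep(1, h), 1:nc, rep(nc, h))]
    cs <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- t(cs)
    cs <- rbind(0, cbind(0, cs))
    w <- 2 * h + 1
    cs[(w + 1):(w + nr), (w + 1):(w + nc)] - cs[1:nr, (w + 1):(w + nc)] -
      cs[(w + 1):(w + nr), 1:nc] + cs[1:nr, 1:nc]
  }
  wsum <- matrix(0, nrow(image), ncol(image))
  vsum <- matrix(0, nrow(image), ncol(image))
  for (dr in -patch_distance:patch_distance) {
    for (dc in -patch_distance:patch_distance) {
      shifted <- shift_mat(image, dr, dc, fill = NA)
      # replicate-fill the out-of-range band so diffs stay finite
      shifted[is.na(shifted)] <- image[is.na(shifted)]
      d2 <- box_sum((image - shifted)^2, ph) / np
      w <- exp(-d2 / h2)
      wsum <- wsum + w
      vsum <- vsum + w * shifted
    }
  }
  vsum / wsum
}

#' Construct a per-cell region from an image and a cell outline
#'
#' Crops the bounding box of the outline, records the raw patch untouched,
#' and min-max normalizes in-mask intensities to `[0, 1]` (a constant patch
#' normalizes to all zeros). For contouring, out-of-mask pixels are filled
#' with the in-mask minimum (`norm_filled`) so that iso-contours cannot hug
#' the mask edge.
#'
#' @param image 2-D fluorescence image (projected, optionally denoised).
#' @param outline a `cell_outline` (see [segment_cells()] /
#'   [outlines_from_mask()]).
#' @param pixel_size nm per px.
#' @return an object of class `cell_region` with fields `raw`, `normalized`,
#'   `norm_filled`, `mask`, `offset` (top-left pixel of the crop in the
#'   source image), `outline`, `pixel_size`.
#' @export
cell_region <- function(image, outline, pixel_size = 40.7) {
  m <- outline$mask
  stopifnot(all(dim(m) == dim(image)))
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  raw <- image[r0:r1, c0:c1, drop = FALSE]
  mask <- m[r0:r1, c0:c1, drop = FALSE]
  lo <- min(raw[mask]); hi <- max(raw[mask])
  if (hi > lo) norm <- (raw - lo) / (hi - lo) else norm <- raw * 0
  norm_filled <- norm
  norm_filled[!mask] <- if (hi > lo) 0 else 0
  norm[!mask] <- NA_real_
  structure(list(raw = raw, normalized = norm, norm_filled = norm_filled,
                 mask = mask, offset = c(r0, c0), outline = outline,
                 pixel_size = pixel_size),
            class = "cell_region")
}

#' Extract per-cell normalized regions from a fluorescence image
#'
#' @param image 2-D fluorescence image.
#' @param outlines list of `cell_outline` objects.
#' @param pixel_size nm per px.
#' @param min_area outlines below this area (px^2) are skipped with a warning.
#' @return list of [cell_region()] objects.
#' @export
extract_cells <- function(image, outlines, pixel_size = 40.7, min_area = 9) {
  out <- list()
  for (ol in outlines) {
    if (ol$area < min_area) {
      warning("skipping degenerate outline (area ", round(ol$area, 1), " px^2)")
      next
    }
    out[[length(out) + 1L]] <- cell_region(image, ol, pixel_size)
  }
  out
}
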