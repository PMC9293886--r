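# Colocalization between two channels: Pearson correlation per cell and per
# focus, and geometric relations (centroid/boundary distances, overlap) of
# foci pairs.

#' Per-cell Pearson correlation of two channels
#'
#' Pearson correlation over the in-mask pixels of the two raw patches. Both
#' regions must come from the same cell outline.
#'
#' @param ch0,ch1 [cell_region()]s of the two channels, same mask.
#' @return correlation in `[-1, 1]`, or `NA` for a constant channel.
#' @export
pearson_cell <- function(ch0, ch1) {
  stopifnot(all(dim(ch0$mask) == dim(ch1$mask)), all(ch0$mask == ch1$mask))
  a <- ch0$raw[ch0$mask]; b <- ch1$raw[ch1$mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Per-focus Pearson correlation
#'
#' Pearson correlation over the pixels inside one focus outline only.
#'
#' @param focus a `focus_outline`.
#' @param ch0,ch1 the two channel regions.
#' @return correlation, or `NA` with fewer than 4 in-focus pixels or a
#'   constant patch.
#' @export
pearson_focus <- function(focus, ch0, ch1) {
  m <- polygon_mask(focus$contour$vertices, dim(ch0$raw)) & ch0$mask
  if (sum(m) < 4) return(NA_real_)
  a <- ch0$raw[m]; b <- ch1$raw[m]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Pairwise geometry of two channels' foci
#'
#' For every pair (A x B): centroid distance, boundary distance (minimum
#' edge-to-edge distance, 0 when the contours overlap or touch), polygon
#' overlap area, and the overlap fraction of each partner. Additionally each
#' focus's nearest neighbor in the other channel (by centroid distance) is
#' reported. Distances/areas are returned both in px/px^2 and nm/nm^2.
#'
#' @param fociA,fociB lists of `focus_outline`s from the same cell.
#' @param pixel_size nm per px.
#' @return data.frame of pair records (empty if either channel is empty),
#'   with attribute `nearest` (per-focus nearest partner indices).
#' @export
pair_geometry <- function(fociA, fociB, pixel_size = 40.7) {
  empty <- data.frame(a = integer(0), b = integer(0),
                      centroid_dist_px = numeric(0), centroid_dist_nm = numeric(0),
                      boundary_dist_px = numeric(0), boundary_dist_nm = numeric(0),
                      overlap_px2 = numeric(0), overlap_nm2 = numeric(0),
                      overlap_frac_a = numeric(0), overlap_frac_b = numeric(0),
                      nearest_of_a = logical(0), nearest_of_b = logical(0))
  if (!length(fociA) || !length(fociB)) {
    attr(empty, "nearest") <- list(a = integer(0), b = integer(0))
    return(empty)
  }
  rows <- list()
  cd <- matrix(NA_real_, length(fociA), length(fociB))
  for (i in seq_along(fociA)) {
    for (j in seq_along(fociB)) {
      pa <- fociA[[i]]$contour$vertices; pb <- fociB[[j]]$contour$vertices
      cdist <- sqrt(sum((fociA[[i]]$centroid - fociB[[j]]$centroid)^2))
      cd[i, j] <- cdist
      bdist <- polygon_boundary_distance(pa, pb)
      ov <- if (bdist == 0) polygon_overlap_area(pa, pb) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        a = i, b = j,
        centroid_dist_px = cdist, centroid_dist_nm = cdist * pixel_size,
        boundary_dist_px = bdist, boundary_dist_nm = bdist * pixel_size,
        overlap_px2 = ov, overlap_nm2 = ov * pixel_size^2,
        overlap_frac_a = min(1, ov / fociA[[i]]$area),
        overlap_frac_b = min(1, ov / fociB[[j]]$area))
    }
  }
  out <- do.call(rbind, rows)
  nearest <- list(a = apply(cd, 1, which.min), b = apply(cd, 2, which.min))
  out$nearest_of_a <- out$b == nearest$a[out$a]
  out$nearest_of_b <- out$a == nearest$b[out$b]
  attr(out, "nearest") <- nearest
  out
}

#' Fit a trend between two foci properties
#'
#' Least-squares fit of `y ~ x` under a linear (`y = a + b x`), power
#' (`y = a x^b`, fitted on log-log scale) or exponential (`y = a exp(b x)`,
#' fitted on semi-log scale) family, with the coefficient of determination
#' evaluated on the original scale.
#'
#' @param x,y numeric vectors (>= 3 points; power/exponential require
#'   positive responses, power also positive x).
#' @param model one of `"linear"`, `"power"`, `"exponential"`.
#' @return list with `model`, `coefficients` (a, b), `r_squared`, `fitted`.
#' @export
trend_fit <- function(x, y, model = c("linear", "power", "exponential")) {
  model <- match.arg(model)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("degenerate x: constant")
  fit <- switch(model,
    linear = {
      f <- stats::lm(y ~ x)
      list(a = unname(coef(f)[1]), b = unname(coef(f)[2]),
           fitted = unname(stats::fitted(f)))
    },
    power = {
      stopifnot(all(x > 0), all(y > 0))
      f <- stats::lm(log(y) ~ log(x))
      a <- exp(unname(coef(f)[1])); b <- unname(coef(f)[2])
      list(a = a, b = b, fitted = a * x^b)
    },
    exponential = {
      stopifnot(all(y > 0))
      f <- stats::lm(log(y) ~ x)
      a <- exp(unname(coef(f)[1])); b <- unname(coef(f)[2])
      list(a = a, b = b, fitted = a * exp(b * x))
    })
  ss_res <- sum((y - fit$fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(model = model, coefficients = c(a = fit$a, b = fit$b),
       r_squared = r2, fitted = fit$fitted)
}

#' Full colocalization record for one cell
#'
#' @param ch0,ch1 channel regions (same outline).
#' @param foci0,foci1 classified foci of each channel.
#' @param cell_id identifier copied into the output.
#' @return list with `cell`, `pearson` (per cell), `pearson_foci0/1`
#'   (per focus), and `pairs` ([pair_geometry()]).
#' @export
coloc_cell <- function(ch0, ch1, foci0, foci1, cell_id = 1L) {
  list(cell = cell_id,
       pearson = pearson_cell(ch0, ch1),
       pearson_foci0 = vapply(foci0, pearson_focus, numeric(1), ch0, ch1),
       pearson_foci1 = vapply(foci1, pearson_focus, numeric(1), ch0, ch1),
       pairs = pair_geometry(foci0, foci1, ch0$pixel_size))
}
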