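# Per-candidate feature vectors for the classifier, and the dataset-level
# whitening + 0-1 rescaling applied before the SVM.

feature_names <- c("f1_max", "f1_min", "f1_mean", "f2_area",
                   "f2_eccentricity", "f2_solidity", "f3_rel_size",
                   "f4_ratio_pred", "f5_ratio_outer", "f6_abs_diff",
                   "f7_center_dist", "f8_brightness_index")

# Mean normalized intensity sampled along a polygon's vertices.
contour_mean_intensity <- function(region, poly) {
  v <- close_polygon(poly)
  v <- v[-nrow(v), , drop = FALSE]
  mean(bilinear(region$norm_filled, v[, 1], v[, 2]))
}

polygon_eccentricity <- function(poly, dim) {
  idx <- which(polygon_mask(poly, dim), arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  mask_eccentricity(idx)
}

polygon_solidity <- function(poly) {
  p <- close_polygon(poly)[-1, , drop = FALSE]
  h <- grDevices::chull(p)
  hull_area <- polygon_area(close_polygon(p[h, , drop = FALSE]))
  if (hull_area <= 0) return(1)
  min(1, polygon_area(p) / hull_area)
}

#' Extract the per-focus feature vector
#'
#' Twelve numbers in eight feature groups, computed on the per-cell
#' normalized patch (so they are invariant to affine rescaling of the raw
#' intensities): (1) max/min/mean intensity inside the final outline;
#' (2) area (px^2), eccentricity, solidity of the outline; (3) focus area /
#' cell area; (4) mean intensity on the predicted outline / center
#' intensity; (5) mean intensity on the outer (longest) contour / center
#' intensity; (6) center minus predicted-outline intensity; (7) centroid
#' distance to the cell centroid normalized by the cell's equivalent radius;
#' (8) brightness rank among the cell's candidates mapped to `[0, 1]`
#' (1 = brightest, 0 = dimmest; a lone candidate scores 1). The "center"
#' intensity is the maximum inside the inner contour.
#'
#' Feature 8 depends on the whole cell and is filled by
#' [extract_features_cell()]; [extract_features()] sets it to `NA`.
#'
#' @param candidate the source `focus_candidate` (first of
#'   `outline$candidates`).
#' @param outline the `focus_outline`.
#' @param region the [cell_region()].
#' @return named numeric vector, or `NULL` for degenerate outlines
#'   (area < 1 px^2).
#' @export
extract_features <- function(candidate, outline, region) {
  if (outline$area < 1) return(NULL)
  fm <- polygon_mask(outline$contour$vertices, dim(region$raw)) & region$mask
  vals <- region$norm_filled[fm]
  if (!length(vals))
    vals <- bilinear(region$norm_filled,
                     outline$centroid[1], outline$centroid[2])
  inner_mask <- polygon_mask(candidate$inner$vertices, dim(region$raw)) & region$mask
  center_int <- if (any(inner_mask)) max(region$norm_filled[inner_mask]) else max(vals)
  center_int <- max(center_int, 1e-9)
  pred_mean <- contour_mean_intensity(region, outline$contour$vertices)
  outer_mean <- contour_mean_intensity(region, candidate$outer$vertices)
  cell_area <- sum(region$mask)
  cell_ctr_idx <- which(region$mask, arr.ind = TRUE)
  cell_ctr <- colMeans(cell_ctr_idx)
  cell_radius <- sqrt(cell_area / pi)
  c(f1_max = max(vals), f1_min = min(vals), f1_mean = mean(vals),
    f2_area = outline$area,
    f2_eccentricity = polygon_eccentricity(outline$contour$vertices, dim(region$raw)),
    f2_solidity = polygon_solidity(outline$contour$vertices),
    f3_rel_size = outline$area / cell_area,
    f4_ratio_pred = min(1, pred_mean / center_int),
    f5_ratio_outer = min(1, outer_mean / center_int),
    f6_abs_diff = max(0, center_int - pred_mean),
    f7_center_dist = sqrt(sum((outline$centroid - cell_ctr)^2)) / cell_radius,
    f8_brightness_index = NA_real_)
}

#' Feature matrix for all foci of one cell
#'
#' Runs [extract_features()] per focus and fills the brightness index
#' (feature 8): peak intensities are ranked within the cell and mapped onto
#' `{0, 1/(n-1), ..., 1}`; a single candidate scores 1.
#'
#' @param foci list of `focus_outline`s ([finalize_foci()]).
#' @param region the [cell_region()].
#' @return numeric matrix (foci x features); rows of rejected (degenerate)
#'   foci are dropped, with the kept indices in attribute `kept`.
#' @export
extract_features_cell <- function(foci, region) {
  rows <- list(); kept <- integer(0)
  for (i in seq_along(foci)) {
    fv <- extract_features(foci[[i]]$candidates[[1]], foci[[i]], region)
    if (is.null(fv)) next
    rows[[length(rows) + 1L]] <- fv
    kept <- c(kept, i)
  }
  if (!length(rows))
    return(structure(matrix(numeric(0), 0, length(feature_names),
                            dimnames = list(NULL, feature_names)), kept = integer(0)))
  m <- do.call(rbind, rows)
  peak <- m[, "f1_max"]
  n <- nrow(m)
  m[, "f8_brightness_index"] <-
    if (n == 1) 1 else (rank(peak, ties.method = "first") - 1) / (n - 1)
  structure(m, kept = kept)
}

#' Whiten and 0-1 rescale a feature matrix
#'
#' Per feature: subtract the mean, divide by the standard deviation, then
#' min-max rescale to `[0, 1]`. The fitted scaler must be reapplied verbatim
#' to prediction-time data with [apply_scaler()]. Zero-variance features map
#' to a constant 0.5 with a warning.
#'
#' @param x numeric feature matrix (>= 2 rows).
#' @return list with `scaled` matrix and `scaler` (class `feature_scaler`).
#' @export
whiten_rescale <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning("zero-variance feature(s) mapped to 0.5: ",
            paste(colnames(x)[flat], collapse = ", "))
    sdv[flat] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  zmin <- apply(z, 2, min); zmax <- apply(z, 2, max)
  rngs <- zmax - zmin
  rngs[rngs == 0] <- 1
  scaled <- sweep(sweep(z, 2, zmin), 2, rngs, "/")
  scaled[, flat] <- 0.5
  scaler <- structure(list(mean = mu, sd = sdv, zmin = zmin, zrange = rngs,
                           flat = flat, features = colnames(x)),
                      class = "feature_scaler")
  list(scaled = scaled, scaler = scaler)
}

#' Apply a fitted feature scaler
#' @param scaler a `feature_scaler` from [whiten_rescale()].
#' @param x feature matrix with the same columns as at fitting time.
#' @return scaled matrix (values can leave `[0, 1]` for unseen data).
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (!is.null(scaler$features) && !is.null(colnames(x)))
    x <- x[, scaler$features, drop = FALSE]
  z <- sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
  out <- sweep(sweep(z, 2, scaler$zmin), 2, scaler$zrange, "/")
  out[, scaler$flat] <- 0.5
  out
}
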