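# Core foci detection: candidates as nested closed iso-intensity contour
# loops of bounded length, and the parameterless final outline at the
# intensity where the curvature of the reconstructed radial profile peaks.
#
# Contour loops at different levels around the same point never cross: they
# are equal, disjoint, or nested. Clumped foci therefore need no explicit
# segmentation step; nearby candidates merge or separate on their own when
# the final outlines are drawn.

contour_loop <- function(vertices, level) {
  vertices <- close_polygon(vertices)
  structure(list(vertices = vertices, level = level,
                 length = polygon_perimeter(vertices),
                 area = polygon_area(vertices)),
            class = "contour_loop")
}

#' @export
print.contour_loop <- function(x, ...) {
  cat(sprintf("contour_loop: level %.4f, length %.2f px, area %.2f px^2\n",
              x$level, x$length, x$area))
  invisible(x)
}

# All closed marching-squares contours of `img` at `levels` that lie fully
# inside `mask` (if given) and away from the patch border.
closed_contours_at <- function(img, levels, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  cl <- grDevices::contourLines(seq_len(nr), seq_len(nc), img, levels = levels)
  out <- list()
  for (cc in cl) {
    n <- length(cc$x)
    if (n < 4) next
    if (abs(cc$x[1] - cc$x[n]) > 1e-9 || abs(cc$y[1] - cc$y[n]) > 1e-9) next
    v <- cbind(cc$x, cc$y)
    if (min(v[, 1]) <= 1 || max(v[, 1]) >= nr ||
        min(v[, 2]) <= 1 || max(v[, 2]) >= nc) next
    if (!is.null(mask)) {
      px <- cbind(pmin(pmax(round(v[, 1]), 1), nr),
                  pmin(pmax(round(v[, 2]), 1), nc))
      if (!all(mask[px])) next
    }
    lp <- contour_loop(v, cc$level)
    if (lp$area <= 0) next
    out[[length(out) + 1L]] <- lp
  }
  out
}

#' Extract closed contour loops from a cell region
#'
#' Runs marching squares on the normalized (mask-filled) patch at `n_levels`
#' evenly spaced intensity levels in (0, 1) and keeps closed loops lying
#' fully inside the cell mask, each annotated with its level, perimeter
#' length (px) and enclosed area (px^2).
#'
#' @param region a [cell_region()].
#' @param n_levels number of iso-intensity levels (>= 8).
#' @return list of `contour_loop` objects, ordered by level.
#' @export
extract_loops <- function(region, n_levels = 64L) {
  stopifnot(inherits(region, "cell_region"), n_levels >= 8)
  levels <- seq_len(n_levels) / (n_levels + 1)
  loops <- closed_contours_at(region$norm_filled, levels, region$mask)
  loops[order(vapply(loops, `[[`, numeric(1), "level"))]
}

# Representative interior point of a loop: its centroid if inside, else the
# midpoint of the first edge nudged inward, else the first vertex.
loop_inner_point <- function(loop) {
  ctr <- polygon_centroid(loop$vertices)
  if (point_in_polygon(ctr, loop$vertices)) return(ctr)
  loop$vertices[1, ]
}

# containment[i, j]: loop i strictly contains loop j.
loop_containment <- function(loops) {
  n <- length(loops)
  m <- matrix(FALSE, n, n)
  if (n < 2) return(m)
  pts <- t(vapply(loops, loop_inner_point, numeric(2)))
  areas <- vapply(loops, `[[`, numeric(1), "area")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || areas[i] <= areas[j]) next
      m[i, j] <- point_in_polygon(pts[j, ], loops[[i]]$vertices)
    }
  }
  m
}

#' Build focus candidates from a cell's contour loops
#'
#' A candidate is a tuple of an outer and a contained inner loop. The inner
#' loops are the innermost loops with length at least `L_min` (those not
#' containing another such loop); each is paired with the longest containing
#' loop of length at most `L_max`. An outer loop containing several inner
#' loops yields one candidate per inner loop; such candidates merge or stay
#' separate when the final outlines are computed.
#'
#' @param loops list of `contour_loop`s from one cell ([extract_loops()]).
#' @param L_min,L_max perimeter bounds (px), `0 < L_min < L_max`.
#' @return list of `focus_candidate` objects (`outer`, `inner`).
#' @export
build_candidates <- function(loops, L_min, L_max) {
  stopifnot(L_min > 0, L_max > L_min)
  n <- length(loops)
  if (n == 0) return(list())
  len <- vapply(loops, `[[`, numeric(1), "length")
  lev <- vapply(loops, `[[`, numeric(1), "level")
  contains <- loop_containment(loops)
  inner_ok <- len >= L_min
  is_inner <- inner_ok & !vapply(seq_len(n), function(i)
    any(contains[i, ] & inner_ok), logical(1))
  out <- list()
  for (j in which(is_inner)) {
    holders <- which(contains[, j] & len <= L_max)
    if (!length(holders)) next
    k <- holders[which.max(len[holders])]
    if (lev[k] >= lev[j]) next
    out[[length(out) + 1L]] <- structure(
      list(outer = loops[[k]], inner = loops[[j]]), class = "focus_candidate")
  }
  out
}

#' @export
print.focus_candidate <- function(x, ...) {
  cat(sprintf("focus_candidate: outer level %.3f (L=%.1f px), inner level %.3f (L=%.1f px)\n",
              x$outer$level, x$outer$length, x$inner$level, x$inner$length))
  invisible(x)
}

#' Sample the contour area function of a candidate
#'
#' Evaluates, at `n_eval` intensities between the outer and inner levels, the
#' area of the contour containing the candidate's inner loop. The result is
#' a monotone non-increasing piecewise-linear `a(I)`.
#'
#' @param candidate a `focus_candidate`.
#' @param region its [cell_region()].
#' @param n_eval number of sampled intensities.
#' @return data.frame with columns `I` and `area`; attribute `n_skipped`
#'   counts levels whose contour was broken by the mask.
#' @export
area_function <- function(candidate, region, n_eval = 32L) {
  I0 <- candidate$outer$level; I1 <- candidate$inner$level
  stopifnot(I0 < I1)
  pt <- loop_inner_point(candidate$inner)
  levels <- seq(I0, I1, length.out = n_eval)
  areas <- rep(NA_real_, n_eval)
  areas[1] <- candidate$outer$area
  areas[n_eval] <- candidate$inner$area
  for (i in 2:(n_eval - 1)) {
    cs <- closed_contours_at(region$norm_filled, levels[i], region$mask)
    hit <- NULL
    for (lp in cs)
      if (point_in_polygon(pt, lp$vertices) &&
          (is.null(hit) || lp$area < hit$area)) hit <- lp
    if (!is.null(hit)) areas[i] <- hit$area
  }
  n_skipped <- sum(is.na(areas))
  if (n_skipped) warning(n_skipped, " level(s) skipped: contour broken by mask")
  keep <- !is.na(areas)
  levels <- levels[keep]; areas <- areas[keep]
  # enforce monotone non-increase (resolve numeric ties/inversions)
  for (i in rev(seq_along(areas))[-1]) areas[i] <- max(areas[i], areas[i + 1])
  out <- data.frame(I = levels, area = areas)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Intensity of maximal radial-profile curvature
#'
#' Converts the sampled area function to an equivalent radius
#' `r(I) = sqrt(a(I) / pi)` and inverts the monotone map to get the radial
#' intensity profile `I(r)`. The profile is fitted with a low-rank smoothing
#' spline (the radial decay of a focus a few pixels across is smooth and
#' unimodal, while the sampled areas carry pixel-level wiggle from the
#' marching-squares polygonization) whose analytic second derivative
#' `d^2 I / d r^2` is evaluated on a dense radius grid; the returned
#' intensity sits at its global maximum — the curvature-maximum boundary
#' level. For a Gaussian focus this radius is `sqrt(3) * sigma`. Ties pick
#' the lower intensity (larger contour).
#'
#' @param af area function from [area_function()].
#' @param n_grid radius grid resolution for the argmax search.
#' @param spline_df degrees of freedom of the smoothing spline.
#' @return list with `I_opt`, `r_opt` (px), and `fallback` (TRUE when fewer
#'   than 5 valid samples forced the midpoint fallback).
#' @export
optimal_intensity <- function(af, n_grid = 128L, spline_df = 6) {
  if (nrow(af) < 5) {
    warning("fewer than 5 area samples; falling back to midpoint intensity")
    return(list(I_opt = mean(range(af$I)), r_opt = NA_real_, fallback = TRUE))
  }
  r <- sqrt(af$area / pi)
  I <- af$I
  # r is non-increasing in I; build I(r) on an increasing r grid
  ord <- order(r)
  r_s <- r[ord]; I_s <- I[ord]
  dup <- duplicated(r_s)
  r_s <- r_s[!dup]; I_s <- I_s[!dup]
  if (length(r_s) < 5)
    return(list(I_opt = mean(range(af$I)), r_opt = NA_real_, fallback = TRUE))
  fit <- stats::smooth.spline(r_s, I_s, df = min(spline_df, length(r_s) - 2))
  rg <- seq(min(r_s), max(r_s), length.out = n_grid)
  d2 <- stats::predict(fit, rg, deriv = 2)$y
  # the curvature maximum is an interior feature by construction
  # (I_k < I_opt < I_j); exclude the spline's unconstrained boundary zone
  span <- diff(range(r_s))
  valid <- rg > min(r_s) + 0.05 * span & rg < max(r_s) - 0.05 * span
  d2v <- d2[valid]
  # global max; ties -> lower intensity = larger radius = later index
  best <- which(d2v >= max(d2v) - 1e-15)
  i_star <- which(valid)[best[length(best)]]
  r_opt <- rg[i_star]
  I_opt <- stats::approx(r_s, I_s, xout = r_opt)$y
  eps <- diff(range(af$I)) * 1e-3
  I_opt <- min(max(I_opt, min(af$I) + eps), max(af$I) - eps)
  list(I_opt = I_opt, r_opt = r_opt, fallback = FALSE)
}

focus_outline <- function(contour, candidate, region, I_opt) {
  mask <- polygon_mask(contour$vertices, dim(region$raw)) & region$mask
  vals <- region$raw[mask]
  if (!length(vals)) vals <- NA_real_
  structure(list(contour = contour, level = I_opt,
                 area = contour$area,
                 centroid = polygon_centroid(contour$vertices),
                 intensity_max = max(vals), intensity_min = min(vals),
                 intensity_mean = mean(vals),
                 candidates = list(candidate)),
            class = "focus_outline")
}

#' @export
print.focus_outline <- function(x, ...) {
  cat(sprintf("focus_outline: level %.3f, area %.2f px^2, centroid (%.1f, %.1f)\n",
              x$level, x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Compute final outlines for a cell's candidates
#'
#' For each candidate the contour at its curvature-maximum intensity is
#' extracted; candidates whose final contours coincide (each contains the
#' other's inner loop) merge into a single focus. Areas can be adjusted by a
#' fixed factor (`area_scale`) by radially scaling the contour about its
#' centroid. Intensity statistics are computed on the raw patch.
#'
#' @param candidates list of `focus_candidate`s from one cell.
#' @param region their [cell_region()].
#' @param area_scale fixed area adjustment factor (1 = none).
#' @param n_eval area-function sampling density.
#' @return list of `focus_outline` objects, pairwise disjoint.
#' @export
finalize_foci <- function(candidates, region, area_scale = 1, n_eval = 32L) {
  n <- length(candidates)
  if (n == 0) return(list())
  finals <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- candidates[[i]]
    af <- area_function(cand, region, n_eval)
    oi <- optimal_intensity(af)
    pt <- loop_inner_point(cand$inner)
    cs <- closed_contours_at(region$norm_filled, oi$I_opt, region$mask)
    hit <- NULL
    for (lp in cs)
      if (point_in_polygon(pt, lp$vertices) &&
          (is.null(hit) || lp$area < hit$area)) hit <- lp
    if (is.null(hit)) hit <- cand$inner  # mask-broken level: keep inner loop
    finals[[i]] <- focus_outline(hit, cand, region, oi$I_opt)
  }
  # merge candidates whose final contours contain each other's peaks
  group <- seq_len(n)
  pts <- t(vapply(candidates, function(cd) loop_inner_point(cd$inner), numeric(2)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (point_in_polygon(pts[j, ], finals[[i]]$contour$vertices) ||
          point_in_polygon(pts[i, ], finals[[j]]$contour$vertices)) {
        g <- min(group[i], group[j])
        group[group %in% c(group[i], group[j])] <- g
      }
    }
  }
  out <- list()
  for (g in unique(group)) {
    members <- which(group == g)
    areas <- vapply(members, function(i) finals[[i]]$area, numeric(1))
    keep <- finals[[members[which.max(areas)]]]
    keep$candidates <- lapply(members, function(i) candidates[[i]])
    if (area_scale != 1) {
      sc <- contour_loop(scale_polygon_area(keep$contour$vertices, area_scale),
                         keep$level)
      keep$contour <- sc
      keep$area <- sc$area
      keep$centroid <- polygon_centroid(sc$vertices)
    }
    out[[length(out) + 1L]] <- keep
  }
  out
}

#' Detect foci in a cell region
#'
#' Convenience chain: [extract_loops()], [build_candidates()],
#' [finalize_foci()]. Length bounds are given in nm and converted to px via
#' the region's pixel size, so settings transfer across magnifications.
#'
#' @param region a [cell_region()].
#' @param L_min_nm,L_max_nm contour length bounds (nm).
#' @param n_levels,n_eval sampling densities.
#' @param area_scale fixed area adjustment factor.
#' @return list with `loops`, `candidates`, `foci`.
#' @export
detect_foci <- function(region, L_min_nm = 250, L_max_nm = 2500,
                        n_levels = 64L, n_eval = 32L, area_scale = 1) {
  L_min <- L_min_nm / region$pixel_size
  L_max <- L_max_nm / region$pixel_size
  loops <- extract_loops(region, n_levels)
  candidates <- build_candidates(loops, L_min, L_max)
  foci <- finalize_foci(candidates, region, area_scale, n_eval)
  list(loops = loops, candidates = candidates, foci = foci)
}
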