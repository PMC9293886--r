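# Cell segmentation from brightfield images: Frangi ridge detection,
# blob cleaning, Zhang-Suen thinning, ellipse-fit center scoring and
# active-contour boundary snapping.

#' Frangi vesselness ridge detection
#'
#' Computes the 2-D Frangi vesselness from the scale-normalized Hessian
#' eigenvalues at each scale in `scale_range` and takes the per-pixel
#' maximum, then thresholds it into a binary ridge mask. Brightfield cell
#' edges appear as bright or dark rings depending on focus; set
#' `invert = TRUE` for dark ridges.
#'
#' @param brightfield 2-D grayscale matrix.
#' @param scale_range Gaussian scales (px) of the Hessian.
#' @param threshold vesselness threshold in `[0, 1]` of the response maximum
#'   when `relative = TRUE` (default), absolute otherwise.
#' @param beta blobness sensitivity of the vesselness measure.
#' @param invert detect dark ridges instead of bright ones.
#' @param relative interpret `threshold` relative to the maximum response.
#' @return logical ridge mask.
#' @export
detect_ridges <- function(brightfield, scale_range = c(1, 1.5, 2),
                          threshold = 0.25, beta = 0.5, invert = FALSE,
                          relative = TRUE) {
  stopifnot(is.matrix(brightfield))
  img <- if (invert) -brightfield else brightfield
  if (length(img) == 0 || diff(range(img)) == 0) {
    warning("constant or empty image: no ridges")
    return(matrix(FALSE, nrow(brightfield), ncol(brightfield)))
  }
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scale_range) {
    sm <- gauss_smooth(img, s)
    nr <- nrow(sm); nc <- ncol(sm)
    Hrr <- sm[c(2:nr, nr), ] - 2 * sm + sm[c(1, 1:(nr - 1)), ]
    Hcc <- sm[, c(2:nc, nc)] - 2 * sm + sm[, c(1, 1:(nc - 1))]
    g <- grad_rc(sm)
    Hrc <- grad_rc(g$dr)$dc
    # scale normalization
    Hrr <- Hrr * s^2; Hcc <- Hcc * s^2; Hrc <- Hrc * s^2
    tmp <- sqrt(((Hrr - Hcc) / 2)^2 + Hrc^2)
    mu <- (Hrr + Hcc) / 2
    l1 <- mu + tmp; l2 <- mu - tmp  # l2 <= l1
    # order by |lambda|: lam2 = larger magnitude
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    Rb2 <- (lam1 / ifelse(lam2 == 0, 1e-12, lam2))^2
    S2 <- lam1^2 + lam2^2
    c2 <- max(S2) / 4
    if (c2 == 0) next
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[lam2 > 0] <- 0  # bright ridges have strongly negative cross-curvature
    best <- pmax(best, v)
  }
  thr <- if (relative) threshold * max(best) else threshold
  if (max(best) == 0) {
    warning("no ridge response")
    return(best > 0)
  }
  best >= thr & best > 0
}

#' Remove mask blobs failing size and shape criteria
#'
#' Labels connected components and keeps those whose area, eccentricity and
#' solidity fall inside the given bounds.
#'
#' @param mask logical matrix.
#' @param min_size,max_size area bounds (px^2).
#' @param eccentricity_bounds length-2 numeric in `[0, 1]`.
#' @param solidity_bounds length-2 numeric in `(0, 1]`.
#' @return cleaned logical mask.
#' @export
clean_mask <- function(mask, min_size = 50, max_size = Inf,
                       eccentricity_bounds = c(0, 1),
                       solidity_bounds = c(0, 1)) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0) return(mask & FALSE)
  keep <- logical(n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    a <- nrow(idx)
    if (a < min_size || a > max_size) next
    ecc <- mask_eccentricity(idx)
    sol <- mask_solidity(idx)
    keep[k] <- ecc >= eccentricity_bounds[1] && ecc <= eccentricity_bounds[2] &&
      sol >= solidity_bounds[1] && sol <= solidity_bounds[2]
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab %in% which(keep) & lab > 0] <- TRUE
  out
}

# Eccentricity of a pixel set from its second central moments (ellipse of
# equal moments), as used for region shape descriptors.
mask_eccentricity <- function(idx) {
  if (nrow(idx) < 2) return(0)
  mu <- colMeans(idx)
  d <- sweep(idx, 2, mu)
  crr <- mean(d[, 1]^2) + 1 / 12  # pixel extent correction
  ccc <- mean(d[, 2]^2) + 1 / 12
  crc <- mean(d[, 1] * d[, 2])
  tmp <- sqrt(((crr - ccc) / 2)^2 + crc^2)
  l1 <- (crr + ccc) / 2 + tmp; l2 <- (crr + ccc) / 2 - tmp
  if (l1 <= 0) return(0)
  sqrt(pmax(0, 1 - l2 / l1))
}

# Solidity = pixel count / pixel count of the rasterized convex hull (the
# regionprops convention: both numerator and denominator are pixel areas).
mask_solidity <- function(idx) {
  if (nrow(idx) < 3) return(1)
  h <- grDevices::chull(idx)
  hull <- close_polygon(idx[h, , drop = FALSE])
  if (polygon_area(hull) <= 0) return(1)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  dim <- c(max(idx[, 1]) - r0 + 1L, max(idx[, 2]) - c0 + 1L)
  shifted <- cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)
  hull_sh <- cbind(hull[, 1] - r0 + 1L, hull[, 2] - c0 + 1L)
  hull_px <- polygon_mask(hull_sh, dim)
  hull_px[shifted] <- TRUE  # the region's own pixels always count
  min(1, nrow(idx) / sum(hull_px))
}

#' Topology-preserving thinning (Zhang-Suen)
#'
#' Reduces a binary mask to a 1-px-wide skeleton; every skeleton pixel was
#' set in the input.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize_outlines <- function(mask) {
  m <- mask * 1L
  if (sum(m) == 0) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p2 <- shift_mat(m, 1, 0); p6 <- shift_mat(m, -1, 0)   # N, S
      p4 <- shift_mat(m, 0, -1); p8 <- shift_mat(m, 0, 1)   # E, W (col+1 = E)
      p3 <- shift_mat(m, 1, -1); p5 <- shift_mat(m, -1, -1)
      p7 <- shift_mat(m, -1, 1); p9 <- shift_mat(m, 1, 1)
      nb <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seq9[[i]] == 0 & seq9[[i + 1]] == 1)
      if (step == 0) {
        cond <- m == 1 & nb >= 2 & nb <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & nb >= 2 & nb <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Direct least-squares (Fitzgibbon) ellipse fit; returns conic coefficients
# (a, b, c, d, e, f) for a x^2 + b xy + c y^2 + d x + e y + f = 0, or NULL.
fit_ellipse_conic <- function(pts) {
  if (nrow(pts) < 5) return(NULL)
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y); sc <- max(stats::sd(x), stats::sd(y), 1e-6)
  x <- (x - mx) / sc; y <- (y - my) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T)) return(NULL)
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- evec[, ok[1]]
  coefs <- c(a1, T %*% a1)
  # undo normalization: conic in u=(x-mx)/sc, v=(y-my)/sc
  A <- coefs[1] / sc^2
  B <- coefs[2] / sc^2
  C <- coefs[3] / sc^2
  D <- -2 * coefs[1] * mx / sc^2 - coefs[2] * my / sc^2 + coefs[4] / sc
  E <- -2 * coefs[3] * my / sc^2 - coefs[2] * mx / sc^2 + coefs[5] / sc
  F <- coefs[1] * mx^2 / sc^2 + coefs[2] * mx * my / sc^2 + coefs[3] * my^2 / sc^2 -
    coefs[4] * mx / sc - coefs[5] * my / sc + coefs[6]
  c(A, B, C, D, E, F)
}

# Geometric parameters (center, semi-axes, angle) from conic coefficients.
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2] / 2; C <- k[3]; D <- k[4] / 2; E <- k[5] / 2; F <- k[6]
  den <- A * C - B^2
  if (den <= 0) return(NULL)
  cx <- (B * E - C * D) / den
  cy <- (B * D - A * E) / den
  F0 <- F + D * cx + E * cy  # constant term after centering
  ev <- eigen(matrix(c(A, B, B, C), 2), symmetric = TRUE)
  ax2 <- -F0 / ev$values  # semi-axis^2 along each eigenvector
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(NULL)
  i_major <- which.max(ax2)  # conic scale is arbitrary: go by axis length
  v <- ev$vectors[, i_major]
  list(center = c(cx, cy),
       axes = sqrt(c(ax2[i_major], ax2[-i_major][1])),
       theta = atan2(v[2], v[1]))
}

# Mean squared Sampson (gradient-normalized algebraic) distance of points to
# a conic.
conic_fit_error <- function(k, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  Fv <- k[1] * x^2 + k[2] * x * y + k[3] * y^2 + k[4] * x + k[5] * y + k[6]
  gx <- 2 * k[1] * x + k[2] * y + k[4]
  gy <- k[2] * x + 2 * k[3] * y + k[5]
  mean(Fv^2 / pmax(gx^2 + gy^2, 1e-12))
}

#' Score candidate cell centers by local ellipse-fit error
#'
#' Every pixel whose distance to the skeleton lies in `[r_min, r_max]` is a
#' candidate cell center. For each, the skeleton points within `r_max` are
#' collected; candidates around which the skeleton directions leave an empty
#' angular gap larger than `1 - angular_coverage_min` of the circle are
#' discarded (open outlines: a half-circle arc covers at most 3/4 of the
#' directions). The rest receive the mean squared distance of an ellipse
#' fitted to those points, scaled up by the candidate's displacement from
#' the fitted center. Local minima of this error map are the cell-center
#' hypotheses.
#'
#' @param skeleton logical skeleton matrix.
#' @param r_min,r_max cell radius bounds (px).
#' @param angular_coverage_min minimum covered fraction of angular directions
#'   (strict).
#' @param stride candidate grid stride (px) for speed.
#' @return list of class `center_score_map` with `score` matrix (NA where not
#'   a candidate), and `minima`: list of `(point, ellipse, error)`.
#' @export
score_cell_centers <- function(skeleton, r_min, r_max,
                               angular_coverage_min = 0.75,
                               stride = 2L) {
  stopifnot(any(skeleton), r_min > 0, r_max > r_min)
  dist <- EBImage::distmap(1 - skeleton * 1)
  dist <- matrix(as.numeric(dist), nrow(skeleton))
  sk <- which(skeleton, arr.ind = TRUE)
  cand <- which(dist >= r_min & dist <= r_max, arr.ind = TRUE)
  if (stride > 1L)
    cand <- cand[cand[, 1] %% stride == 0 & cand[, 2] %% stride == 0, , drop = FALSE]
  score <- matrix(NA_real_, nrow(skeleton), ncol(skeleton))
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    d2 <- (sk[, 1] - p[1])^2 + (sk[, 2] - p[2])^2
    near <- sk[d2 <= r_max^2, , drop = FALSE]
    if (nrow(near) < 5) next
    ang <- sort(atan2(near[, 2] - p[2], near[, 1] - p[1]))
    # covered fraction of the circle = 1 - largest empty angular gap; a
    # half-circle arc tops out at exactly 3/4 seen from its apex, so the
    # comparison is strict
    gaps <- c(diff(ang), ang[1] + 2 * pi - ang[length(ang)])
    if (1 - max(gaps) / (2 * pi) <= angular_coverage_min) next
    k <- fit_ellipse_conic(near)
    if (is.null(k)) next
    ell <- conic_to_ellipse(k)
    if (is.null(ell)) next
    # the fit error alone is flat wherever the same skeleton points are in
    # range; candidates far from their own fitted center are poorer center
    # hypotheses, so the error is scaled by that displacement
    d_ctr2 <- sum((ell$center - p)^2) / r_max^2
    score[p[1], p[2]] <- conic_fit_error(k, near) * (1 + d_ctr2)
    fits[[i]] <- k
  }
  # smooth the (finite part of the) score map to suppress plateau duplicates
  finite <- !is.na(score)
  if (!any(finite))
    return(structure(list(score = score, minima = list()), class = "center_score_map"))
  filled <- score; filled[!finite] <- max(score, na.rm = TRUE)
  sm <- gauss_smooth(filled, 1)
  sm[!finite] <- NA
  minima <- list()
  idx <- which(finite, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    v <- sm[p[1], p[2]]
    nb <- sm[pmax(1, p[1] - stride):pmin(nrow(sm), p[1] + stride),
             pmax(1, p[2] - stride):pmin(ncol(sm), p[2] + stride)]
    if (v <= min(nb, na.rm = TRUE) + 1e-12) {
      d2 <- (sk[, 1] - p[1])^2 + (sk[, 2] - p[2])^2
      near <- sk[d2 <= r_max^2, , drop = FALSE]
      k <- fit_ellipse_conic(near)
      ell <- if (!is.null(k)) conic_to_ellipse(k) else NULL
      if (!is.null(ell))
        minima[[length(minima) + 1L]] <-
          list(point = unname(p), ellipse = ell, error = score[p[1], p[2]])
    }
  }
  # deduplicate minima closer than r_min, keeping the lower error
  if (length(minima) > 1) {
    ord <- order(vapply(minima, `[[`, numeric(1), "error"))
    kept <- list()
    for (m in minima[ord]) {
      dup <- any(vapply(kept, function(k2)
        sum((k2$point - m$point)^2) < r_min^2, logical(1)))
      if (!dup) kept[[length(kept) + 1L]] <- m
    }
    minima <- kept
  }
  structure(list(score = score, minima = minima), class = "center_score_map")
}

#' Construct a cell outline from a closed polygon
#' @param polygon closed (row, col) polygon.
#' @param dim image dimension for the rasterized mask.
#' @param rejected rejection flag.
#' @return object of class `cell_outline` with `polygon`, `mask`, `centroid`,
#'   `area` (px^2), `equivalent_radius` (px), `rejected`.
#' @export
cell_outline <- function(polygon, dim, rejected = FALSE) {
  polygon <- close_polygon(polygon)
  mask <- polygon_mask(polygon, dim)
  area <- polygon_area(polygon)
  structure(list(polygon = polygon, mask = mask,
                 centroid = polygon_centroid(polygon), area = area,
                 equivalent_radius = sqrt(area / pi), rejected = rejected),
            class = "cell_outline")
}

#' Snap an ellipse to image boundaries (greedy active contour)
#'
#' Deforms the ellipse polygon vertex by vertex along the local normal to
#' maximize an external energy (by default the ridge intensity of a smoothed
#' image, since cell edges are bright crests; `external = "edge"` uses the
#' gradient magnitude instead), balanced against continuity and curvature
#' penalties. Converges when the maximal vertex displacement per sweep drops
#' below `tol`.
#'
#' @param ellipse list with `center`, `axes`, `theta` (as from
#'   [score_cell_centers()] minima).
#' @param brightfield the brightfield image.
#' @param n_vertices polygon resolution.
#' @param search_radius normal search window (px).
#' @param alpha,beta continuity and curvature weights.
#' @param smooth_sigma Gaussian smoothing of the image before sampling.
#' @param external `"ridge"` or `"edge"`.
#' @param max_iter,tol convergence controls.
#' @param min_area,max_area acceptance bounds (px^2); violations set the
#'   `rejected` flag.
#' @return a [cell_outline()].
#' @export
snap_boundary <- function(ellipse, brightfield, n_vertices = 48L,
                          search_radius = 3, alpha = 0.15, beta = 0.15,
                          smooth_sigma = 1, external = c("ridge", "edge"),
                          max_iter = 40L, tol = 0.05,
                          min_area = 50, max_area = Inf) {
  external <- match.arg(external)
  if (diff(range(brightfield)) == 0)
    return(cell_outline(ellipse_polygon(ellipse$center, ellipse$axes,
                                        ellipse$theta, n_vertices),
                        dim(brightfield), rejected = TRUE))
  img <- gauss_smooth(brightfield, smooth_sigma)
  E <- if (external == "ridge") img else grad_magnitude(img)
  E <- (E - min(E)) / max(diff(range(E)), 1e-12)
  poly <- ellipse_polygon(ellipse$center, ellipse$axes, ellipse$theta, n_vertices)
  v <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(v)
  offsets <- seq(-search_radius, search_radius, by = 0.5)
  for (it in seq_len(max_iter)) {
    maxmove <- 0
    spacing <- mean(sqrt(rowSums(diff(rbind(v, v[1, ]))^2)))
    for (i in seq_len(n)) {
      ip <- if (i == 1) n else i - 1
      inx <- if (i == n) 1 else i + 1
      tang <- v[inx, ] - v[ip, ]
      tl <- sqrt(sum(tang^2)); if (tl == 0) next
      normal <- c(-tang[2], tang[1]) / tl
      cand <- sweep(outer(offsets, normal), 2, v[i, ], "+")
      ext <- bilinear(E, cand[, 1], cand[, 2])
      cont <- (sqrt(rowSums(sweep(cand, 2, v[ip, ])^2)) - spacing)^2 +
        (sqrt(rowSums(sweep(cand, 2, v[inx, ])^2)) - spacing)^2
      curv <- rowSums((sweep(cand * 2, 2, v[ip, ] + v[inx, ]))^2)
      en <- -ext + alpha * cont / spacing^2 + beta * curv / spacing^2
      j <- which.min(en)
      move <- abs(offsets[j])
      if (move > 0) { v[i, ] <- cand[j, ]; maxmove <- max(maxmove, move) }
    }
    if (maxmove < tol) break
  }
  out <- cell_outline(rbind(v, v[1, ]), dim(brightfield))
  out$rejected <- out$area < min_area || out$area > max_area
  out
}

#' Default segmentation parameters
#' @param pixel_size nm/px used to convert the nm-denominated radius bounds.
#' @param r_min_nm,r_max_nm cell radius bounds in nm.
#' @param ... overrides for any other parameter.
#' @return named list of parameters.
#' @export
segmentation_params <- function(pixel_size = 40.7, r_min_nm = 200,
                                r_max_nm = 1400, ...) {
  p <- list(
    pixel_size = pixel_size,
    frangi_scales = c(1, 1.5, 2), frangi_threshold = 0.2, invert = FALSE,
    min_blob = 40, max_blob = Inf,
    eccentricity_bounds = c(0, 1), solidity_bounds = c(0, 1),
    r_min = r_min_nm / pixel_size, r_max = r_max_nm / pixel_size,
    angular_coverage_min = 0.75, stride = 2L, max_center_error = 0.5,
    n_vertices = 48L, search_radius = 3, alpha = 0.15, beta = 0.15,
    snap_external = "ridge", min_area = 80, max_area = Inf,
    overlap_tol = 0.2)
  o <- list(...)
  p[names(o)] <- o
  p
}

#' Segment cells from a brightfield image
#'
#' Full chain: ridge detection, mask cleaning, thinning, center scoring and
#' boundary snapping. Rejected outlines (collapsed, exploded or overlapping
#' beyond `overlap_tol`) are dropped; failures never abort the image.
#'
#' @param brightfield 2-D matrix.
#' @param params list from [segmentation_params()].
#' @return list of accepted [cell_outline()]s.
#' @export
segment_cells <- function(brightfield, params = segmentation_params()) {
  p <- params
  ridges <- detect_ridges(brightfield, p$frangi_scales, p$frangi_threshold,
                          invert = p$invert)
  if (!any(ridges)) return(list())
  cleaned <- clean_mask(ridges, p$min_blob, p$max_blob,
                        p$eccentricity_bounds, p$solidity_bounds)
  if (!any(cleaned)) return(list())
  skel <- skeletonize_outlines(cleaned)
  if (!any(skel)) return(list())
  csm <- score_cell_centers(skel, p$r_min, p$r_max, p$angular_coverage_min,
                            stride = p$stride)
  outlines <- list()
  for (m in csm$minima) {
    # skeleton RMS distance to the fitted ellipse ~0.3-0.4 px for genuine
    # closed outlines; minima fitted across several cells score far worse
    if (m$error > p$max_center_error) next
    ol <- tryCatch(
      snap_boundary(m$ellipse, brightfield, n_vertices = p$n_vertices,
                    search_radius = p$search_radius, alpha = p$alpha,
                    beta = p$beta, external = p$snap_external,
                    min_area = p$min_area, max_area = p$max_area),
      error = function(e) NULL)
    if (is.null(ol) || ol$rejected) next
    overlap <- any(vapply(outlines, function(o2)
      sum(o2$mask & ol$mask) / min(sum(o2$mask), sum(ol$mask)) > p$overlap_tol,
      logical(1)))
    if (!overlap) outlines[[length(outlines) + 1L]] <- ol
  }
  outlines
}

#' Build cell outlines from an externally produced label or binary mask
#'
#' Bypasses the segmentation pipeline: each connected component (binary
#' input) or label (integer input) becomes one outline whose polygon traces
#' the component boundary.
#'
#' @param mask binary or integer label matrix.
#' @return list of [cell_outline()]s.
#' @export
outlines_from_mask <- function(mask) {
  lab <- if (is.logical(mask) || all(mask %in% c(0, 1)))
    EBImage::bwlabel(mask * 1) else mask
  lab <- matrix(as.integer(round(as.numeric(lab))), nrow(mask))
  out <- list()
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    if (!any(comp)) next
    oc <- EBImage::ocontour(comp * 1)[[1]]  # (x=row-1, y=col-1) 0-based
    poly <- close_polygon(cbind(oc[, 1] + 1, oc[, 2] + 1))
    ol <- cell_outline(poly, dim(mask))
    ol$mask <- comp  # exact component mask, not the rasterized trace
    ol$area <- sum(comp)
    ol$equivalent_radius <- sqrt(ol$area / pi)
    out[[length(out) + 1L]] <- ol
  }
  out
}
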