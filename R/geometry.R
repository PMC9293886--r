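# Polygon geometry on sub-pixel (row, col) vertex lists. Polygons are
# n x 2 matrices; a closed polygon repeats its first vertex as the last row.

close_polygon <- function(p) {
  if (!isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- rbind(p, p[1, ])
  p
}

is_closed_polygon <- function(p, tol = 1e-8) {
  nrow(p) >= 4 && all(abs(p[1, ] - p[nrow(p), ]) < tol)
}

#' Signed polygon area by the shoelace formula
#' @param p closed polygon, n x 2 matrix of (row, col) vertices.
#' @return area in px^2 (always positive).
#' @keywords internal
polygon_area <- function(p) {
  p <- close_polygon(p)
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

polygon_perimeter <- function(p) {
  p <- close_polygon(p)
  sum(sqrt(rowSums(diff(p)^2)))
}

polygon_centroid <- function(p) {
  p <- close_polygon(p)
  x <- p[, 1]; y <- p[, 2]; n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p[-nrow(p), , drop = FALSE]))
  c(sum((x[-n] + x[-1]) * cr) / (6 * a), sum((y[-n] + y[-1]) * cr) / (6 * a))
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(pts, poly) {
  poly <- close_polygon(poly)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

point_in_polygon <- function(pt, poly) {
  points_in_polygon(matrix(pt, 1, 2), poly)
}

# Rasterize a polygon into a logical mask of dimension dim (pixel centers at
# integer coordinates).
polygon_mask <- function(poly, dim) {
  nr <- dim[1]; nc <- dim[2]
  poly <- close_polygon(poly)
  r0 <- max(1L, floor(min(poly[, 1]))); r1 <- min(nr, ceiling(max(poly[, 1])))
  c0 <- max(1L, floor(min(poly[, 2]))); c1 <- min(nc, ceiling(max(poly[, 2])))
  m <- matrix(FALSE, nr, nc)
  if (r1 < r0 || c1 < c0) return(m)
  grid <- as.matrix(expand.grid(r = r0:r1, c = c0:c1))
  inside <- points_in_polygon(grid, poly)
  m[grid[inside, , drop = FALSE]] <- TRUE
  m
}

is_convex_polygon <- function(p, tol = 1e-9) {
  p <- close_polygon(p)
  v <- diff(p)
  n <- nrow(v)
  cr <- v[c(seq_len(n - 1), 1), 1] * v[c(2:n, 2), 2] -
        v[c(seq_len(n - 1), 1), 2] * v[c(2:n, 2), 1]
  cr <- cr[abs(cr) > tol]
  length(cr) == 0 || all(cr > 0) || all(cr < 0)
}

# Sutherland-Hodgman clipping of polygon `subject` by CONVEX polygon `clip`.
clip_polygon_convex <- function(subject, clip) {
  clip <- close_polygon(clip)
  # Ensure counter-clockwise orientation of clip
  x <- clip[, 1]; y <- clip[, 2]; n <- nrow(clip)
  if (sum(x[-n] * y[-1] - x[-1] * y[-n]) < 0) clip <- clip[n:1, ]
  out <- close_polygon(subject)
  out <- out[-nrow(out), , drop = FALSE]
  nc <- nrow(clip) - 1L
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[i + 1, ]
    side <- function(p) (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
    inp <- out
    s <- side(inp)
    res <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    for (j in seq_len(m)) {
      k <- if (j == m) 1L else j + 1L
      cur_in <- s[j] >= -1e-12; nxt_in <- s[k] >= -1e-12
      if (cur_in) res <- rbind(res, inp[j, ])
      if (cur_in != nxt_in) {
        t <- s[j] / (s[j] - s[k])
        res <- rbind(res, inp[j, ] + t * (inp[k, ] - inp[j, ]))
      }
    }
    out <- res
  }
  out
}

#' Overlap area of two polygons
#'
#' Exact Sutherland-Hodgman clipping when both polygons are convex; otherwise
#' supersampled point-in-polygon counting on a 0.25 px grid.
#' @keywords internal
polygon_overlap_area <- function(a, b) {
  if (is_convex_polygon(a) && is_convex_polygon(b)) {
    inter <- clip_polygon_convex(a, b)
    if (nrow(inter) < 3) return(0)
    return(polygon_area(inter))
  }
  step <- 0.25
  r0 <- max(min(a[, 1]), min(b[, 1])); r1 <- min(max(a[, 1]), max(b[, 1]))
  c0 <- max(min(a[, 2]), min(b[, 2])); c1 <- min(max(a[, 2]), max(b[, 2]))
  if (r1 <= r0 || c1 <= c0) return(0)
  grid <- as.matrix(expand.grid(r = seq(r0, r1, by = step), c = seq(c0, c1, by = step)))
  inside <- points_in_polygon(grid, a) & points_in_polygon(grid, b)
  sum(inside) * step^2
}

segment_segment_distance <- function(p1, p2, q1, q2) {
  # minimum distance between 2-D segments [p1,p2] and [q1,q2]
  seg_pt <- function(a, b, p) {
    d <- b - a
    L2 <- sum(d^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * d) / L2))
    sqrt(sum((a + t * d - p)^2))
  }
  ccw <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  # proper intersection -> distance 0
  d1 <- ccw(q1, q2, p1); d2 <- ccw(q1, q2, p2)
  d3 <- ccw(p1, p2, q1); d4 <- ccw(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(seg_pt(q1, q2, p1), seg_pt(q1, q2, p2), seg_pt(p1, p2, q1), seg_pt(p1, p2, q2))
}

# Minimum distance between two polygon boundaries (over all edge pairs);
# 0 if the polygons overlap or touch.
polygon_boundary_distance <- function(a, b) {
  a <- close_polygon(a); b <- close_polygon(b)
  if (point_in_polygon(a[1, ], b) || point_in_polygon(b[1, ], a)) return(0)
  best <- Inf
  na <- nrow(a) - 1L; nb <- nrow(b) - 1L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- segment_segment_distance(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

# Sample an ellipse boundary as a closed polygon. center (row, col), semi-axes
# (a along orientation theta, b across), theta in radians.
ellipse_polygon <- function(center, axes, theta = 0, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  x <- axes[1] * cos(t); y <- axes[2] * sin(t)
  r <- center[1] + x * cos(theta) - y * sin(theta)
  c <- center[2] + x * sin(theta) + y * cos(theta)
  cbind(r, c)
}

# Scale a closed polygon radially about its centroid so that its area is
# multiplied by `factor`.
scale_polygon_area <- function(p, factor) {
  if (factor == 1) return(p)
  ctr <- polygon_centroid(p)
  sweep(sweep(p, 2, ctr, "-") * sqrt(factor), 2, ctr, "+")
}
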