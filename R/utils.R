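# Shared numerical helpers: seeded evaluation, separable Gaussian smoothing,
# finite-difference derivatives and bilinear sampling. All images are plain
# numeric matrices indexed [row, col].

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators (the synthetic
#' fixtures, the random quantifier, fold assignment) do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

gauss_kernel_1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicate padding.
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel_1d(sigma)
  h <- (length(k) - 1L) / 2L
  pad_rows <- function(m, h) rbind(m[rep(1L, h), , drop = FALSE], m,
                                   m[rep(nrow(m), h), , drop = FALSE])
  conv_cols <- function(m) {
    # stats::filter runs the FIR filter down each column at C speed
    p <- pad_rows(m, h)
    f <- stats::filter(p, k, method = "convolution", sides = 2)
    f[(h + 1L):(h + nrow(m)), , drop = FALSE]
  }
  t(conv_cols(t(conv_cols(img))))
}

# Central-difference gradients; one-sided at the borders.
grad_rc <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  dr <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  dr[c(1, nr), ] <- dr[c(1, nr), ] * 2  # one-sided spacing is 1, interior 2
  dc <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  dc[, c(1, nc)] <- dc[, c(1, nc)] * 2
  list(dr = dr / 2, dc = dc / 2)
}

grad_magnitude <- function(img) {
  g <- grad_rc(img)
  sqrt(g$dr^2 + g$dc^2)
}

# Bilinear interpolation at sub-pixel (row, col) positions (1-based).
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)];     i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

moving_average <- function(x, window = 3L) {
  if (window <= 1L || length(x) < window) return(x)
  h <- window %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1):(h + length(x))]
}

md5_of <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
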