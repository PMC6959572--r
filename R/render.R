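# Internal rasterizers for the synthetic-data generators.
#
# Objects are anti-aliased ellipses / discs / capsules evaluated at pixel
# centers (pixel j covers ((j-1)*ps, j*ps] um; its center maps to pixel
# coordinate x_um / ps + 0.5). Soft edges use a ~1 px linear ramp so that
# sub-pixel geometry is controllable; ground-truth masks use the hard
# center-inside rule on the same geometry.

# Add a rotated soft-edged ellipse to a matrix. All coordinates in pixels.
.add_ellipse <- function(mat, cx, cy, a, b, theta = 0, amp = 1) {
  ny <- nrow(mat); nx <- ncol(mat)
  rmax <- max(a, b) + 1
  js <- max(1L, floor(cx - rmax)):min(nx, ceiling(cx + rmax))
  is <- max(1L, floor(cy - rmax)):min(ny, ceiling(cy + rmax))
  if (!length(js) || !length(is)) return(mat)
  dx <- outer(rep(1, length(is)), js - cx)
  dy <- outer(is - cy, rep(1, length(js)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  rho <- sqrt((u / a)^2 + (v / b)^2)
  cov <- pmin(pmax((1 - rho) * min(a, b) + 0.5, 0), 1)
  mat[is, js] <- mat[is, js] + amp * cov
  mat
}

# Hard mask of the same ellipse (pixel-center-inside).
.mask_ellipse <- function(ny, nx, cx, cy, a, b, theta = 0) {
  m <- matrix(FALSE, ny, nx)
  rmax <- max(a, b) + 1
  js <- max(1L, floor(cx - rmax)):min(nx, ceiling(cx + rmax))
  is <- max(1L, floor(cy - rmax)):min(ny, ceiling(cy + rmax))
  if (!length(js) || !length(is)) return(m)
  dx <- outer(rep(1, length(is)), js - cx)
  dy <- outer(is - cy, rep(1, length(js)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  m[is, js] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Add a soft-edged capsule (segment with round caps) to a matrix.
.add_capsule <- function(mat, x1, y1, x2, y2, halfwidth, amp = 1) {
  ny <- nrow(mat); nx <- ncol(mat)
  pad <- halfwidth + 1
  js <- max(1L, floor(min(x1, x2) - pad)):min(nx, ceiling(max(x1, x2) + pad))
  is <- max(1L, floor(min(y1, y2) - pad)):min(ny, ceiling(max(y1, y2) + pad))
  if (!length(js) || !length(is)) return(mat)
  px <- outer(rep(1, length(is)), js)
  py <- outer(is, rep(1, length(js)))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
  d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  cov <- pmin(pmax(halfwidth - d + 0.5, 0), 1)
  mat[is, js] <- mat[is, js] + amp * cov
  mat
}

.mask_capsule <- function(ny, nx, x1, y1, x2, y2, halfwidth) {
  m <- matrix(FALSE, ny, nx)
  pad <- halfwidth + 1
  js <- max(1L, floor(min(x1, x2) - pad)):min(nx, ceiling(max(x1, x2) + pad))
  is <- max(1L, floor(min(y1, y2) - pad)):min(ny, ceiling(max(y1, y2) + pad))
  if (!length(js) || !length(is)) return(m)
  px <- outer(rep(1, length(is)), js)
  py <- outer(is, rep(1, length(js)))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
  d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  m[is, js] <- d <= halfwidth
  m
}

# Vectorized splat of many soft discs (cx, cy, r in px; amp recycled).
.add_discs <- function(mat, cx, cy, r, amp = 1) {
  n <- length(cx)
  if (n == 0L) return(mat)
  ny <- nrow(mat); nx <- ncol(mat)
  amp <- rep_len(amp, n)
  rmax <- ceiling(max(r) + 1)
  offs <- expand.grid(dy = -rmax:rmax, dx = -rmax:rmax)
  jc <- round(cx); ic <- round(cy)
  j <- rep(jc, each = nrow(offs)) + rep(offs$dx, n)
  i <- rep(ic, each = nrow(offs)) + rep(offs$dy, n)
  cxe <- rep(cx, each = nrow(offs)); cye <- rep(cy, each = nrow(offs))
  re <- rep(r, each = nrow(offs)); ae <- rep(amp, each = nrow(offs))
  d <- sqrt((j - cxe)^2 + (i - cye)^2)
  cov <- pmin(pmax(re - d + 0.5, 0), 1) * ae
  ok <- cov > 0 & i >= 1 & i <= ny & j >= 1 & j <= nx
  if (!any(ok)) return(mat)
  idx <- i[ok] + (j[ok] - 1) * ny
  add <- rowsum(cov[ok], idx)
  ii <- as.integer(rownames(add))
  mat[ii] <- mat[ii] + add[, 1L]
  mat
}

# Gaussian blur of one plane (sigma in px); identity for sigma <= 0.
# Separable 1-D convolutions (circular edges; kernel support 4 sigma).
.blur_plane <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  y <- stats::filter(mat, k, circular = TRUE)           # along columns
  y <- stats::filter(t(matrix(as.numeric(y), nrow(mat))), k, circular = TRUE)
  t(matrix(as.numeric(y), ncol(mat)))
}

# Linear pixel indices of an ellipse / capsule footprint (center-inside),
# evaluated only on the bounding box.
.idx_ellipse <- function(ny, nx, cx, cy, a, b, theta = 0) {
  rmax <- max(a, b) + 1
  js <- max(1L, floor(cx - rmax)):min(nx, ceiling(cx + rmax))
  is <- max(1L, floor(cy - rmax)):min(ny, ceiling(cy + rmax))
  if (!length(js) || !length(is)) return(integer(0))
  dx <- outer(rep(1, length(is)), js - cx)
  dy <- outer(is - cy, rep(1, length(js)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  hit <- which((u / a)^2 + (v / b)^2 <= 1)
  ii <- (hit - 1L) %% length(is) + 1L
  jj <- (hit - 1L) %/% length(is) + 1L
  is[ii] + (js[jj] - 1L) * ny
}

.idx_capsule <- function(ny, nx, x1, y1, x2, y2, halfwidth) {
  pad <- halfwidth + 1
  js <- max(1L, floor(min(x1, x2) - pad)):min(nx, ceiling(max(x1, x2) + pad))
  is <- max(1L, floor(min(y1, y2) - pad)):min(ny, ceiling(max(y1, y2) + pad))
  if (!length(js) || !length(is)) return(integer(0))
  px <- outer(rep(1, length(is)), js)
  py <- outer(is, rep(1, length(js)))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
  d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  hit <- which(d <= halfwidth)
  ii <- (hit - 1L) %% length(is) + 1L
  jj <- (hit - 1L) %/% length(is) + 1L
  is[ii] + (js[jj] - 1L) * ny
}

# Uniform draw of a point inside an ellipse scaled by `shrink`,
# returned in the parent (unrotated -> rotated, translated) frame.
.point_in_ellipse <- function(cx, cy, a, b, theta, shrink = 1) {
  rho <- sqrt(stats::runif(1))
  phi <- stats::runif(1, 0, 2 * pi)
  u <- rho * cos(phi) * a * shrink
  v <- rho * sin(phi) * b * shrink
  c(cx + cos(theta) * u - sin(theta) * v,
    cy + sin(theta) * u + cos(theta) * v)
}
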