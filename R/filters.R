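# Array primitives shared by preprocessing, regularization and masking:
# integer shifts, neighbourhood extremum filters, separable Gaussian
# smoothing, binary morphology and 6-connected components. All operate on
# plain 3-D arrays; volume wrappers live with their callers.

# Shift an array by an integer offset, filling exposed entries with `fill`.
shift_array <- function(a, offset, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- offset[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else        { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Offsets of a cube (Chebyshev) or ball (Euclidean) neighbourhood, incl. center.
neighbourhood_offsets <- function(radius, shape = c("cube", "ball")) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  if (shape == "ball") g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ]
  as.matrix(g)
}

# Neighbourhood extremum filter; the workhorse behind the critical-intensity
# filter and binary dilation/erosion. Out-of-volume neighbours are ignored.
extremum_filter <- function(a, offsets, mode = c("max", "min")) {
  mode <- match.arg(mode)
  fill <- if (mode == "max") -Inf else Inf
  red <- if (mode == "max") pmax else pmin
  out <- array(fill, dim(a))
  for (r in seq_len(nrow(offsets))) {
    out <- red(out, shift_array(a, offsets[r, ], fill))
  }
  out
}

# Morphology uses the (2r+1)^3 cube (Chebyshev ball): closing then opening
# with it leaves solid axis-aligned regions untouched, which the Euclidean
# cross element does not (it clips corners).
binary_dilate <- function(m, radius = 1L, shape = "cube") {
  off <- neighbourhood_offsets(radius, shape)
  extremum_filter(array(as.numeric(m), dim(m)), off, "max") > 0.5
}

binary_erode <- function(m, radius = 1L, shape = "cube") {
  off <- neighbourhood_offsets(radius, shape)
  # outside the volume counts as background
  extremum_filter(array(as.numeric(m), dim(m)), off, "min") > 0.5
}

binary_close <- function(m, radius = 1L) {
  if (radius <= 0L) return(m > 0.5)
  binary_erode(binary_dilate(m, radius), radius)
}

binary_open <- function(m, radius = 1L) {
  if (radius <= 0L) return(m > 0.5)
  binary_dilate(binary_erode(m, radius), radius)
}

# Largest 6-connected foreground component of a logical array.
largest_component <- function(m) {
  idx <- which(m)
  if (!length(idx)) return(m)
  d <- dim(m)
  lab <- array(0L, d); lab[idx] <- seq_along(idx)
  edges <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  ijk <- arrayInd(idx, d)
  for (ax in 1:3) {
    ok <- ijk[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    has <- lab[nb] > 0L
    if (any(has)) edges <- c(edges, rbind(lab[idx[ok]][has], lab[nb][has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[comp$membership == keep]] <- TRUE
  out
}

# Discrete Gaussian kernel, truncated at 3 sigma, normalized to sum 1.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable 3-D Gaussian smoothing (zero padding at edges). `sigma_mm` is
# isotropic in world units; anisotropic voxels get per-axis kernel widths.
gaussian_smooth <- function(a, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(a)
  out <- a
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sigma_mm / spacing[ax])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L); off[ax] <- j - 1L - r
      acc <- acc + k[j] * shift_array(out, off, 0)
    }
    out <- acc
  }
  out
}

# Mask-renormalized Gaussian smoothing: smooth(x*m)/smooth(m) inside the
# mask, 0 outside, so values near the mask boundary are not diluted by
# out-of-mask zeros. Constant fields are preserved exactly inside the mask.
masked_gaussian_smooth <- function(a, sigma_mm, spacing, mask) {
  m <- array(as.numeric(mask > 0.5), dim(a))
  if (sigma_mm <= 0) return(a * m)
  num <- gaussian_smooth(a * m, sigma_mm, spacing)
  den <- gaussian_smooth(m, sigma_mm, spacing)
  out <- array(0, dim(a))
  inside <- m > 0.5 & den > .Machine$double.eps
  out[inside] <- num[inside] / den[inside]
  out
}

# Trilinear interpolation of `a` at fractional 1-based voxel coordinates
# (n x 3 matrix). Points outside the grid return `outside`.
interp_trilinear <- function(a, pts, outside = 0) {
  d <- dim(a)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}
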