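# Separable, spacing-aware Gaussian filtering and trilinear interpolation on
# 3D arrays. Kernels are sampled Gaussians truncated at 3 sigma and
# renormalised; edges use replicate padding so constant volumes are invariant.

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Shift an array along one axis by `offset` voxels with edge replication.
shift_axis <- function(arr, offset, axis) {
  if (offset == 0L) return(arr)
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[axis]) + offset, 1L), d[axis])
  args <- rep(list(quote(expr = )), 3)
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

convolve_axis <- function(arr, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  n <- dm[1]
  r <- (nk - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  idx <- seq_len(n)
  for (t in seq_len(nk)) {
    src <- pmin(pmax(idx + (t - r - 1L), 1L), n)
    out <- out + kernel[t] * m[src, , drop = FALSE]
  }
  dim(out) <- dm
  aperm(out, order(perm))
}

#' Gaussian smoothing of a 3D array in physical units
#'
#' Separable Gaussian convolution with the standard deviation given in mm,
#' converted per axis to voxel units through the spacing. A per-axis sigma of
#' zero leaves that axis untouched (used e.g. for one-dimensional motion
#' blur).
#'
#' @param arr 3D numeric array.
#' @param sigma_mm scalar or length-3 standard deviation in mm.
#' @param spacing voxel spacing in mm (x, y, z).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3L)
  if (any(sigma_mm < 0)) stop("`sigma_mm` must be non-negative")
  for (ax in 1:3) {
    if (sigma_mm[ax] > 0)
      arr <- convolve_axis(arr, gaussian_kernel(sigma_mm[ax] / spacing[ax]), ax)
  }
  arr
}

# First derivative along an axis by central differences, in mm^-1.
axis_gradient <- function(arr, axis, h) {
  (shift_axis(arr, 1L, axis) - shift_axis(arr, -1L, axis)) / (2 * h)
}

# Laplacian by the standard 7-point stencil, spacing-aware.
laplacian3 <- function(arr, spacing) {
  out <- array(0, dim(arr))
  for (ax in 1:3) {
    h <- spacing[ax]
    out <- out + (shift_axis(arr, 1L, ax) - 2 * arr + shift_axis(arr, -1L, ax)) / h^2
  }
  out
}

#' Trilinear interpolation of a 3D array at world points
#'
#' @param arr 3D numeric array sampled at voxel centres.
#' @param spacing,origin grid geometry in mm (see [ct_volume()]).
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param outside value returned for points outside the grid (default 0).
#' @return numeric(n) of interpolated values.
#' @export
interp_trilinear <- function(arr, spacing, origin, pts, outside = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(arr)
  u <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")  # 0-based voxel coords
  out <- rep(outside, nrow(pts))
  ok <- u[, 1] >= 0 & u[, 1] <= d[1] - 1 &
        u[, 2] >= 0 & u[, 2] <= d[2] - 1 &
        u[, 3] >= 0 & u[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  u <- u[ok, , drop = FALSE]
  i0 <- pmin(floor(u), matrix(rep(d - 2, each = nrow(u)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- u - i0
  val <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
         (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
         (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    ind <- cbind(i0[, 1] + cx + 1, i0[, 2] + cy + 1, i0[, 3] + cz + 1)
    val <- val + w * arr[ind]
  }
  out[ok] <- val
  out
}
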