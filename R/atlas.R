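#' Spatial normalisation by moment matching
#'
#' Computes the affine transform into the atlas reference frame from the
#' first and second moments of a heart-region mask: world points are centred
#' on the mask centroid and scaled by the per-axis standard deviation, so the
#' reference frame is in units of mask SDs. This is a deliberately simple
#' stand-in for full image registration; it only needs to bring homologous
#' territories of different scans into rough correspondence.
#'
#' @param mask logical 3D array delineating the region used for
#'   normalisation.
#' @param spacing,origin grid geometry (mm).
#' @return object of class `spatial_transform` with `center` and `scale`
#'   (mm).
#' @export
moment_transform <- function(mask, spacing, origin = c(0, 0, 0)) {
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) < 2L) stop("normalisation mask needs at least 2 voxels")
  mm <- sweep(sweep(vox - 1, 2, spacing, "*"), 2, origin, "+")
  scale <- apply(mm, 2, sd)
  scale[scale == 0] <- 1
  structure(list(center = colMeans(mm), scale = scale),
            class = "spatial_transform")
}

#' Apply a spatial transform to world points
#'
#' @param transform a `spatial_transform` (or NULL for identity).
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of reference-frame coordinates.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (is.null(transform)) return(pts)
  sweep(sweep(pts, 2, transform$center, "-"), 2, transform$scale, "/")
}

#' Build a coronary calcium probability atlas
#'
#' The atlas is the voxelwise mean of spatially normalised binary coronary
#' masks, optionally Gaussian-smoothed and clipped to `[0, 1]`; it provides
#' the a-priori spatial probability that a location contains coronary
#' calcium. With `transforms = NULL` all masks must share one grid, which
#' then is the reference frame (identity normalisation); otherwise each
#' mask's TRUE voxels are mapped through its transform and rasterised into a
#' common normalised grid.
#'
#' @param masks list of logical 3D arrays.
#' @param spacings list of spacing vectors (mm), one per mask (or a single
#'   vector recycled).
#' @param transforms list of `spatial_transform`s (one per mask), or NULL for
#'   identity.
#' @param sigma smoothing sd, in mm for the identity frame or in
#'   reference-frame units otherwise; 0 disables.
#' @param ref_range,ref_spacing extent (+/-) and voxel size of the normalised
#'   reference grid (ignored for the identity frame).
#' @return object of class `cac_atlas`.
#' @export
build_atlas <- function(masks, spacings, transforms = NULL, sigma = 0,
                        ref_range = 4, ref_spacing = 0.25) {
  if (length(masks) == 0L) stop("atlas requires at least one training mask")
  if (!is.list(spacings)) spacings <- rep(list(spacings), length(masks))
  if (is.null(transforms)) {
    d <- dim(masks[[1]])
    for (m in masks) if (!identical(dim(m), d))
      stop("identity-frame atlas requires masks on a common grid")
    prob <- Reduce(`+`, lapply(masks, function(m) array(as.numeric(m), d))) /
      length(masks)
    spacing <- as.numeric(spacings[[1]])
    origin <- c(0, 0, 0)
    normalized <- FALSE
  } else {
    if (length(transforms) != length(masks))
      stop("need one transform per mask")
    n1 <- as.integer(2 * ref_range / ref_spacing) + 1L
    d <- rep(n1, 3L)
    spacing <- rep(ref_spacing, 3L)
    origin <- rep(-ref_range, 3L)
    prob <- array(0, d)
    for (i in seq_along(masks)) {
      vox <- which(masks[[i]], arr.ind = TRUE)
      if (nrow(vox) == 0L) next
      mm <- sweep(vox - 1, 2, as.numeric(spacings[[i]]), "*")
      ref <- apply_transform(transforms[[i]], mm)
      idx <- round(sweep(ref, 2, origin, "-") / ref_spacing) + 1
      keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
              idx[, 2] >= 1 & idx[, 2] <= d[2] &
              idx[, 3] >= 1 & idx[, 3] <= d[3]
      occ <- array(0, d)
      occ[idx[keep, , drop = FALSE]] <- 1
      prob <- prob + occ
    }
    prob <- prob / length(masks)
    normalized <- TRUE
  }
  if (sigma > 0) prob <- gaussian_smooth(prob, sigma, spacing)
  prob <- pmin(pmax(prob, 0), 1)
  structure(list(prob = prob, spacing = spacing, origin = origin,
                 normalized = normalized, sigma = sigma,
                 n_train = length(masks)),
            class = "cac_atlas")
}

#' @export
print.cac_atlas <- function(x, ...) {
  d <- dim(x$prob)
  cat(sprintf(
    "cac_atlas: %d x %d x %d %s frame, %d training mask(s), sigma %.2f\n",
    d[1], d[2], d[3], if (x$normalized) "normalised" else "native",
    x$n_train, x$sigma))
  invisible(x)
}

#' A-priori spatial probability of coronary calcium at world points
#'
#' Trilinear interpolation of the atlas at the (transformed) query points;
#' points outside the reference frame return 0 by contract.
#'
#' @param atlas a `cac_atlas`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param transform the scan's `spatial_transform` into the atlas frame
#'   (NULL for identity / native-frame atlases).
#' @return numeric(n) probabilities in `[0, 1]`.
#' @export
spatial_probability <- function(atlas, pts, transform = NULL) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (atlas$normalized) pts <- apply_transform(transform, pts)
  p <- interp_trilinear(atlas$prob, atlas$spacing, atlas$origin, pts,
                        outside = 0)
  pmin(pmax(p, 0), 1)
}
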