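#' Multi-scale Gaussian texture features at world points
#'
#' For each scale sigma (mm) the volume is Gaussian-smoothed and three
#' rotation-invariant quantities are sampled at the query points by trilinear
#' interpolation: the smoothed intensity, the gradient magnitude and the
#' Laplacian, with all derivatives taken in mm units (spacing-aware central
#' differences).
#'
#' @param volume a [ct_volume()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param scales positive Gaussian scales in mm.
#' @return n x (3 * length(scales)) matrix with columns
#'   `int_s<scale>, grad_s<scale>, lap_s<scale>`.
#' @export
texture_features <- function(volume, pts, scales = c(1, 2, 4)) {
  if (any(scales <= 0)) stop("`scales` must be positive")
  pts <- matrix(as.numeric(pts), ncol = 3)
  sp <- volume$spacing
  out <- matrix(0, nrow(pts), 0)
  for (s in scales) {
    sm <- gaussian_smooth(volume$data, s, sp)
    gm <- sqrt(axis_gradient(sm, 1L, sp[1])^2 +
               axis_gradient(sm, 2L, sp[2])^2 +
               axis_gradient(sm, 3L, sp[3])^2)
    lp <- laplacian3(sm, sp)
    block <- cbind(
      interp_trilinear(sm, sp, volume$origin, pts),
      interp_trilinear(gm, sp, volume$origin, pts),
      interp_trilinear(lp, sp, volume$origin, pts))
    colnames(block) <- paste0(c("int_s", "grad_s", "lap_s"), s)
    out <- cbind(out, block)
  }
  out
}

#' Feature names used by [featurize()]
#' @param scales texture scales (mm).
#' @return character vector of column names.
#' @export
feature_names <- function(scales = c(1, 2, 4)) {
  c("volume_mm3", "atlas_prob", "cx", "cy", "cz",
    as.vector(outer(c("int_s", "grad_s", "lap_s"), scales, paste0)))
}

#' Compute the feature vector of each candidate
#'
#' One row per candidate: the candidate volume (size feature), the atlas
#' probability at its centroid and the normalised centroid coordinates
#' (spatial features), and the multi-scale Gaussian texture features at the
#' centroid. Standardisation is *not* applied here; the classifier owns it.
#'
#' @param candidates list of `cac_candidate`.
#' @param volume the originating [ct_volume()].
#' @param atlas a `cac_atlas`.
#' @param transform the scan's `spatial_transform` into the atlas frame.
#' @param scales texture scales (mm).
#' @return numeric matrix (n_candidates x n_features) with fixed column
#'   order [feature_names()]; zero rows for an empty candidate list.
#' @export
featurize <- function(candidates, volume, atlas, transform = NULL,
                      scales = c(1, 2, 4)) {
  fn <- feature_names(scales)
  if (length(candidates) == 0L)
    return(matrix(numeric(0), 0, length(fn), dimnames = list(NULL, fn)))
  cen <- t(vapply(candidates, function(x) x$centroid, numeric(3)))
  norm_cen <- apply_transform(transform, cen)
  feat <- cbind(
    vapply(candidates, function(x) x$volume_mm3, 0),
    spatial_probability(atlas, cen, transform),
    norm_cen,
    texture_features(volume, cen, scales))
  colnames(feat) <- fn
  feat
}
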