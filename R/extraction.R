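#' Candidate extraction configuration
#'
#' Candidates are extracted by thresholding at `threshold` HU (inclusive, the
#' Agatston convention) followed by 3D connected-component labeling.
#'
#' @param threshold HU threshold, default 130; voxels with HU >= threshold are
#'   candidate material.
#' @param connectivity 6, 18 or 26 (default 26): the 3D neighbourhood defining
#'   connectedness.
#' @param min_volume candidates smaller than this (mm^3) are dropped
#'   (default 0 = keep all).
#' @param max_volume candidates larger than this (mm^3) are flagged
#'   `oversize` (e.g. bone) but kept; the classifier decides their fate.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(threshold = 130, connectivity = 26,
                              min_volume = 0, max_volume = Inf) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(threshold = threshold, connectivity = as.integer(connectivity),
                 min_volume = min_volume, max_volume = max_volume),
            class = "extraction_config")
}

#' Threshold a CT volume
#'
#' @param volume a [ct_volume()].
#' @param threshold HU threshold; the mask is TRUE exactly where HU >=
#'   threshold.
#' @return logical array aligned with the volume.
#' @export
threshold_mask <- function(volume, threshold = 130) {
  volume$data >= threshold
}

#' 3D connected-component labeling
#'
#' Labels maximal connected sets of TRUE voxels under the chosen
#' neighbourhood. Components are numbered deterministically in raster-scan
#' order of their first voxel (smallest z, then y, then x).
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  ccl3d(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

# Build a candidate record from its voxel index set (n x 3, 1-based).
new_candidate <- function(voxels, volume, id) {
  sp <- volume$spacing
  hu <- volume$data[voxels]
  nvox <- nrow(voxels)
  pix_area <- sp[1] * sp[2]
  slices <- sort(unique(voxels[, 3]))
  area <- vapply(slices, function(z) sum(voxels[, 3] == z) * pix_area, 0)
  smax <- vapply(slices, function(z) max(hu[voxels[, 3] == z]), 0)
  structure(list(
    id = id,
    voxels = voxels,
    centroid = volume$origin + (colMeans(voxels) - 1) * sp,
    bbox = rbind(min = apply(voxels, 2, min), max = apply(voxels, 2, max)),
    volume_mm3 = nvox * prod(sp),
    max_hu = max(hu),
    slice_stats = data.frame(slice = slices, area_mm2 = area, max_hu = smax),
    oversize = FALSE,
    label = "unclassified"
  ), class = "cac_candidate")
}

#' @export
print.cac_candidate <- function(x, ...) {
  cat(sprintf("candidate %d: %d voxels, %.2f mm^3, max %.0f HU, label '%s'\n",
              x$id, nrow(x$voxels), x$volume_mm3, x$max_hu, x$label))
  invisible(x)
}

#' Extract calcification candidates from a CT volume
#'
#' Applies the HU threshold and 3D connected-component labeling, fills
#' per-candidate geometry and per-slice statistics, removes candidates below
#' the minimum volume and flags oversize ones.
#'
#' @param volume a [ct_volume()].
#' @param config an [extraction_config()].
#' @return list of `cac_candidate` objects, ordered by first-voxel raster
#'   scan position.
#' @export
extract_candidates <- function(volume, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  labels <- label_components(threshold_mask(volume, config$threshold),
                             config$connectivity)
  nlab <- max(labels)
  if (nlab == 0L) return(list())
  vox <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  cands <- lapply(seq_len(nlab), function(i)
    new_candidate(vox[lab == i, , drop = FALSE], volume, i))
  cands <- Filter(function(cc) cc$volume_mm3 >= config$min_volume, cands)
  for (i in seq_along(cands)) {
    cands[[i]]$id <- i
    cands[[i]]$oversize <- cands[[i]]$volume_mm3 > config$max_volume
  }
  cands
}

#' Summarise a candidate list as a data frame
#'
#' @param candidates list of `cac_candidate`.
#' @return data.frame with one row per candidate.
#' @export
candidates_df <- function(candidates) {
  if (length(candidates) == 0L)
    return(data.frame(id = integer(), volume_mm3 = numeric(),
                      max_hu = numeric(), label = character(),
                      oversize = logical()))
  data.frame(
    id = vapply(candidates, function(x) x$id, 0L),
    volume_mm3 = vapply(candidates, function(x) x$volume_mm3, 0),
    max_hu = vapply(candidates, function(x) x$max_hu, 0),
    label = vapply(candidates, function(x) x$label, ""),
    oversize = vapply(candidates, function(x) x$oversize, FALSE))
}

#' Render candidate labels back into a volume
#'
#' @param candidates list of `cac_candidate`.
#' @param volume the originating [ct_volume()] (for geometry).
#' @return a [ct_volume()] whose voxel values are candidate ids (0 elsewhere).
#' @export
candidate_label_volume <- function(candidates, volume) {
  lab <- array(0L, dim(volume$data))
  for (cc in candidates) lab[cc$voxels] <- cc$id
  ct_volume(lab, volume$spacing, volume$origin,
            paste0(volume$scan_id, "_labels"), volume$slice_thickness)
}
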