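#' Read a CT volume from NIfTI
#'
#' Reads `.nii` / `.nii.gz` with [RNifti] and fails loudly if the header
#' carries no usable voxel spacing (all three pixdims must be strictly
#' positive) rather than silently assuming 1 mm voxels.
#'
#' @param path NIfTI file path.
#' @param slice_thickness reconstructed slice thickness metadata (mm);
#'   defaults to the z spacing.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, slice_thickness = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume in ", path)
  arr <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("volume ", path, " has no valid voxel spacing metadata")
  ct_volume(arr, sp,
            scan_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
            slice_thickness = slice_thickness %||% sp[3])
}

#' Write a CT volume (or mask) to NIfTI
#'
#' @param volume a [ct_volume()], or a logical/integer array with `spacing`
#'   given.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override when `volume` is a bare array.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$data
    sp <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("`spacing` required for a bare array")
    sp <- spacing
  }
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write per-scan score tables
#'
#' CSV with the fixed header `scan_id,agatston,volume_mm3,n_lesions,category`.
#'
#' @param scores data.frame of [score_scan()] records.
#' @param path CSV path.
#' @return `read_scores` returns the data.frame.
#' @export
write_scores <- function(scores, path) {
  stopifnot(all(c("scan_id", "agatston", "volume_mm3", "n_lesions",
                  "category") %in% names(scores)))
  write.csv(scores[, c("scan_id", "agatston", "volume_mm3", "n_lesions",
                       "category")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(scan_id = "character", category = "character"))
}

#' Serialise candidates to JSON and back
#'
#' Geometry and statistics only (voxel index sets, centroid, per-slice
#' stats, label); the grid geometry travels alongside so the list can be
#' re-rendered with [candidate_label_volume()].
#'
#' @param candidates list of `cac_candidate`.
#' @param path JSON path.
#' @return `read_candidates` returns the candidate list.
#' @export
write_candidates <- function(candidates, path) {
  obj <- lapply(candidates, function(cc) {
    list(id = cc$id, voxels = cc$voxels, centroid = cc$centroid,
         volume_mm3 = cc$volume_mm3, max_hu = cc$max_hu,
         slice_stats = cc$slice_stats, oversize = cc$oversize,
         label = cc$label)
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj) == 0L) return(list())
  lapply(seq_len(nrow(obj)), function(i) {
    vox <- matrix(unlist(obj$voxels[[i]]), ncol = 3)
    colnames(vox) <- c("dim1", "dim2", "dim3")
    ss <- obj$slice_stats[[i]]
    cc <- list(id = obj$id[i], voxels = vox,
               centroid = unlist(obj$centroid[[i]]),
               bbox = rbind(min = apply(vox, 2, min),
                            max = apply(vox, 2, max)),
               volume_mm3 = obj$volume_mm3[i], max_hu = obj$max_hu[i],
               slice_stats = as.data.frame(ss), oversize = obj$oversize[i],
               label = obj$label[i])
    class(cc) <- "cac_candidate"
    cc
  })
}
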