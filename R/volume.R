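#' CT volume container
#'
#' A minimal container for a 3D CT image in Hounsfield units. The array is
#' indexed `[x, y, z]` with z the slice axis; `spacing` gives the voxel size
#' in mm along (x, y, z) and `origin` the world coordinate (mm) of the centre
#' of voxel (1, 1, 1). World coordinates are therefore
#' `origin + (index - 1) * spacing`.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing numeric(3), voxel spacing in mm (x, y, z); strictly positive.
#' @param origin numeric(3), world position of the first voxel centre (mm).
#' @param scan_id character scan identifier.
#' @param slice_thickness reconstructed slice thickness in mm (may exceed the
#'   z spacing when slices overlap, e.g. 3.1 mm slices at 1.4 mm increment);
#'   stored as metadata and used only by Agatston score normalisation.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), scan_id = "scan",
                      slice_thickness = spacing[3]) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values (mm)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("HU values must be finite")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         scan_id = as.character(scan_id),
         slice_thickness = as.numeric(slice_thickness)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_volume '%s': %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$scan_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], slice thickness %.2f mm\n",
              min(x$data), max(x$data), x$slice_thickness))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# mm coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

# voxel volume in mm^3
voxel_volume <- function(vol) prod(vol$spacing)
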