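#' Scoring configuration
#'
#' Parameters of Agatston / volume / count quantification. The Agatston
#' density weight is derived from the per-slice maximum HU with the classic
#' bins 130-199 -> 1, 200-299 -> 2, 300-399 -> 3, >=400 -> 4. The Agatston
#' definition assumes contiguous 3 mm slices; for other reconstructions the
#' per-scan sum is multiplied by `slice_thickness / 3` (configurable via
#' `thickness_factor`). Volume and count are never thickness-normalised.
#'
#' @param hu_bins lower HU edges of the density-weight bins (weights
#'   1..length(hu_bins)); must be increasing with the first edge equal to the
#'   extraction threshold.
#' @param min_area minimum per-slice lesion area in mm^2 (default 1, the
#'   classic Agatston speck filter); slices below it contribute nothing.
#' @param cutoffs upper stratum bounds (0, 10, 100, 400) for risk
#'   categorisation.
#' @param slice_thickness reconstructed slice thickness in mm.
#' @param thickness_factor multiplier applied to the Agatston sum; default
#'   `slice_thickness / 3`.
#' @param threshold HU threshold shared with extraction.
#' @return An object of class `score_config`.
#' @export
score_config <- function(hu_bins = c(130, 200, 300, 400), min_area = 1,
                         cutoffs = c(0, 10, 100, 400), slice_thickness = 3.1,
                         thickness_factor = slice_thickness / 3,
                         threshold = 130) {
  if (is.unsorted(hu_bins, strictly = TRUE))
    stop("`hu_bins` must be strictly increasing")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("`cutoffs` must be strictly increasing")
  structure(list(hu_bins = hu_bins, min_area = min_area, cutoffs = cutoffs,
                 slice_thickness = slice_thickness,
                 thickness_factor = thickness_factor, threshold = threshold),
            class = "score_config")
}

#' Agatston density weight of a maximum HU value
#'
#' @param max_hu per-slice maximum HU (vectorised).
#' @param hu_bins lower bin edges, see [score_config()].
#' @return integer weight, 0 below the first edge.
#' @export
agatston_weight <- function(max_hu, hu_bins = c(130, 200, 300, 400)) {
  findInterval(max_hu, hu_bins)
}

#' Per-lesion Agatston contribution
#'
#' Sum over slices of area (mm^2) times the density weight of that slice's
#' maximum HU; slices with area below `min_area` are dropped; the total is
#' multiplied by the slice-thickness normalisation factor.
#'
#' @param candidate a `cac_candidate`.
#' @param config a [score_config()].
#' @return numeric Agatston contribution (unitless, >= 0).
#' @export
agatston_lesion <- function(candidate, config = score_config()) {
  ss <- candidate$slice_stats
  keep <- ss$area_mm2 >= config$min_area
  if (!any(keep)) return(0)
  sum(ss$area_mm2[keep] * agatston_weight(ss$max_hu[keep], config$hu_bins)) *
    config$thickness_factor
}

#' Total calcium volume of coronary-labeled candidates
#'
#' @param candidates list of `cac_candidate`.
#' @param config a [score_config()] (unused fields kept for symmetry).
#' @return total volume in mm^3 (voxel count times voxel volume; no
#'   thickness normalisation).
#' @export
volume_score <- function(candidates, config = score_config()) {
  cor <- Filter(function(x) identical(x$label, "coronary"), candidates)
  if (length(cor) == 0L) return(0)
  sum(vapply(cor, function(x) x$volume_mm3, 0))
}

#' Assign the cardiovascular risk stratum of an Agatston score
#'
#' Strata are half-open: 0 -> "0"; (0, 10] -> "1-10"; (10, 100] -> "11-100";
#' (100, 400] -> "101-400"; above 400 -> ">400". Fractional automated scores
#' are categorised without rounding.
#'
#' @param score Agatston score(s), must be >= 0.
#' @param cutoffs upper bounds of the first four strata.
#' @return factor with levels [risk_levels].
#' @export
risk_category <- function(score, cutoffs = c(0, 10, 100, 400)) {
  if (any(score < 0)) stop("Agatston scores must be non-negative")
  idx <- findInterval(score, cutoffs, left.open = TRUE)
  factor(risk_levels[idx + 1L], levels = risk_levels)
}

#' Score one scan
#'
#' Aggregates the coronary-labeled candidates of a scan into the per-scan
#' Agatston score, calcium volume, number of calcifications, and risk
#' category.
#'
#' @param candidates classified candidate list.
#' @param config a [score_config()].
#' @param scan_id scan identifier for the record.
#' @return one-row data.frame: `scan_id, agatston, volume_mm3, n_lesions,
#'   category`.
#' @export
score_scan <- function(candidates, config = score_config(), scan_id = "scan") {
  cor <- Filter(function(x) identical(x$label, "coronary"), candidates)
  ag <- if (length(cor)) sum(vapply(cor, agatston_lesion, 0, config = config)) else 0
  data.frame(
    scan_id = scan_id,
    agatston = ag,
    volume_mm3 = volume_score(candidates, config),
    n_lesions = length(cor),
    category = as.character(risk_category(ag, config$cutoffs)),
    stringsAsFactors = FALSE)
}
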