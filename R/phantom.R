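#' Synthetic chest-CT phantom generator
#'
#' Deterministic, seeded generation of non-gated low-dose chest-CT-like
#' volumes with known ground truth, so the whole scoring pipeline can be
#' exercised without patient data. Lesions are rendered as Gaussian-profile
#' spheres whose profile crosses the 130 HU calcium threshold exactly at the
#' nominal radius, which gives an analytic volume oracle; Gaussian noise and
#' optional one-dimensional motion blur (anterior-posterior, i.e. the y axis)
#' are applied after lesion rendering, while the ground truth reflects the
#' clean pre-noise geometry.
#'
#' @name phantom
NULL

# Geometric stand-ins for the coronary and aortic territories: fixed boxes
# (mm, c(lo, hi) per axis) inside the default 72 x 72 x 40 grid at
# 0.66 x 0.66 x 1.4 mm spacing.
territory_boxes <- list(
  coronary = rbind(lo = c(8, 8, 8),   hi = c(22, 22, 48)),
  aorta    = rbind(lo = c(26, 26, 8), hi = c(40, 40, 48))
)

#' Define a phantom lesion
#'
#' @param center numeric(3) world coordinates (mm).
#' @param radius sphere radius in mm (> 0); the rendered HU profile crosses
#'   130 HU at this radius.
#' @param peak_hu peak HU at the lesion centre (>= 130).
#' @param territory one of "coronary", "aorta", "valve", "bone".
#' @return list describing the lesion.
#' @export
phantom_lesion <- function(center, radius, peak_hu,
                           territory = c("coronary", "aorta", "valve", "bone")) {
  territory <- match.arg(territory)
  if (radius <= 0) stop("lesion radius must be > 0")
  if (peak_hu < 130) stop("calcified lesion peak HU must be >= 130")
  list(center = as.numeric(center), radius = radius, peak_hu = peak_hu,
       territory = territory)
}

#' Phantom configuration
#'
#' Defaults mirror a low-dose lung-screening reconstruction: in-plane
#' spacing 0.66 mm, slice increment 1.4 mm, with a 3.1 mm slice thickness
#' recorded as metadata (used only by Agatston normalisation). The z grid is
#' generated at the 1.4 mm increment.
#'
#' @param dim integer(3) grid size in voxels (x, y, z).
#' @param spacing voxel spacing mm.
#' @param slice_thickness reconstructed thickness mm (metadata).
#' @param background_mean soft-tissue background HU.
#' @param noise_sd additive Gaussian noise sd (HU), applied after rendering.
#' @param motion_blur_sigma sd (mm) of 1D Gaussian blur along y emulating
#'   cardiac motion unsharpness; 0 disables.
#' @param lesions list of [phantom_lesion()].
#' @param rater_noise list(p_drop, p_add, jitter_sd) used by
#'   [simulate_rater_scores()].
#' @param seed integer RNG seed; a fixed seed makes the output bit-identical.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(72, 72, 40), spacing = c(0.66, 0.66, 1.4),
                           slice_thickness = 3.1, background_mean = 30,
                           noise_sd = 0, motion_blur_sigma = 0,
                           lesions = list(),
                           rater_noise = list(p_drop = 0, p_add = 0,
                                              jitter_sd = 0),
                           seed = 1L) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (noise_sd < 0 || motion_blur_sigma < 0)
    stop("noise and blur parameters must be non-negative")
  extent <- (dim - 1) * spacing
  for (L in lesions) {
    if (any(L$center - L$radius < 0) || any(L$center + L$radius > extent))
      stop(sprintf(
        "lesion at (%.1f, %.1f, %.1f) mm with radius %.1f mm extends outside the grid",
        L$center[1], L$center[2], L$center[3], L$radius))
  }
  structure(list(dim = as.integer(dim), spacing = spacing,
                 slice_thickness = slice_thickness,
                 background_mean = background_mean, noise_sd = noise_sd,
                 motion_blur_sigma = motion_blur_sigma, lesions = lesions,
                 rater_noise = rater_noise, seed = as.integer(seed)),
            class = "phantom_config")
}

# Gaussian-profile sphere: peak at centre, exactly 130 HU at `radius`.
render_lesions <- function(config) {
  d <- config$dim
  profile <- array(0, d)
  labels <- array(0L, d)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * config$spacing[a])
  for (i in seq_along(config$lesions)) {
    L <- config$lesions[[i]]
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - L$center[a]) <= 2 * L$radius)
    })
    if (any(lengths(rng) == 0)) next
    d2 <- outer(outer((ax[[1]][rng[[1]]] - L$center[1])^2,
                      (ax[[2]][rng[[2]]] - L$center[2])^2, "+"),
                (ax[[3]][rng[[3]]] - L$center[3])^2, "+")
    if (L$peak_hu > 130) {
      s2 <- L$radius^2 / (2 * log(L$peak_hu / 130))
      val <- L$peak_hu * exp(-d2 / (2 * s2))
    } else {
      val <- ifelse(d2 <= L$radius^2, 130, 0)
    }
    sub <- profile[rng[[1]], rng[[2]], rng[[3]]]
    win <- val > sub
    inside <- d2 <= L$radius^2 & win
    profile[rng[[1]], rng[[2]], rng[[3]]][win] <- val[win]
    lsub <- labels[rng[[1]], rng[[2]], rng[[3]]]
    lsub[inside] <- i
    labels[rng[[1]], rng[[2]], rng[[3]]] <- lsub
  }
  list(profile = profile, labels = labels)
}

#' Generate a phantom volume with ground truth
#'
#' @param config a [phantom_config()].
#' @return list with elements
#'   * `volume`: the noisy/blurred [ct_volume()] the pipeline sees,
#'   * `clean`: the pre-noise rendered volume,
#'   * `truth`: list(mask — logical coronary-calcium mask, labels — integer
#'     per-lesion label array covering all territories, lesions — per-lesion
#'     data.frame (id, territory, volume_mm3, agatston), score — the
#'     scan-level true score record).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  rend <- render_lesions(config)
  clean_arr <- pmax(rend$profile, config$background_mean)
  vol_arr <- clean_arr
  if (config$motion_blur_sigma > 0)
    vol_arr <- gaussian_smooth(vol_arr, c(0, config$motion_blur_sigma, 0),
                               config$spacing)
  if (config$noise_sd > 0)
    vol_arr <- vol_arr + with_seed(config$seed,
      array(rnorm(prod(config$dim), 0, config$noise_sd), config$dim))

  clean <- ct_volume(clean_arr, config$spacing, scan_id = "clean",
                     slice_thickness = config$slice_thickness)
  volume <- ct_volume(vol_arr, config$spacing,
                      scan_id = sprintf("phantom_%d", config$seed),
                      slice_thickness = config$slice_thickness)

  territories <- vapply(config$lesions, function(L) L$territory, "")
  sconf <- score_config(slice_thickness = config$slice_thickness)
  cands <- lapply(seq_along(config$lesions), function(i) {
    vox <- which(rend$labels == i, arr.ind = TRUE)
    if (nrow(vox) == 0L) return(NULL)
    cc <- new_candidate(vox, clean, i)
    cc$label <- if (territories[i] == "coronary") "coronary" else "non-coronary"
    cc
  })
  keep <- !vapply(cands, is.null, TRUE)
  cands <- cands[keep]
  lesions <- data.frame(
    id = vapply(cands, function(x) x$id, 0L),
    territory = territories[vapply(cands, function(x) x$id, 0L)],
    volume_mm3 = vapply(cands, function(x) x$volume_mm3, 0),
    agatston = vapply(cands, agatston_lesion, 0, config = sconf))
  truth_score <- score_scan(cands, sconf, volume$scan_id)

  list(volume = volume, clean = clean,
       truth = list(mask = rend$labels > 0L &
                      territories[pmax(rend$labels, 1L)] == "coronary",
                    labels = rend$labels, lesions = lesions,
                    score = truth_score))
}

#' Draw a phantom configuration under the default study conditions
#'
#' Samples 0-4 coronary lesions (radius 1.5-4 mm, peak 180-700 HU) in the
#' fixed coronary territory box and 0-2 aortic distractors (radius 2-5 mm)
#' in the disjoint aortic box, on the default grid.
#'
#' @param seed integer seed; drives both the scene sampling and the phantom's
#'   own noise stream.
#' @param noise_sd Gaussian noise sd in HU (default 20).
#' @param motion_blur_sigma motion blur sd in mm (default 0).
#' @return a [phantom_config()].
#' @export
study_phantom_config <- function(seed, noise_sd = 20, motion_blur_sigma = 0) {
  with_seed(seed, {
    n_cor <- sample(0:4, 1)
    n_ao <- sample(0:2, 1)
    lesions <- list()
    for (i in seq_len(n_cor)) {
      b <- territory_boxes$coronary
      lesions[[length(lesions) + 1L]] <- phantom_lesion(
        center = runif(3, b["lo", ], b["hi", ]),
        radius = runif(1, 1.5, 4), peak_hu = runif(1, 180, 700),
        territory = "coronary")
    }
    for (i in seq_len(n_ao)) {
      b <- territory_boxes$aorta
      lesions[[length(lesions) + 1L]] <- phantom_lesion(
        center = runif(3, b["lo", ], b["hi", ]),
        radius = runif(1, 2, 5), peak_hu = runif(1, 180, 700),
        territory = "aorta")
    }
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
    phantom_config(lesions = lesions, noise_sd = noise_sd,
                   motion_blur_sigma = motion_blur_sigma, seed = noise_seed)
  })
}

#' Simulate a noisy rater re-scoring of a truth table
#'
#' Perturbs a per-scan score table with a simple rater-noise model: each of a
#' scan's lesions is independently dropped with probability `p_drop`
#' (remaining scores scaled by the kept fraction), with probability `p_add`
#' one small spurious lesion is added, and surviving scores receive a
#' multiplicative log-normal jitter of sd `jitter_sd`. Zero noise returns the
#' reference column unchanged.
#'
#' @param truth_table data.frame with columns `scan_id, agatston, volume_mm3,
#'   n_lesions` (a stack of [score_scan()] records).
#' @param rater_noise list(p_drop, p_add, jitter_sd), all non-negative,
#'   probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame pairing reference and perturbed values:
#'   `scan_id, agatston_ref, agatston_auto, volume_ref, volume_auto, n_ref,
#'   n_auto, category_ref, category_auto`.
#' @export
simulate_rater_scores <- function(truth_table,
                                  rater_noise = list(p_drop = 0, p_add = 0,
                                                     jitter_sd = 0),
                                  seed = 1L) {
  if (nrow(truth_table) == 0L) stop("`truth_table` must be nonempty")
  p_drop <- rater_noise$p_drop %||% 0
  p_add <- rater_noise$p_add %||% 0
  jitter_sd <- rater_noise$jitter_sd %||% 0
  if (p_drop < 0 || p_drop > 1 || p_add < 0 || p_add > 1 || jitter_sd < 0)
    stop("rater-noise parameters must be non-negative (probabilities in [0, 1])")
  n <- nrow(truth_table)
  with_seed(seed, {
    ag <- vol <- numeric(n)
    nl <- integer(n)
    for (i in seq_len(n)) {
      m <- truth_table$n_lesions[i]
      kept <- if (m > 0) stats::rbinom(1, m, 1 - p_drop) else 0L
      frac <- if (m > 0) kept / m else 1
      jit <- if (jitter_sd > 0) exp(rnorm(1, 0, jitter_sd)) else 1
      ag[i] <- truth_table$agatston[i] * frac * jit
      vol[i] <- truth_table$volume_mm3[i] * frac * jit
      nl[i] <- kept
      if (p_add > 0 && runif(1) < p_add) {
        extra <- runif(1, 1, 10)
        ag[i] <- ag[i] + extra
        vol[i] <- vol[i] + extra
        nl[i] <- nl[i] + 1L
      }
    }
    data.frame(
      scan_id = truth_table$scan_id,
      agatston_ref = truth_table$agatston, agatston_auto = ag,
      volume_ref = truth_table$volume_mm3, volume_auto = vol,
      n_ref = truth_table$n_lesions, n_auto = nl,
      category_ref = as.character(risk_category(truth_table$agatston)),
      category_auto = as.character(risk_category(ag)),
      stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
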