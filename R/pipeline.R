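#' Scan-to-atlas transform used by the pipeline
#'
#' Moment-matching transform computed from the thoracic soft-tissue region
#' (HU above `hu_min`), the desk-scale stand-in for heart-region
#' registration.
#'
#' @param volume a [ct_volume()].
#' @param hu_min lower HU bound of the region used for moment matching.
#' @return a `spatial_transform`.
#' @export
scan_transform <- function(volume, hu_min = -200) {
  moment_transform(volume$data > hu_min, volume$spacing, volume$origin)
}

#' Train the detector (atlas + classifier) on labelled phantoms
#'
#' Builds the coronary calcium atlas from the phantoms' ground-truth masks
#' and their moment transforms, extracts candidates from the noisy volumes,
#' labels each candidate by majority overlap with the ground-truth lesion
#' map, and trains the two-stage classifier on the pooled features.
#'
#' @param phantoms list of [generate_phantom()] results.
#' @param extraction an [extraction_config()].
#' @param scales texture scales (mm).
#' @param atlas_sigma atlas smoothing in reference-frame units.
#' @param seed integer seed for the classifier.
#' @param ... further arguments to [train_classifier()].
#' @return list(atlas, model, transform_fun).
#' @export
train_detector <- function(phantoms, extraction = extraction_config(),
                           scales = c(1, 2, 4), atlas_sigma = 0.2, seed = 1L,
                           ...) {
  transforms <- lapply(phantoms, function(p) scan_transform(p$volume))
  atlas <- build_atlas(
    masks = lapply(phantoms, function(p) p$truth$mask),
    spacings = lapply(phantoms, function(p) p$volume$spacing),
    transforms = transforms, sigma = atlas_sigma)
  feats <- list(); labs <- list()
  for (i in seq_along(phantoms)) {
    p <- phantoms[[i]]
    cands <- extract_candidates(p$volume, extraction)
    if (length(cands) == 0L) next
    feats[[length(feats) + 1L]] <-
      featurize(cands, p$volume, atlas, transforms[[i]], scales)
    labs[[length(labs) + 1L]] <- truth_candidate_labels(cands, p$truth)
  }
  x <- do.call(rbind, feats)
  y <- unlist(labs)
  model <- train_classifier(x, y == "coronary", seed = seed, ...)
  list(atlas = atlas, model = model, scales = scales,
       extraction = extraction)
}

#' Ground-truth label of each extracted candidate
#'
#' A candidate is "coronary" when the majority of its voxels fall on
#' coronary-territory lesions of the ground-truth label map, otherwise
#' "non-coronary" (aortic/valve/bone lesions and pure-noise components).
#'
#' @param candidates list of `cac_candidate`.
#' @param truth the `truth` element of [generate_phantom()].
#' @return character vector of labels.
#' @export
truth_candidate_labels <- function(candidates, truth) {
  vapply(candidates, function(cc) {
    cor_frac <- mean(truth$mask[cc$voxels])
    if (cor_frac > 0.5) "coronary" else "non-coronary"
  }, "")
}

#' Score a CT volume with a trained detector
#'
#' Extract, featurize, classify, score: the fully automated path from HU
#' volume to score record.
#'
#' @param volume a [ct_volume()].
#' @param detector result of [train_detector()] (atlas + model).
#' @param score a [score_config()]; its slice thickness defaults to the
#'   volume's metadata.
#' @return list(record — one-row score data.frame, candidates — classified
#'   candidate list).
#' @export
score_volume <- function(volume, detector,
                         score = score_config(
                           slice_thickness = volume$slice_thickness)) {
  cands <- extract_candidates(volume, detector$extraction)
  if (length(cands) > 0L) {
    tf <- scan_transform(volume)
    feat <- featurize(cands, volume, detector$atlas, tf, detector$scales)
    cls <- classify(detector$model, feat)
    for (i in seq_along(cands)) cands[[i]]$label <- cls$label[i]
  }
  list(record = score_scan(cands, score, volume$scan_id),
       candidates = cands)
}

#' Run the automated scoring pipeline over a set of volumes
#'
#' Applies [score_volume()] to each input (a `ct_volume` or a NIfTI path)
#' and stacks the per-scan records. Per-scan failures are caught, reported
#' as warnings, and recorded in the `failures` attribute.
#'
#' @param inputs list of [ct_volume()] objects and/or NIfTI paths.
#' @param detector result of [train_detector()].
#' @param score a [score_config()] (NULL = per-volume default).
#' @return data.frame of score records (attribute `failures`: named list of
#'   error messages for scans that could not be processed).
#' @export
run_pipeline <- function(inputs, detector, score = NULL) {
  records <- list(); failures <- list()
  if (length(inputs) == 0L) warning("no input volumes")
  for (i in seq_along(inputs)) {
    res <- tryCatch({
      vol <- inputs[[i]]
      if (is.character(vol)) vol <- read_volume(vol)
      sc <- score %||% score_config(slice_thickness = vol$slice_thickness)
      score_volume(vol, detector, sc)$record
    }, error = function(e) e)
    if (inherits(res, "error")) {
      id <- if (is.character(inputs[[i]])) inputs[[i]] else
        sprintf("input %d", i)
      warning("scan ", id, " failed: ", conditionMessage(res))
      failures[[id]] <- conditionMessage(res)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(scan_id = character(), agatston = numeric(),
               volume_mm3 = numeric(), n_lesions = integer(),
               category = character(), stringsAsFactors = FALSE)
  attr(out, "failures") <- failures
  out
}

#' Train-and-evaluate the detector on seeded phantom cohorts
#'
#' Generates `n_train` phantoms for training and `n_test` held-out phantoms
#' under the default study conditions, trains the detector, and evaluates
#' per-candidate classification accuracy and scan-level risk-category
#' agreement (linearly weighted kappa of automated vs ground-truth
#' categories) on the held-out cohort.
#'
#' @param n_train,n_test cohort sizes.
#' @param seed master seed; per-phantom seeds are drawn from it.
#' @param noise_sd phantom noise sd in HU.
#' @param motion_blur_sigma phantom motion blur sd in mm.
#' @return list(accuracy, kappa, n_candidates, scores — per-scan data.frame
#'   with truth and automated records, detector).
#' @export
evaluate_pipeline <- function(n_train = 50, n_test = 50, seed = 1L,
                              noise_sd = 20, motion_blur_sigma = 0) {
  seeds <- with_seed(seed, sample.int(1e8, n_train + n_test))
  make <- function(s) generate_phantom(
    study_phantom_config(s, noise_sd = noise_sd,
                         motion_blur_sigma = motion_blur_sigma))
  train <- lapply(seeds[seq_len(n_train)], make)
  test <- lapply(seeds[n_train + seq_len(n_test)], make)
  detector <- train_detector(train, seed = seed)

  n_ok <- 0L; n_tot <- 0L
  recs <- list()
  for (p in test) {
    sv <- score_volume(p$volume, detector)
    if (length(sv$candidates) > 0L) {
      truth_lab <- truth_candidate_labels(sv$candidates, p$truth)
      pred_lab <- vapply(sv$candidates, function(x) x$label, "")
      n_ok <- n_ok + sum(pred_lab == truth_lab)
      n_tot <- n_tot + length(pred_lab)
    }
    recs[[length(recs) + 1L]] <- data.frame(
      scan_id = p$volume$scan_id,
      truth_agatston = p$truth$score$agatston,
      truth_category = p$truth$score$category,
      auto_agatston = sv$record$agatston,
      auto_category = sv$record$category,
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, recs)
  kap <- weighted_kappa(confusion_matrix(scores$truth_category,
                                         scores$auto_category))
  list(accuracy = if (n_tot > 0) n_ok / n_tot else NA_real_,
       kappa = kap, n_candidates = n_tot, scores = scores,
       detector = detector)
}
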