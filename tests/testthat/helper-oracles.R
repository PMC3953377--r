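# Independent oracles and small fixture builders used across the suite.

# Brute-force flood-fill labeling, independent of the compiled path.
flood_labels_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(offs))
  keep <- manh > 0 &
    (connectivity == 26 | (connectivity == 18 & manh <= 2) |
       (connectivity == 6 & manh == 1))
  offs <- offs[keep, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- list(as.integer(arrayInd(start, d)))
    lab[start] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1L) || any(w > d)) next
        wm <- matrix(w, 1)
        if (mask[wm] && lab[wm] == 0L) {
          lab[wm] <- cur
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# Canonical partition of a label array: list of sorted linear-index sets,
# ordered by their smallest member (numbering-independent comparison).
label_partition <- function(lab) {
  sets <- split(which(lab > 0L), lab[lab > 0L])
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, min, 0))])
}

# ICC oracle through stats::aov mean squares (independent ANOVA route).
icc_aov_oracle <- function(x, model = "two-way-mixed") {
  n <- nrow(x)
  k <- ncol(x)
  df <- data.frame(value = as.vector(x),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (model == "two-way-mixed") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

# One-lesion phantom used by several extraction/scoring tests.
one_lesion_phantom <- function(radius = 2, peak = 300, noise_sd = 0,
                               seed = 1L, territory = "coronary", ...) {
  center <- if (territory == "coronary") c(15, 15, 28) else c(33, 33, 28)
  generate_phantom(phantom_config(
    lesions = list(phantom_lesion(center, radius, peak, territory)),
    noise_sd = noise_sd, seed = seed, ...))
}

# Hand-built candidate with prescribed per-slice statistics.
fake_candidate <- function(areas, max_hus, slices = seq_along(areas),
                           label = "coronary", volume_mm3 = 1) {
  structure(list(
    id = 1L, voxels = matrix(1L, 1, 3), centroid = c(0, 0, 0),
    bbox = NULL, volume_mm3 = volume_mm3, max_hu = max(max_hus),
    slice_stats = data.frame(slice = slices, area_mm2 = areas,
                             max_hu = max_hus),
    oversize = FALSE, label = label), class = "cac_candidate")
}
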