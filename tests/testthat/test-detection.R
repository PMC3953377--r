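test_that("identity-frame atlas reproduces its training mask", {
  mask <- array(FALSE, c(8, 8, 8))
  mask[3:5, 3:5, 3:5] <- TRUE
  atlas <- build_atlas(list(mask), c(1, 1, 1))
  expect_equal(atlas$prob, array(as.numeric(mask), dim(mask)))
  # mean is idempotent for duplicated masks
  atlas2 <- build_atlas(list(mask, mask, mask), c(1, 1, 1))
  expect_equal(atlas2$prob, atlas$prob)
  # probability 1 inside the always-calcified region, 0 far outside
  expect_equal(spatial_probability(atlas, matrix(c(3, 3, 3), 1)), 1)
  expect_equal(spatial_probability(atlas, matrix(c(7, 7, 7), 1)), 0)
  # out of frame by contract
  expect_equal(spatial_probability(atlas, matrix(c(50, 0, 0), 1)), 0)
})

test_that("atlas probabilities stay in [0,1]; mass grows with mask volume", {
  small <- array(FALSE, c(8, 8, 8)); small[4, 4, 4] <- TRUE
  big <- array(FALSE, c(8, 8, 8)); big[3:6, 3:6, 3:6] <- TRUE
  a_small <- build_atlas(list(small), c(1, 1, 1), sigma = 1)
  a_big <- build_atlas(list(big), c(1, 1, 1), sigma = 1)
  for (a in list(a_small, a_big)) {
    expect_gte(min(a$prob), 0)
    expect_lte(max(a$prob), 1)
  }
  expect_gt(sum(a_big$prob), sum(a_small$prob))
  expect_error(build_atlas(list(), c(1, 1, 1)), "at least one")
})

test_that("trilinear interpolation is exact at voxel centres and midpoints", {
  arr <- array(0, c(2, 2, 2))
  arr[2, 1, 1] <- 1
  expect_equal(interp_trilinear(arr, c(1, 1, 1), c(0, 0, 0),
                                matrix(c(0.5, 0, 0), 1)), 0.5)
  expect_equal(interp_trilinear(arr, c(1, 1, 1), c(0, 0, 0),
                                matrix(c(1, 0, 0), 1)), 1)
  expect_equal(interp_trilinear(arr, c(1, 1, 1), c(0, 0, 0),
                                matrix(c(-1, 0, 0), 1), outside = 0), 0)
})

test_that("texture features: constant volume has zero derivatives", {
  v <- ct_volume(array(77, c(16, 16, 16)), c(1, 1, 1))
  f <- texture_features(v, matrix(c(8, 8, 8), 1), scales = c(1, 2))
  expect_equal(unname(f[1, c("grad_s1", "lap_s1", "grad_s2", "lap_s2")]),
               rep(0, 4))
  expect_equal(unname(f[1, "int_s1"]), 77)
})

test_that("smoothed Gaussian blob peak matches the closed form", {
  # A * (s0^2 / (s0^2 + s^2))^{3/2} for an isotropic blob of width s0
  s0 <- 3; A <- 100
  n <- 49; sp <- c(0.5, 0.5, 0.5)
  ax <- (seq_len(n) - 1) * sp[1] - 12
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  v <- ct_volume(A * exp(-d2 / (2 * s0^2)), sp)
  for (s in c(1, 2)) {
    f <- texture_features(v, matrix(c(12, 12, 12), 1), scales = s)
    expected <- A * (s0^2 / (s0^2 + s^2))^1.5
    expect_lt(abs(f[1, 1] - expected), 0.05 * expected)
  }
})

test_that("texture intensity and gradient features are linear in HU", {
  p <- one_lesion_phantom(radius = 2.5, peak = 400)
  pt <- matrix(c(15, 15, 28), 1)
  f1 <- texture_features(p$clean, pt, scales = c(1, 2))
  v2 <- ct_volume(2 * p$clean$data, p$clean$spacing)
  f2 <- texture_features(v2, pt, scales = c(1, 2))
  expect_equal(unname(f2), unname(2 * f1), tolerance = 1e-12)
})

test_that("featurize contract: passthrough volume, empty list, determinism", {
  p <- one_lesion_phantom(radius = 2, peak = 300, noise_sd = 10, seed = 6)
  cands <- extract_candidates(p$volume)
  tf <- scan_transform(p$volume)
  atlas <- build_atlas(list(p$truth$mask), list(p$volume$spacing),
                       transforms = list(tf), sigma = 0.2)
  f <- featurize(cands, p$volume, atlas, tf)
  expect_equal(nrow(f), length(cands))
  expect_identical(colnames(f), feature_names())
  expect_equal(unname(f[, "volume_mm3"]),
               vapply(cands, function(x) x$volume_mm3, 0))
  expect_identical(f, featurize(cands, p$volume, atlas, tf))
  empty <- featurize(list(), p$volume, atlas, tf)
  expect_equal(nrow(empty), 0)
  expect_identical(colnames(empty), feature_names())
})

sep_features <- function(n = 500, seed = 1) {
  # two 2D Gaussians 6 sigma apart
  with_seed(seed, {
    x <- rbind(cbind(rnorm(n), rnorm(n)), cbind(rnorm(n) + 6, rnorm(n)))
    list(x = x, y = rep(c(FALSE, TRUE), each = n))
  })
}

test_that("classifier separates well-separated classes", {
  d <- sep_features()
  model <- train_classifier(d$x, d$y, seed = 2)
  pred <- classify(model, d$x)
  acc <- mean((pred$label == "coronary") == d$y)
  expect_gte(acc, 0.99)
  # inverted labels invert the decisions on the same data
  inv <- train_classifier(d$x, !d$y, seed = 2)
  pred_inv <- classify(inv, d$x)
  expect_true(all((pred_inv$label == "coronary") ==
                    (pred$label == "non-coronary")))
})

test_that("classifier is deterministic and duplication-stable", {
  d <- sep_features(n = 200)
  model <- train_classifier(d$x, d$y, seed = 5)
  p1 <- classify(model, d$x)
  p2 <- classify(model, d$x)
  expect_identical(p1, p2)
  dup <- train_classifier(rbind(d$x, d$x), c(d$y, d$y), seed = 5)
  expect_equal(classify(dup, d$x)$label, p1$label)
})

test_that("posterior band routes between pure kNN and pure SVM", {
  d <- sep_features(n = 150)
  knn_only <- train_classifier(d$x, d$y, band = c(0.5, 0.5), seed = 1)
  svm_only <- train_classifier(d$x, d$y, band = c(0, 1), seed = 1)
  pk <- classify(knn_only, d$x)
  ps <- classify(svm_only, d$x)
  expect_true(all(pk$stage == "knn"))
  expect_true(all(ps$stage == "svm"))
  expect_equal(classify(knn_only, matrix(numeric(0), 0, 2))$label,
               character(0))
})

test_that("classifier rejects degenerate input", {
  d <- sep_features(n = 50)
  expect_error(train_classifier(d$x, rep(TRUE, nrow(d$x))), "both classes")
  model <- train_classifier(d$x, d$y, seed = 1)
  expect_error(classify(model, matrix(0, 2, 5)), "dimension")
})

test_that("classifier archive round-trips to identical decisions", {
  d <- sep_features(n = 120, seed = 3)
  model <- train_classifier(d$x, d$y, seed = 4)
  path <- tempfile(fileext = ".json")
  save_classifier(model, path)
  restored <- load_classifier(path)
  grid <- with_seed(9, cbind(runif(200, -3, 9), rnorm(200)))
  expect_equal(classify(restored, grid)$label, classify(model, grid)$label)
  unlink(path)
})
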