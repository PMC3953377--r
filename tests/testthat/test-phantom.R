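test_that("lesion-free noiseless phantom is flat background with score zero", {
  p <- generate_phantom(phantom_config(dim = c(20, 20, 10), seed = 5))
  expect_true(all(p$volume$data == 30))
  expect_equal(p$truth$score$agatston, 0)
  expect_equal(p$truth$score$volume_mm3, 0)
  expect_equal(p$truth$score$category, "0")
  expect_equal(sum(p$truth$mask), 0)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- phantom_config(
    lesions = list(phantom_lesion(c(15, 15, 28), 2.5, 400, "coronary")),
    noise_sd = 15, motion_blur_sigma = 1, seed = 42)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_identical(a$truth$score, b$truth$score)
})

test_that("rendered sphere volume matches the rasterized analytic sphere", {
  # oracle: count voxels of the analytic sphere rasterized on the stated grid
  radius <- 2
  center <- c(15, 15, 28)
  sp <- c(0.66, 0.66, 1.4)
  ax <- lapply(1:3, function(a) (seq_len(c(72, 72, 40)[a]) - 1) * sp[a])
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
              (ax[[3]] - center[3])^2, "+")
  oracle_vol <- sum(d2 <= radius^2) * prod(sp)
  p <- one_lesion_phantom(radius = radius, peak = 300)
  expect_equal(p$truth$lesions$volume_mm3, oracle_vol)
  expect_lt(abs(p$truth$lesions$volume_mm3 - 4 / 3 * pi * radius^3),
            0.15 * (4 / 3 * pi * radius^3))
})

test_that("truth mask equals the 130 HU support of the clean volume", {
  p <- one_lesion_phantom(radius = 3, peak = 500)
  expect_identical(p$truth$mask, p$clean$data >= 130)
  # with aortic lesions the coronary mask is a subset of the 130 HU support
  q <- generate_phantom(phantom_config(
    lesions = list(phantom_lesion(c(15, 15, 28), 2, 300, "coronary"),
                   phantom_lesion(c(33, 33, 28), 3, 400, "aorta")),
    seed = 2))
  expect_true(all(!q$truth$mask | q$clean$data >= 130))
  expect_lt(sum(q$truth$mask), sum(q$clean$data >= 130))
})

test_that("motion blur changes the rendered volume but never the ground truth", {
  les <- list(phantom_lesion(c(15, 15, 28), 2.5, 400, "coronary"))
  a <- generate_phantom(phantom_config(lesions = les, seed = 3))
  b <- generate_phantom(phantom_config(lesions = les, motion_blur_sigma = 2,
                                       seed = 3))
  expect_identical(a$truth$mask, b$truth$mask)
  expect_identical(a$truth$score, b$truth$score)
  expect_false(identical(a$volume$data, b$volume$data))
})

test_that("lesions outside the grid are rejected with an informative error", {
  expect_error(
    phantom_config(lesions = list(phantom_lesion(c(1, 15, 28), 3, 300))),
    "outside the grid")
  expect_error(phantom_lesion(c(10, 10, 10), -1, 300), "radius")
  expect_error(phantom_lesion(c(10, 10, 10), 2, 100), ">= 130")
})

test_that("rater simulation: zero noise is the identity", {
  truth <- data.frame(scan_id = letters[1:4],
                      agatston = c(0, 5, 120, 900),
                      volume_mm3 = c(0, 6, 140, 800),
                      n_lesions = c(0L, 1L, 3L, 6L))
  sim <- simulate_rater_scores(truth, seed = 9)
  expect_equal(sim$agatston_auto, sim$agatston_ref)
  expect_equal(sim$volume_auto, sim$volume_ref)
  expect_equal(sim$n_auto, sim$n_ref)
  m <- confusion_matrix(sim$category_ref, sim$category_auto)
  expect_equal(weighted_kappa(m), 1.0)
})

test_that("rater simulation: drop probability one zeroes every score", {
  truth <- data.frame(scan_id = letters[1:3],
                      agatston = c(12, 250, 700),
                      volume_mm3 = c(15, 260, 650),
                      n_lesions = c(1L, 4L, 5L))
  sim <- simulate_rater_scores(truth, list(p_drop = 1, p_add = 0,
                                           jitter_sd = 0), seed = 1)
  expect_true(all(sim$agatston_auto == 0))
  expect_true(all(sim$n_auto == 0))
  expect_true(all(sim$category_auto == "0"))
})

test_that("rater simulation rejects negative noise parameters", {
  truth <- data.frame(scan_id = "a", agatston = 1, volume_mm3 = 1,
                      n_lesions = 1L)
  expect_error(simulate_rater_scores(truth, list(p_drop = -0.1, p_add = 0,
                                                 jitter_sd = 0)))
  expect_error(simulate_rater_scores(truth, list(p_drop = 0, p_add = 0,
                                                 jitter_sd = -1)))
  expect_error(simulate_rater_scores(truth[0, ]), "nonempty")
})

test_that("bundled category-shift matrix has the published margins", {
  m <- screening_shift_matrix()
  expect_equal(sum(m), 1749)
  expect_equal(sum(m[1, ]), 433)
  expect_equal(sum(m[, 1]), 545)
  expect_identical(rownames(m), risk_levels)
})
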