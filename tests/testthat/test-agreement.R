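test_that("confusion matrix construction, round trip, and transpose", {
  m <- confusion_matrix(rep("0", 3), rep("0", 3))
  expect_equal(sum(m), 3)
  expect_equal(m["0", "0"], 3)
  expect_equal(dim(m), c(5, 5))
  # rebuild the bundled matrix from expanded pairs
  fx <- screening_shift_matrix()
  ref <- rep(rep(risk_levels, each = 5), as.vector(t(fx)))
  auto <- rep(rep(risk_levels, times = 5), as.vector(t(fx)))
  expect_equal(unname(confusion_matrix(ref, auto)), unname(unclass(fx)))
  expect_equal(unname(confusion_matrix(auto, ref)),
               t(unname(unclass(fx))))
  expect_error(confusion_matrix("0", "huge"), "unknown")
})

test_that("proportion of agreement and shift histogram basics", {
  eye <- diag(5); dimnames(eye) <- list(risk_levels, risk_levels)
  expect_equal(proportion_agreement(eye), 1)
  off <- matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(proportion_agreement(off), 0)
  sh <- shift_counts(off)
  expect_equal(unname(sh$histogram["1"]), 5)
  expect_equal(sum(shift_counts(eye)$histogram[-1]), 0)
  # histogram conserves the total
  fx <- screening_shift_matrix()
  expect_equal(sum(shift_counts(fx)$histogram), sum(fx))
})

test_that("false-negative zeros count automated-zero over nonzero reference", {
  eye <- diag(5); dimnames(eye) <- list(risk_levels, risk_levels)
  expect_equal(false_negative_zero(eye)$count, 0)
  m <- matrix(0, 5, 5, dimnames = list(risk_levels, risk_levels))
  m[1, 1] <- 10; m[1, 3] <- 5   # reference all zero
  expect_equal(false_negative_zero(m)$count, 0)
  m[4, 1] <- 7
  expect_equal(false_negative_zero(m)$count, 7)
  expect_equal(false_negative_zero(m)$rate, 7 / 22)
})

test_that("weighted kappa: trivial matrices, transpose symmetry, 2x2 identity", {
  eye <- 10 * diag(5); dimnames(eye) <- list(risk_levels, risk_levels)
  expect_equal(weighted_kappa(eye), 1)
  flat <- matrix(25, 2, 2)
  expect_equal(weighted_kappa(flat), 0)
  m <- with_seed(5, matrix(rpois(25, 20), 5, 5))
  expect_equal(weighted_kappa(m), weighted_kappa(t(m)))
  # linear weights reduce to unweighted kappa on 2x2 tables
  m2 <- matrix(c(30, 5, 10, 55), 2, 2)
  po <- sum(diag(m2)) / sum(m2)
  pe <- sum(rowSums(m2) * colSums(m2)) / sum(m2)^2
  expect_equal(weighted_kappa(m2), (po - pe) / (1 - pe))
  expect_lte(weighted_kappa(m), 1)
})

test_that("weighted kappa of simulated pairs converges to the generating kappa", {
  fx <- screening_shift_matrix()
  target <- weighted_kappa(fx)
  cell <- with_seed(2024, sample.int(25, 1e5, replace = TRUE,
                                     prob = as.vector(fx) / sum(fx)))
  sim <- matrix(tabulate(cell, 25), 5, 5)
  expect_lt(abs(weighted_kappa(sim) - target), 0.01)
})

test_that("ICC equals the aov mean-squares oracle on random small tables", {
  for (seed in 1:100) {
    tab <- with_seed(seed, {
      n <- sample(2:6, 1); k <- sample(2:3, 1)
      matrix(rnorm(n * k, sd = sample(1:3, 1)), n, k) +
        rnorm(n)                      # subject effect
    })
    for (model in c("two-way-mixed", "two-way-random")) {
      expect_equal(icc(tab, model = model), icc_aov_oracle(tab, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("ICC: identical columns give 1; simulation recovers true ICC 0.8", {
  x <- cbind(1:10, 1:10)
  expect_equal(icc(x), 1)
  expect_equal(icc(x, model = "two-way-random"), 1)
  # subject variance 4, error variance 1 -> true consistency ICC 0.8
  tab <- with_seed(77, {
    s <- rnorm(1000, sd = 2)
    cbind(s + rnorm(1000), s + rnorm(1000))
  })
  expect_lt(abs(icc(tab) - 0.8), 0.03)
  expect_error(icc(matrix(5, 4, 2)), "undefined")
  expect_error(icc(matrix(1, 1, 2)), ">= 2")
})

test_that("Kendall's W: perfect concordance, Spearman identity, null level", {
  perfect <- cbind(1:8, 1:8, 1:8)
  expect_equal(kendalls_w(perfect), 1)
  # m = 2: W = (rho + 1) / 2 against a direct Spearman computation
  xy <- with_seed(21, cbind(rnorm(40), rnorm(40)))
  rho <- cor(xy[, 1], xy[, 2], method = "spearman")
  expect_equal(kendalls_w(xy), (rho + 1) / 2, tolerance = 1e-12)
  # independent ratings concord at the chance level E[W] = 1/m
  null <- with_seed(22, matrix(runif(400), 100, 4))
  expect_lt(abs(kendalls_w(null) - 0.25), 0.07)
  expect_error(kendalls_w(matrix(3, 5, 2)), "constant")
})

test_that("QCD from samples and from printed quartiles", {
  expect_equal(qcd(q = c(1, 9)), 0.8)
  expect_equal(round(qcd(q = c(1.1, 449.0)), 2), 1.00)
  expect_equal(qcd(rep(7, 10)), 0)
  x <- with_seed(3, rexp(200))
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  expect_equal(qcd(x), (q[2] - q[1]) / (q[2] + q[1]))
  expect_error(qcd(1:3), "at least 4")
})

test_that("paired difference summary uses reference minus automated", {
  expect_equal(paired_difference_summary(1:5, 1:5),
               c(median = 0, p25 = 0, p75 = 0))
  expect_equal(paired_difference_summary(c(6:10), c(1:5))[["median"]], 5)
  d <- paired_difference_summary(c(1, 2, 3, 4, 5) + 10, rep(10, 5))
  expect_equal(d[["median"]], 3)
})

test_that("agreement report assembles consistent blocks", {
  cats <- rep(risk_levels, times = c(5, 4, 3, 2, 1))
  rep1 <- agreement_report(cats, cats,
                           continuous = list(agatston = list(
                             ref = c(0, 4, 50, 200, 900, 30),
                             auto = c(0, 4, 50, 200, 900, 30))))
  expect_equal(rep1$categorical$proportion_agreement, 1)
  expect_equal(rep1$categorical$weighted_kappa, 1)
  expect_equal(rep1$categorical$n_shift_gt1, 0)
  expect_equal(rep1$continuous$agatston$icc, 1)
  # matrix-only input: categorical block only
  rep2 <- agreement_report(matrix = screening_shift_matrix())
  expect_length(rep2$continuous, 0)
  expect_equal(sum(rep2$categorical$shift_histogram),
               sum(screening_shift_matrix()))
  # simulated rater distortion: finite, internally consistent report
  truth <- data.frame(scan_id = sprintf("s%02d", 1:40),
                      agatston = with_seed(8, round(rexp(40, 1 / 150), 1)),
                      volume_mm3 = 0, n_lesions = rep(2:6, 8))
  truth$volume_mm3 <- truth$agatston * 1.2
  sim <- simulate_rater_scores(truth, list(p_drop = 0.2, p_add = 0.1,
                                           jitter_sd = 0.1), seed = 14)
  rep3 <- agreement_report(sim$category_ref, sim$category_auto,
                           continuous = list(agatston = list(
                             ref = sim$agatston_ref,
                             auto = sim$agatston_auto)))
  expect_equal(sum(rep3$categorical$shift_histogram), 40)
  expect_true(is.finite(rep3$categorical$weighted_kappa))
  expect_true(is.finite(rep3$continuous$agatston$icc))
})
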