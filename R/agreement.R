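#' Cross-tabulate paired risk categories
#'
#' @param ref,auto vectors of category labels (reference and automated),
#'   same length; every value must be one of `levels`.
#' @param levels ordered category labels (default the five Agatston risk
#'   strata).
#' @return k x k integer matrix, reference on rows.
#' @export
confusion_matrix <- function(ref, auto, levels = risk_levels) {
  ref <- as.character(ref); auto <- as.character(auto)
  bad <- setdiff(unique(c(ref, auto)), levels)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(ref, levels = levels), factor(auto, levels = levels))
  m <- unclass(m)
  names(dimnames(m)) <- c("reference", "automated")
  m
}

check_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2L)
    stop("need a square k x k matrix with k >= 2")
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) <= 0) stop("matrix total must be positive")
  invisible(m)
}

#' Proportion of agreement
#'
#' Fraction of subjects assigned the same category by both raters:
#' trace / total.
#'
#' @param m square confusion matrix of counts.
#' @return proportion in `[0, 1]`.
#' @export
proportion_agreement <- function(m) {
  check_matrix(m)
  sum(diag(m)) / sum(m)
}

#' Category-shift histogram
#'
#' Counts subjects by the absolute distance between their reference and
#' automated categories.
#'
#' @param m square confusion matrix.
#' @return list: `histogram` (named counts for shift 0 .. k-1), `n_gt1`
#'   (subjects shifted by more than one category), `total`.
#' @export
shift_counts <- function(m) {
  check_matrix(m)
  k <- nrow(m)
  d <- abs(row(m) - col(m))
  hist <- vapply(0:(k - 1), function(s) sum(m[d == s]), 0)
  names(hist) <- 0:(k - 1)
  list(histogram = hist, n_gt1 = sum(hist[-(1:2)]), total = sum(m))
}

#' False-negative zero scores
#'
#' Subjects with calcium by the reference but an automated category of zero:
#' the zero-category column summed over nonzero reference rows.
#'
#' @param m square confusion matrix; the zero category must be present.
#' @param zero label of the zero category.
#' @return list(count, rate).
#' @export
false_negative_zero <- function(m, zero = "0") {
  check_matrix(m)
  z <- match(zero, colnames(m))
  if (is.na(z)) stop("zero category '", zero, "' not found")
  count <- sum(m[-z, z])
  list(count = count, rate = count / sum(m))
}

#' Weighted kappa
#'
#' Chance-corrected agreement with disagreement weights
#' `v_ij = |i - j| / (k - 1)` (linear, default) or its square (quadratic):
#' `kappa_w = 1 - sum(v * o) / sum(v * e)` with observed proportions `o` and
#' chance expectation `e` from the marginal products. Linear weights are the
#' convention for ordinal Agatston risk strata.
#'
#' @param m square confusion matrix.
#' @param weighting "linear" or "quadratic".
#' @return kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(m, weighting = c("linear", "quadratic")) {
  check_matrix(m)
  weighting <- match.arg(weighting)
  n <- sum(m)
  k <- nrow(m)
  o <- m / n
  pr <- rowSums(o); pc <- colSums(o)
  if (sum(pr > 0 & pc > 0) < 1L)
    stop("degenerate matrix: no category used by both raters")
  v <- abs(row(m) - col(m)) / (k - 1)
  if (weighting == "quadratic") v <- v^2
  e <- outer(pr, pc)
  denom <- sum(v * e)
  if (denom == 0) stop("degenerate matrix: chance disagreement is zero")
  1 - sum(v * o) / denom
}

#' Intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way ANOVA mean squares of an n x k
#' subjects-by-raters table. `"two-way-mixed"` returns the consistency form
#' ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE); `"two-way-random"` the
#' absolute-agreement form
#' ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#'
#' @param x numeric matrix (n subjects x k raters) without missing cells, or
#'   a vector paired with `y`.
#' @param y optional second rater vector (two-rater shortcut).
#' @param model "two-way-mixed" (consistency, default) or "two-way-random"
#'   (absolute agreement).
#' @return ICC point estimate.
#' @export
icc <- function(x, y = NULL, model = c("two-way-mixed", "two-way-random")) {
  model <- match.arg(model)
  if (!is.null(y)) x <- cbind(x, y)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(x)) stop("missing cells are not supported")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2) /
    ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0)
    stop("zero total variance: ICC undefined")
  if (model == "two-way-mixed") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

#' Kendall's coefficient of concordance
#'
#' Tie-corrected Kendall's W for an n-subjects x m-raters table of ordinal
#' ratings. Each rater's column is converted to mid-ranks;
#' `W = 12 S / (m^2 (n^3 - n) - m sum(T_j))` with S the sum of squared
#' deviations of the subject rank sums and `T_j = sum(t^3 - t)` over tie
#' groups of rater j.
#'
#' @param x numeric matrix (n x m), n >= 2 subjects, m >= 2 raters.
#' @return W in `[0, 1]`.
#' @export
kendalls_w <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 2L || m < 2L) stop("need >= 2 subjects and >= 2 raters")
  ranks <- apply(x, 2, rank)          # mid-rank ties
  s <- sum((rowSums(ranks) - m * (n + 1) / 2)^2)
  tie <- sum(apply(x, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie
  if (denom <= 0) stop("all ratings constant: W undefined")
  12 * s / denom
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with quartiles by linear interpolation between
#' order statistics. Supply either a sample `x` (>= 4 values) or the
#' quartiles directly via `q`.
#'
#' @param x numeric sample.
#' @param q optional numeric(2) quartiles (Q1, Q3), overriding `x`.
#' @return QCD; 0 for a constant sample, 1 in the `Q1 = -Q3 < 0 < Q3` limit.
#' @export
qcd <- function(x = NULL, q = NULL) {
  if (is.null(q)) {
    if (length(x) < 4L) stop("need at least 4 values (or supply `q`)")
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  }
  q1 <- q[1]; q3 <- q[2]
  if (q3 + q1 == 0) return(if (q3 > 0) 1 else 0)
  (q3 - q1) / (q3 + q1)
}

#' Median and interquartile range of paired differences
#'
#' Differences are reference minus automated; quartiles use linear
#' interpolation.
#'
#' @param ref,auto paired numeric vectors.
#' @return named numeric: `median, p25, p75`.
#' @export
paired_difference_summary <- function(ref, auto) {
  if (length(ref) != length(auto) || length(ref) < 1L)
    stop("need equally long, nonempty paired vectors")
  d <- ref - auto
  c(median = median(d),
    p25 = unname(quantile(d, 0.25, type = 7)),
    p75 = unname(quantile(d, 0.75, type = 7)))
}

#' Full agreement-and-reliability report
#'
#' Assembles the categorical block (confusion matrix, proportion of
#' agreement, shift histogram, weighted kappa, false-negative zeros) and,
#' for each supplied continuous measure, the reliability block (ICC, median
#' paired difference with IQR, QCD of both score sets, Bland-Altman model)
#' into one serialisable report.
#'
#' @param ref_cat,auto_cat paired category vectors (or NULL if `matrix` is
#'   given).
#' @param matrix a precomputed confusion matrix (alternative to the paired
#'   vectors).
#' @param continuous named list of `list(ref =, auto =)` paired numeric
#'   vectors, e.g. `list(agatston = list(ref = r, auto = a))`.
#' @param icc_model ICC model passed to [icc()].
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(ref_cat = NULL, auto_cat = NULL, matrix = NULL,
                             continuous = list(),
                             icc_model = "two-way-mixed") {
  if (is.null(matrix)) {
    if (is.null(ref_cat) || is.null(auto_cat))
      stop("supply either paired categories or a confusion matrix")
    matrix <- confusion_matrix(ref_cat, auto_cat)
  }
  check_matrix(matrix)
  sh <- shift_counts(matrix)
  rep_ <- list(
    categorical = list(
      matrix = matrix,
      proportion_agreement = proportion_agreement(matrix),
      shift_histogram = sh$histogram,
      n_shift_gt1 = sh$n_gt1,
      weighted_kappa = weighted_kappa(matrix),
      false_negative_zero = false_negative_zero(matrix)),
    continuous = lapply(continuous, function(p) {
      list(icc = icc(p$ref, p$auto, model = icc_model),
           difference = paired_difference_summary(p$ref, p$auto),
           qcd_ref = qcd(p$ref), qcd_auto = qcd(p$auto),
           bland_altman = tryCatch(unclass(bland_altman_fit(p$ref, p$auto))[
             c("a", "b", "m")], error = function(e) NULL))
    }))
  structure(rep_, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report\n")
  cat(sprintf("  n = %d, proportion of agreement %.3f, weighted kappa %.3f\n",
              sum(x$categorical$matrix), x$categorical$proportion_agreement,
              x$categorical$weighted_kappa))
  cat(sprintf("  shifts > 1 stratum: %d; false-negative zeros: %d (%.1f%%)\n",
              x$categorical$n_shift_gt1,
              x$categorical$false_negative_zero$count,
              100 * x$categorical$false_negative_zero$rate))
  for (nm in names(x$continuous)) {
    cc <- x$continuous[[nm]]
    cat(sprintf("  %s: ICC %.3f, median diff %.2f (P25-P75 %.2f-%.2f)\n",
                nm, cc$icc, cc$difference["median"], cc$difference["p25"],
                cc$difference["p75"]))
  }
  invisible(x)
}
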