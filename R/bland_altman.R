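#' Bland-Altman analysis with regression-modelled non-uniform limits
#'
#' Calcium-score measurement error grows with the score itself, so uniform
#' 95% limits of agreement are inappropriate. Instead the absolute paired
#' difference `|ref - auto|` is regressed (OLS) on the square root of the
#' pair mean, and the 95% repeatability limits at mean `x` are
#' `+/- (a + b * sqrt(x)) * 1.96 * sqrt(pi / 2)`: for a zero-centred normal
#' difference the absolute difference is half-normal with mean
#' `sd * sqrt(2 / pi)`, so multiplying the predicted absolute difference by
#' `1.96 * sqrt(pi / 2) ~= 2.4567` recovers the +/- 1.96 sd band. Limits are
#' zero-centred; where the fitted absolute difference would be negative it
#' is clipped to 0.
#'
#' @param ref,auto paired numeric score vectors (>= 3 pairs with
#'   non-constant means).
#' @return object of class `bland_altman` with intercept `a`, slope `b`,
#'   multiplier `m`, and the underlying `lm` fit.
#' @export
bland_altman_fit <- function(ref, auto) {
  if (length(ref) != length(auto) || length(ref) < 3L)
    stop("need at least 3 pairs")
  mu <- (ref + auto) / 2
  if (any(mu < 0)) stop("pair means must be non-negative (sqrt transform)")
  if (diff(range(mu)) == 0)
    stop("constant pair means: slope undefined")
  ad <- abs(ref - auto)
  rx <- sqrt(mu)
  fit <- lm(ad ~ rx)
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 m = half_normal_multiplier(), fit = fit,
                 n = length(ref)),
            class = "bland_altman")
}

#' The half-normal 95% multiplier
#'
#' `1.96 * sqrt(pi / 2) ~= 2.4567`: converts a predicted mean absolute
#' difference into the +/- 1.96 sd limit, since `E|X| = sd * sqrt(2 / pi)`
#' for a zero-mean normal X.
#'
#' @return the constant.
#' @export
half_normal_multiplier <- function() 1.96 * sqrt(pi / 2)

#' @export
coef.bland_altman <- function(object, ...) {
  c(a = object$a, b = object$b, m = object$m)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman non-uniform limits (n = %d):\n  |d| ~ %.3f + %.3f * sqrt(mean);  95%% limits = +/- (a + b sqrt(x)) * %.4f\n",
    x$n, x$a, x$b, x$m))
  invisible(x)
}

#' Evaluate the 95% limits of a fitted Bland-Altman model
#'
#' @param object a `bland_altman` model.
#' @param newdata numeric vector of pair means `x` at which to evaluate.
#' @param ... unused.
#' @return data.frame with `mean`, `lower`, `upper`; the predicted absolute
#'   difference is clipped at 0 before scaling.
#' @export
predict.bland_altman <- function(object, newdata, ...) {
  pred <- pmax(object$a + object$b * sqrt(newdata), 0)
  data.frame(mean = newdata, lower = -pred * object$m, upper = pred * object$m)
}

#' Fraction of paired differences inside the fitted limits
#'
#' @param object a `bland_altman` model.
#' @param ref,auto the paired scores to check (typically the fitting data).
#' @return proportion of pairs with `|ref - auto|` within the limits.
#' @export
ba_coverage <- function(object, ref, auto) {
  lim <- predict(object, (ref + auto) / 2)
  mean(abs(ref - auto) <= lim$upper)
}
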