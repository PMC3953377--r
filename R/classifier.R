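#' Train the two-stage kNN / SVM candidate classifier
#'
#' Candidates are classified coronary vs non-coronary by a two-stage
#' supervised system: a k-nearest-neighbour stage produces a posterior
#' (fraction of coronary neighbours); candidates whose posterior falls
#' outside the uncertainty band `(band[1], band[2])` take the kNN decision,
#' while candidates inside the band are routed to an RBF support vector
#' machine trained on the same data. Both degenerate single-stage modes are
#' reachable: `band = c(0.5, 0.5)` is pure kNN, `band = c(0, 1)` pure SVM.
#' Features are z-scored with training statistics stored in the model, so
#' training and application use identical scaling.
#'
#' @param features numeric matrix (n x p), as returned by [featurize()].
#' @param labels logical (TRUE = coronary) or character/factor with level
#'   "coronary"; both classes must be present.
#' @param k number of neighbours for the kNN stage (default 15; capped at
#'   n - 1).
#' @param band numeric(2) posterior band (lo, hi), 0 <= lo <= hi <= 1.
#' @param cost,gamma RBF-SVM hyperparameters (gamma defaults to 1/p).
#' @param seed integer seed recorded in the model and used for the SVM fit.
#' @return object of class `cac_classifier`.
#' @export
train_classifier <- function(features, labels, k = 15, band = c(0.3, 0.7),
                             cost = 1, gamma = NULL, seed = 1L) {
  features <- as.matrix(features)
  y <- if (is.logical(labels)) labels else as.character(labels) == "coronary"
  if (length(y) != nrow(features))
    stop("`labels` length must match feature rows")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  if (band[1] < 0 || band[2] > 1 || band[1] > band[2])
    stop("`band` must satisfy 0 <= lo <= hi <= 1")
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- scale(features, center = mu, scale = sdv)
  k <- max(1L, min(as.integer(k), nrow(xs) - 1L))
  yf <- factor(ifelse(y, "coronary", "non-coronary"),
               levels = c("non-coronary", "coronary"))
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  svm_fit <- with_seed(seed,
    e1071::svm(xs, yf, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE))
  structure(list(k = k, band = band, mu = mu, sd = sdv,
                 x = unclass(xs)[, , drop = FALSE], y = yf, svm = svm_fit,
                 cost = cost, gamma = gamma,
                 feature_names = colnames(features), seed = as.integer(seed)),
            class = "cac_classifier")
}

#' @export
print.cac_classifier <- function(x, ...) {
  cat(sprintf(
    "cac_classifier: kNN (k = %d) + RBF SVM, band (%.2f, %.2f), %d training candidates (%d coronary)\n",
    x$k, x$band[1], x$band[2], nrow(x$x), sum(x$y == "coronary")))
  invisible(x)
}

#' Classify candidate feature vectors
#'
#' Deterministic given the model: the kNN posterior (fraction of coronary
#' neighbours among the k nearest, distance ties included) is computed first;
#' outside the posterior band the kNN majority decides, inside it the SVM
#' decides.
#'
#' @param model a `cac_classifier`.
#' @param features numeric matrix with the model's feature columns.
#' @return data.frame with `label` ("coronary"/"non-coronary"),
#'   `knn_posterior`, and `stage` ("knn"/"svm") per row.
#' @export
classify <- function(model, features) {
  features <- as.matrix(features)
  if (nrow(features) == 0L)
    return(data.frame(label = character(), knn_posterior = numeric(),
                      stage = character()))
  if (ncol(features) != length(model$mu))
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(features), length(model$mu)))
  xs <- scale(features, center = model$mu, scale = model$sd)
  pred <- class::knn(model$x, xs, model$y, k = model$k, prob = TRUE,
                     use.all = TRUE)
  pwin <- attr(pred, "prob")
  post <- ifelse(pred == "coronary", pwin, 1 - pwin)
  in_band <- post >= model$band[1] & post <= model$band[2]
  label <- ifelse(post > 0.5, "coronary", "non-coronary")
  stage <- rep("knn", length(post))
  if (any(in_band)) {
    sv <- predict(model$svm, xs[in_band, , drop = FALSE])
    label[in_band] <- as.character(sv)
    stage[in_band] <- "svm"
  }
  data.frame(label = label, knn_posterior = post, stage = stage,
             stringsAsFactors = FALSE)
}

#' @export
predict.cac_classifier <- function(object, newdata, ...) {
  classify(object, newdata)
}

#' Persist / restore a classifier
#'
#' The archive is JSON holding the training configuration, the
#' standardisation statistics and the standardised training data; on load
#' the SVM stage is refitted deterministically from the stored data and
#' seed, so the restored model makes identical decisions.
#'
#' @param model a `cac_classifier`.
#' @param path file path (.json).
#' @return `load_classifier` returns the restored `cac_classifier`.
#' @export
save_classifier <- function(model, path) {
  obj <- list(k = model$k, band = model$band, mu = model$mu, sd = model$sd,
              x = model$x, y = as.character(model$y), cost = model$cost,
              gamma = model$gamma, feature_names = model$feature_names,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- matrix(unlist(obj$x), nrow = length(obj$y))
  colnames(x) <- obj$feature_names
  # undo the stored standardisation so train_classifier reproduces it
  raw <- sweep(sweep(x, 2, obj$sd, "*"), 2, obj$mu, "+")
  train_classifier(raw, obj$y == "coronary", k = obj$k, band = obj$band,
                   cost = obj$cost, gamma = obj$gamma, seed = obj$seed)
}
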