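## Pluggable multiclass classifier used identically by every protocol.
## Default backend: soft-margin-style RBF-kernel regularized
## least-squares with one-vs-one voting (a deterministic kernel
## classifier standing in for a library SVM, which is not available in
## the supported dependency set). Alternates: linear kernel, nearest
## centroid. All backends standardize on training statistics and are
## fully deterministic given config and inputs.

#' Classifier configuration
#'
#' @param backend `"rbf"` (default; radial-basis-kernel regularized
#'   least squares with one-vs-one voting), `"linear"` (linear-kernel
#'   variant) or `"centroid"` (nearest class centroid, a fast reference
#'   backend for sensitivity analyses).
#' @param cost regularization constant C > 0 (ridge penalty is `1/cost`);
#'   default 1.
#' @param gamma RBF kernel width; default `NULL` applies the
#'   variance-scaled rule `1 / (n_features * mean feature variance)`
#'   computed on the (standardized) training set.
#' @param standardize z-score each feature by training mean/sd
#'   (default TRUE; band powers span orders of magnitude across bands
#'   and kernel classifiers are scale-sensitive).
#' @param transform `"log10"` (default) maps strictly positive band
#'   powers to the log scale before standardizing — the standard
#'   variance stabilizer for spectral power features; `"none"` uses the
#'   raw features (required for inputs that can be non-positive).
#' @param seed unused by the built-in deterministic backends; kept so
#'   stochastic backends can be injected without changing call sites.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(backend = c("rbf", "linear", "centroid"),
                              cost = 1, gamma = NULL, standardize = TRUE,
                              transform = c("log10", "none"),
                              seed = NULL) {
  backend <- match.arg(backend)
  transform <- match.arg(transform)
  if (!is.finite(cost) || cost <= 0) stop("cost must be positive")
  structure(list(backend = backend, cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize), transform = transform,
                 seed = seed),
            class = "classifier_config")
}

#' Train on one feature table and predict another
#'
#' Fits the configured backend on `train` and returns predictions and
#' accuracy on `test`. Standardization statistics are computed on
#' training rows only and applied to both sets. Deterministic given
#' the config and inputs.
#'
#' @param train,test [feature_table()]s sharing the same feature
#'   columns (test columns are aligned by name).
#' @param cfg a [classifier_config()].
#' @return list with `predicted` (character vector), `accuracy`
#'   (fraction of test rows predicted correctly), `classes`, and `cfg`.
#' @export
fit_predict <- function(train, test, cfg = classifier_config()) {
  fc <- feature_cols(train)
  if (!setequal(fc, feature_cols(test)))
    stop("train and test feature columns differ")
  res <- fit_predict_xy(feature_matrix(train), train$class,
                        as.matrix(test[fc]), cfg)
  res$accuracy <- mean(res$predicted == test$class)
  res
}

## Matrix-level core (no data.frame overhead) used by the RFE inner loop.
## cols: optional integer/character subset of columns to use.
fit_predict_xy <- function(X, y, Xte, cfg, cols = NULL) {
  if (!is.null(cols)) {
    X <- X[, cols, drop = FALSE]
    Xte <- Xte[, cols, drop = FALSE]
  }
  classes <- unique(y)
  if (length(classes) < 2L) stop("training set must contain >= 2 classes")
  if (identical(cfg$transform, "log10")) {
    if (any(X <= 0) || any(Xte <= 0))
      stop("non-positive feature values; use transform = \"none\"")
    X <- log10(X)
    Xte <- log10(Xte)
  }
  if (cfg$standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    X <- scale(X, center = mu, scale = sdv)
    Xte <- scale(Xte, center = mu, scale = sdv)
  }
  pred <- switch(cfg$backend,
    rbf = ovo_kernel_predict(X, y, Xte, cfg, kernel = "rbf"),
    linear = ovo_kernel_predict(X, y, Xte, cfg, kernel = "linear"),
    centroid = centroid_predict(X, y, Xte)
  )
  list(predicted = pred, classes = classes, cfg = cfg)
}

sq_dist <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

## One-vs-one regularized least-squares in the kernel: for each class
## pair solve (K + I/C) alpha = y(+-1), vote by the sign of the test
## score; voting ties broken toward the earlier class in training order.
ovo_kernel_predict <- function(X, y, Xte, cfg, kernel) {
  classes <- unique(y)
  k <- length(classes)
  votes <- matrix(0L, nrow(Xte), k)
  lambda <- 1 / cfg$cost
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    idx <- y %in% classes[c(a, b)]
    Xa <- X[idx, , drop = FALSE]
    ya <- ifelse(y[idx] == classes[a], 1, -1)
    if (kernel == "rbf") {
      g <- cfg$gamma %||% {
        v <- mean(apply(Xa, 2, stats::var))
        if (!is.finite(v) || v <= 0) v <- 1
        1 / (ncol(Xa) * v)
      }
      K <- exp(-g * sq_dist(Xa, Xa))
      Kte <- exp(-g * sq_dist(Xte, Xa))
    } else {
      K <- tcrossprod(Xa)
      Kte <- tcrossprod(Xte, Xa)
    }
    alpha <- solve(K + diag(lambda, nrow(K)), ya)
    score <- drop(Kte %*% alpha)
    if (any(!is.finite(score))) stop("non-finite classifier scores")
    win <- ifelse(score > 0, a, b)
    votes[cbind(seq_len(nrow(Xte)), win)] <- votes[cbind(seq_len(nrow(Xte)), win)] + 1L
  }
  classes[max.col(votes, ties.method = "first")]
}

centroid_predict <- function(X, y, Xte) {
  classes <- unique(y)
  cen <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  d <- sq_dist(Xte, cen)
  classes[max.col(-d, ties.method = "first")]
}
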