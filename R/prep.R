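#' Stratified train/test split
#'
#' Per-class test counts are set by largest-remainder allocation of
#' `n_c * test_fraction` (targeting `round(n * test_fraction)` total), so
#' the test share is within one clip per class of the requested fraction.
#' Assignment within a class is randomized by `seed`.
#'
#' @param y class labels.
#' @param test_fraction held-out proportion (default 0.2).
#' @param seed integer seed.
#' @return List of class `bleat_split` with integer index vectors `train`
#'   and `test` (disjoint, covering all rows).
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  y <- as.character(y)
  tab <- table(y)
  if (any(tab < 2L))
    stop("singleton class cannot be split: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  n <- length(y)
  target_total <- round(n * test_fraction)
  quota <- as.numeric(tab) * test_fraction
  base <- floor(quota)
  rem <- target_total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(min(rem, length(base)))]] <-
      base[ord[seq_len(min(rem, length(base)))]] + 1L
  }
  # keep at least one row per class on each side
  base <- pmin(pmax(base, 1L), as.numeric(tab) - 1L)
  test_idx <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(tab)) {
      rows <- which(y == names(tab)[ci])
      test_idx <- c(test_idx, sample(rows, base[ci]))
    }
  })
  test_idx <- sort(test_idx)
  structure(list(train = setdiff(seq_len(n), test_idx), test = test_idx),
            class = "bleat_split")
}

#' SMOTE class balancing
#'
#' Synthetic Minority Over-sampling: every minority class is grown to the
#' majority count by interpolation `x_new = x_i + u (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` and `x_nn` a random one of the `k` nearest same-class
#' neighbors (Euclidean). Must be applied to the training partition only;
#' the API takes training rows and nothing else. `k` falls back to
#' `n_c - 1` for classes smaller than `k + 1`.
#'
#' @param X_train training feature matrix.
#' @param y_train training labels.
#' @param k neighbor count (default 5).
#' @param seed integer seed.
#' @return List with balanced `X`, `y`, and logical `synthetic` flags.
#' @export
smote_balance <- function(X_train, y_train, k = 5L, seed = 1L) {
  X_train <- as.matrix(X_train)
  y_train <- as.character(y_train)
  stopifnot(nrow(X_train) == length(y_train))
  tab <- table(y_train)
  if (any(tab < 2L))
    stop("SMOTE cannot interpolate a class of size 1: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  n_max <- max(tab)
  Xs <- list(); ys <- character(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      rows <- which(y_train == cl)
      need <- n_max - length(rows)
      if (need == 0L) next
      Xc <- X_train[rows, , drop = FALSE]
      kk <- min(k, length(rows) - 1L)
      nn <- FNN::get.knn(Xc, k = kk)$nn.index
      base <- sample(length(rows), need, replace = TRUE)
      pick <- nn[cbind(base, sample(kk, need, replace = TRUE))]
      u <- stats::runif(need)
      Xnew <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      Xs[[cl]] <- Xnew
      ys <- c(ys, rep(cl, need))
    }
  })
  if (length(Xs)) {
    Xadd <- do.call(rbind, Xs)
    list(X = rbind(X_train, Xadd), y = c(y_train, ys),
         synthetic = c(rep(FALSE, nrow(X_train)), rep(TRUE, nrow(Xadd))))
  } else {
    list(X = X_train, y = y_train, synthetic = rep(FALSE, nrow(X_train)))
  }
}

#' Z-score standardization fitted on training data
#'
#' `z = (x - mu) / sigma` with `mu` and `sigma` (population standard
#' deviation) estimated from the training partition only. Zero-variance
#' features use `sigma = 1`, mapping them to exactly 0.
#'
#' @param X_train training feature matrix.
#' @return An object of class `bleat_scaler` with `mu` and `sigma`.
#' @export
fit_scaler <- function(X_train) {
  X_train <- as.matrix(X_train)
  mu <- colMeans(X_train)
  sigma <- sqrt(colMeans(sweep(X_train, 2L, mu)^2))
  zero <- sigma <= 0
  sigma[zero] <- 1
  structure(list(mu = mu, sigma = sigma, feature_names = colnames(X_train)),
            class = "bleat_scaler")
}

#' @rdname fit_scaler
#' @param params a fitted `bleat_scaler`.
#' @param X matrix to transform.
#' @return Standardized matrix (same shape as `X`).
#' @export
apply_scaler <- function(params, X) {
  if (!inherits(params, "bleat_scaler")) stop("scaler has not been fitted")
  X <- as.matrix(X)
  if (!is.null(params$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), params$feature_names))
    stop("feature columns do not match the fitted scaler")
  sweep(sweep(X, 2L, params$mu), 2L, params$sigma, `/`)
}

#' Importance-threshold feature selection
#'
#' Fits a gradient-boosted tree ensemble on the training partition and
#' retains every feature whose importance (accumulated split gain) meets
#' the threshold rule — by default the mean importance, the standard
#' select-from-model convention. Tree ensembles are scale-free, so `X` may
#' be raw or standardized.
#'
#' @param X_train training feature matrix.
#' @param y_train training labels (>= 2 classes).
#' @param threshold `"mean"` or a numeric cutoff.
#' @param seed integer seed.
#' @param n_rounds,max_depth boosting budget for the importance model.
#' @return Integer indices of retained features, in schema order, with the
#'   importance vector as attribute `importance`.
#' @export
select_features <- function(X_train, y_train, threshold = "mean",
                            seed = 1L, n_rounds = 60L, max_depth = 3L) {
  X_train <- as.matrix(X_train)
  y_train <- as.character(y_train)
  if (length(unique(y_train)) < 2L) stop("need at least two classes")
  fit <- with_seed(seed,
    gbt_fit(X_train, y_train, n_rounds = n_rounds, max_depth = max_depth))
  imp <- fit$importance
  if (all(imp <= 0)) stop("all feature importances are zero")
  cut <- if (identical(threshold, "mean")) mean(imp) else as.numeric(threshold)
  keep <- which(imp >= cut)
  if (!length(keep)) stop("selection threshold exceeds every importance")
  attr(keep, "importance") <- imp
  keep
}
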