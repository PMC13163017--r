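#' Classifier specification
#'
#' Names one of the screened model families plus its hyperparameters and a
#' seed. MLP defaults are the tuned edge configuration: hidden layers
#' (256, 128), tanh activation, softmax output, Adam at learning rate
#' 0.001, batch 32, L2 penalty 0.001, early-stopping patience 10, at most
#' 500 epochs.
#'
#' @param family one of `"gradient_boosted_trees"`, `"random_forest"`,
#'   `"extra_trees"`, `"k_nearest_neighbors"`, `"logistic"`, `"lda"`,
#'   `"qda"`, `"ridge"`, `"linear_svm"`, `"naive_bayes"`,
#'   `"decision_tree"`, `"adaboost"`, `"dummy_majority"`, `"mlp"`.
#' @param hyper named list of family-specific hyperparameter overrides.
#' @param seed integer seed controlling all training randomness.
#' @return An object of class `bleat_model_spec`.
#' @export
model_spec <- function(family, hyper = list(), seed = 1L) {
  families <- c("gradient_boosted_trees", "random_forest", "extra_trees",
                "k_nearest_neighbors", "logistic", "lda", "qda", "ridge",
                "linear_svm", "naive_bayes", "decision_tree", "adaboost",
                "dummy_majority", "mlp")
  family <- match.arg(family, families)
  defaults <- switch(family,
    mlp = list(hidden = c(256L, 128L), activation = "tanh",
               learning_rate = 0.001, batch_size = 32L, alpha = 0.001,
               patience = 10L, max_epochs = 500L, val_fraction = 0.1),
    gradient_boosted_trees = list(n_rounds = 100L, learning_rate = 0.1,
                                  max_depth = 3L, min_leaf = 5L),
    random_forest = list(n_trees = 100L, max_depth = 30L, min_leaf = 1L),
    extra_trees = list(n_trees = 100L, max_depth = 30L, min_leaf = 1L),
    k_nearest_neighbors = list(k = 5L),
    adaboost = list(n_rounds = 50L, max_depth = 1L),
    decision_tree = list(max_depth = 30L, min_leaf = 1L),
    linear_svm = list(epochs = 60L, C = 1),
    list())
  hyper <- utils::modifyList(defaults, hyper)
  structure(list(family = family, hyper = hyper, seed = as.integer(seed)),
            class = "bleat_model_spec")
}

#' Train a classifier
#'
#' Fits the family named by the spec. Label order is alphabetical, matching
#' the confusion-matrix index convention used in reporting. Training is
#' deterministic given the spec seed. Scale-sensitive families (MLP, KNN,
#' linear models) expect standardized inputs — standardization is the
#' pipeline's responsibility, see [fit_scaler()].
#'
#' @param spec a [model_spec()].
#' @param X_train numeric feature matrix with column names (the feature
#'   contract).
#' @param y_train class labels (>= 2 distinct values).
#' @return An object of class `bleat_model`.
#' @export
train_model <- function(spec, X_train, y_train) {
  stopifnot(inherits(spec, "bleat_model_spec"))
  X <- as.matrix(X_train)
  if (anyNA(X) || !all(is.finite(X))) stop("X contains NaN/Inf values")
  y <- as.character(y_train)
  stopifnot(nrow(X) == length(y))
  labels <- sort(unique(y))
  if (length(labels) < 2L && spec$family != "dummy_majority")
    stop("need at least two classes to train")
  y_int <- match(y, labels) - 1L
  K <- length(labels)
  h <- spec$hyper

  fit <- with_seed(spec$seed, switch(spec$family,
    dummy_majority = {
      tab <- table(y)
      list(majority = names(tab)[which.max(tab)])
    },
    mlp = mlp_fit(X, y_int, K, hidden = h$hidden,
                  activation = h$activation,
                  learning_rate = h$learning_rate,
                  batch_size = h$batch_size, alpha = h$alpha,
                  patience = h$patience, max_epochs = h$max_epochs,
                  val_fraction = h$val_fraction),
    gradient_boosted_trees = gbt_fit(X, y, n_rounds = h$n_rounds,
                                     learning_rate = h$learning_rate,
                                     max_depth = h$max_depth,
                                     min_leaf = h$min_leaf),
    random_forest = forest_fit(X, y_int, K, n_trees = h$n_trees,
                               max_depth = h$max_depth,
                               min_leaf = h$min_leaf),
    extra_trees = forest_fit(X, y_int, K, n_trees = h$n_trees,
                             max_depth = h$max_depth,
                             min_leaf = h$min_leaf, extra = TRUE),
    decision_tree = fit_cart(X, y_int, K, max_depth = h$max_depth,
                             min_leaf = h$min_leaf),
    adaboost = ada_fit(X, y_int, K, n_rounds = h$n_rounds,
                       max_depth = h$max_depth),
    k_nearest_neighbors = list(X = X, y_int = y_int, k = h$k),
    logistic = glmnet_fit(X, y, lambda = 1 / nrow(X)),
    ridge = glmnet_fit(X, y, lambda = 1 / nrow(X), alpha0 = TRUE),
    lda = MASS::lda(X, grouping = factor(y, levels = labels)),
    qda = MASS::qda(X, grouping = factor(y, levels = labels)),
    naive_bayes = nb_fit(X, y_int, K),
    linear_svm = svm_fit(X, y_int, K, epochs = h$epochs, C = h$C)))

  structure(list(spec = spec, fit = fit, labels = labels,
                 feature_names = colnames(X)), class = "bleat_model")
}

glmnet_fit <- function(X, y, lambda, alpha0 = FALSE) {
  f <- glmnet::glmnet(X, factor(y), family = "multinomial",
                      alpha = if (alpha0) 0 else 1,
                      lambda = c(lambda * 100, lambda * 10, lambda),
                      standardize = FALSE)
  list(glmnet = f, s = lambda)
}

nb_fit <- function(X, y_int, K) {
  mu <- matrix(0, K, ncol(X)); va <- matrix(0, K, ncol(X))
  prior <- numeric(K)
  for (k in seq_len(K)) {
    rows <- which(y_int == k - 1L)
    mu[k, ] <- colMeans(X[rows, , drop = FALSE])
    va[k, ] <- apply(X[rows, , drop = FALSE], 2L, function(v) mean((v - mean(v))^2))
    prior[k] <- length(rows) / nrow(X)
  }
  va <- va + 1e-9 * max(va)
  list(mu = mu, va = va, prior = prior, K = K)
}

nb_prob <- function(fit, X) {
  n <- nrow(X)
  ll <- matrix(0, n, fit$K)
  for (k in seq_len(fit$K)) {
    ll[, k] <- log(fit$prior[k]) - 0.5 * colSums(
      t(sweep(X, 2L, fit$mu[k, ])^2) / fit$va[k, ] + log(2 * pi * fit$va[k, ]))
  }
  softmax_rows(ll)
}

# one-vs-rest linear SVM via Pegasos-style subgradient descent
svm_fit <- function(X, y_int, K, epochs = 60L, C = 1) {
  n <- nrow(X); p <- ncol(X)
  lam <- 1 / (n * C)
  Wm <- matrix(0, p, K); b <- numeric(K)
  t_step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      t_step <- t_step + 1
      eta <- 1 / (lam * t_step)
      xi <- X[i, ]
      yk <- ifelse(seq_len(K) == y_int[i] + 1L, 1, -1)
      marg <- yk * (drop(xi %*% Wm) + b)
      viol <- marg < 1
      Wm <- (1 - eta * lam) * Wm
      if (any(viol)) {
        Wm[, viol] <- Wm[, viol] + eta / n * outer(xi, yk[viol])
        b[viol] <- b[viol] + eta / n * yk[viol]
      }
    }
  }
  list(W = Wm, b = b, K = K)
}

#' Predict classes or class probabilities
#'
#' Probabilities are finite, non-negative, and row-normalized; the class is
#' the probability argmax with ties broken by label order. The feature-name
#' contract of the training matrix is enforced.
#'
#' @param object a `bleat_model`.
#' @param X feature matrix matching the training columns.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return Character vector of labels, or a clips x classes probability
#'   matrix.
#' @export
predict.bleat_model <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(X)) || !identical(colnames(X), object$feature_names))
      stop("feature contract mismatch: expected columns [",
           paste(head(object$feature_names, 3L), collapse = ", "),
           ", ...] (n=", length(object$feature_names), ")")
  }
  K <- length(object$labels)
  fit <- object$fit
  P <- switch(object$spec$family,
    dummy_majority = {
      m <- matrix(0, nrow(X), K)
      m[, match(fit$majority, object$labels)] <- 1
      m
    },
    mlp = mlp_prob(fit, X),
    gradient_boosted_trees = gbt_prob(fit, X),
    random_forest = forest_prob(fit, X),
    extra_trees = forest_prob(fit, X),
    decision_tree = .predict_tree_cpp(fit, X),
    adaboost = ada_prob(fit, X),
    k_nearest_neighbors = {
      nn <- FNN::get.knnx(fit$X, X, k = fit$k)$nn.index
      m <- matrix(0, nrow(X), K)
      for (j in seq_len(fit$k)) {
        lab <- fit$y_int[nn[, j]] + 1L
        m[cbind(seq_len(nrow(X)), lab)] <- m[cbind(seq_len(nrow(X)), lab)] + 1
      }
      m / fit$k
    },
    logistic = glmnet_prob(fit, X),
    ridge = glmnet_prob(fit, X),
    lda = predict(fit, X)$posterior,
    qda = predict(fit, X)$posterior,
    naive_bayes = nb_prob(fit, X),
    linear_svm = softmax_rows(sweep(X %*% fit$W, 2L, fit$b, `+`)))
  P <- as.matrix(P)
  colnames(P) <- object$labels
  if (type == "prob") return(P)
  object$labels[max.col(P, ties.method = "first")]
}

glmnet_prob <- function(fit, X) {
  pr <- predict(fit$glmnet, X, s = fit$s, type = "response")
  pr[, , 1L]
}

#' Exhaustive MLP grid search with k-fold cross-validation
#'
#' Evaluates every candidate hyperparameter combination by stratified
#' k-fold cross-validated accuracy and returns the winning [model_spec()].
#' Ties go to the smaller network (fewer hidden units), then the lower
#' learning rate.
#'
#' @param X_train,y_train training data (standardized).
#' @param grids list of hyperparameter lists (each a valid `hyper` for
#'   `model_spec("mlp")`); see [default_mlp_grid()] for the canonical
#'   search space.
#' @param folds fold count (default 3); must not exceed the smallest class
#'   size.
#' @param seed integer seed.
#' @return The best `bleat_model_spec`, with the CV table as attribute
#'   `cv`.
#' @export
grid_search_mlp <- function(X_train, y_train, grids, folds = 3L, seed = 1L) {
  y <- as.character(y_train)
  if (folds > min(table(y)))
    stop("fold count exceeds the smallest class size")
  fold_id <- stratified_folds(y, folds, seed)
  acc <- numeric(length(grids))
  for (g in seq_along(grids)) {
    sp <- model_spec("mlp", hyper = grids[[g]], seed = derive_seed(seed, g))
    scores <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      m <- train_model(sp, X_train[tr, , drop = FALSE], y[tr])
      scores[f] <- mean(predict(m, X_train[te, , drop = FALSE]) == y[te])
    }
    acc[g] <- mean(scores)
  }
  size <- vapply(grids, function(h)
    sum(if (is.null(h$hidden)) c(256L, 128L) else h$hidden), 0)
  lr <- vapply(grids, function(h)
    if (is.null(h$learning_rate)) 0.001 else h$learning_rate, 0)
  ord <- order(-acc, size, lr)
  best <- model_spec("mlp", hyper = grids[[ord[1L]]], seed = seed)
  attr(best, "cv") <- data.frame(candidate = seq_along(grids),
                                 cv_accuracy = acc, n_units = size,
                                 learning_rate = lr)
  best
}

#' The canonical MLP hyperparameter search space
#'
#' Topologies (100), (100, 50), (254, 58), (256, 128), (100, 100, 100);
#' activations relu/tanh; learning rates 0.0005/0.001/0.01; batch sizes
#' 32/64/128; L2 penalties 0.0001/0.001/0.01/0.05. 360 combinations.
#'
#' @return List of hyperparameter lists for [grid_search_mlp()].
#' @export
default_mlp_grid <- function() {
  tops <- list(100L, c(100L, 50L), c(254L, 58L), c(256L, 128L),
               c(100L, 100L, 100L))
  out <- list()
  for (hd in tops) for (av in c("relu", "tanh"))
    for (lr in c(5e-4, 1e-3, 1e-2)) for (bs in c(32L, 64L, 128L))
      for (al in c(1e-4, 1e-3, 1e-2, 5e-2))
        out[[length(out) + 1L]] <- list(hidden = hd, activation = av,
                                        learning_rate = lr,
                                        batch_size = bs, alpha = al)
  out
}

stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      rows <- sample(which(y == cl))
      fold_id[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  fold_id
}

#' Generic stochastic hyperparameter search
#'
#' Pluggable stand-in for Bayesian tuners: samples `n_trials` candidates
#' from a discrete search space, scores each (and the starting spec) by
#' stratified k-fold CV accuracy, and returns the best. Never returns a
#' spec with a worse CV mean than the starting spec, which is always
#' evaluated as trial 0.
#'
#' @param spec starting [model_spec()].
#' @param X_train,y_train training data.
#' @param space named list mapping hyperparameter names to candidate value
#'   lists.
#' @param n_trials number of sampled candidates.
#' @param folds CV fold count.
#' @param seed integer seed.
#' @return The best `bleat_model_spec` with attribute `cv_accuracy`.
#' @export
tune_spec <- function(spec, X_train, y_train, space, n_trials = 10L,
                      folds = 3L, seed = 1L) {
  y <- as.character(y_train)
  fold_id <- stratified_folds(y, folds, seed)
  cv_score <- function(sp) {
    scores <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      m <- train_model(sp, X_train[tr, , drop = FALSE], y[tr])
      scores[f] <- mean(predict(m, X_train[te, , drop = FALSE]) == y[te])
    }
    mean(scores)
  }
  best <- spec; best_acc <- cv_score(spec)
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      h <- spec$hyper
      for (nm in names(space))
        h[[nm]] <- space[[nm]][[sample.int(length(space[[nm]]), 1L)]]
      cand <- model_spec(spec$family, hyper = h,
                         seed = derive_seed(seed, trial))
      acc <- cv_score(cand)
      if (acc > best_acc) { best <- cand; best_acc <- acc }
    }
  })
  attr(best, "cv_accuracy") <- best_acc
  best
}
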