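# Tree-ensemble learners built on the flat CART engine in src/tree.cpp.
# These are internal; user-facing training goes through model_spec()/
# train_model(). Class labels are integer-coded 0..K-1 in alphabetical order
# throughout.

fit_cart <- function(X, y_int, K, weights = NULL, rows = NULL,
                     max_depth = 30L, min_split = 2L, min_leaf = 1L,
                     mtry = ncol(X), extra = FALSE, regression = FALSE) {
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(rows)) rows <- seq_len(n)
  if (regression) {
    .grow_tree_cpp(X, integer(n), as.numeric(y_int), weights, FALSE, 1L,
                   as.integer(rows - 1L), max_depth, min_split, min_leaf,
                   mtry, extra)
  } else {
    .grow_tree_cpp(X, as.integer(y_int), numeric(n), weights, TRUE,
                   as.integer(K), as.integer(rows - 1L), max_depth,
                   min_split, min_leaf, mtry, extra)
  }
}

# ---- random forest / extra trees -------------------------------------------

forest_fit <- function(X, y_int, K, n_trees = 100L, mtry = NULL,
                       max_depth = 30L, min_leaf = 1L, extra = FALSE) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- vector("list", n_trees)
  imp <- numeric(ncol(X))
  for (b in seq_len(n_trees)) {
    rows <- if (extra) seq_len(n) else sample.int(n, n, replace = TRUE)
    trees[[b]] <- fit_cart(X, y_int, K, rows = rows, max_depth = max_depth,
                           min_leaf = min_leaf, mtry = mtry, extra = extra)
    imp <- imp + trees[[b]]$gain
  }
  list(trees = trees, K = K, importance = imp / n_trees)
}

forest_prob <- function(fit, X) {
  acc <- matrix(0, nrow(X), fit$K)
  for (tr in fit$trees) acc <- acc + .predict_tree_cpp(tr, X)
  acc / length(fit$trees)
}

# ---- multiclass gradient boosting (softmax loss) ---------------------------
# One shallow regression tree per class per round, fitted to the softmax
# residual; leaf values use the standard (K-1)/K Newton step.

gbt_fit <- function(X, y, n_rounds = 100L, learning_rate = 0.1,
                    max_depth = 3L, min_leaf = 5L) {
  X <- as.matrix(X)
  labels <- sort(unique(as.character(y)))
  K <- length(labels)
  y_int <- match(as.character(y), labels) - 1L
  n <- nrow(X)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y_int + 1L)] <- 1
  Fm <- matrix(0, n, K)
  trees <- vector("list", n_rounds)
  imp <- numeric(ncol(X))
  for (m in seq_len(n_rounds)) {
    P <- softmax_rows(Fm)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      r <- Y[, k] - P[, k]
      tr <- fit_cart(X, r, 1L, max_depth = max_depth, min_leaf = min_leaf,
                     regression = TRUE)
      leaf_id <- .tree_leaf_ids_cpp(tr, X) + 1L
      h <- abs(r) * (1 - abs(r))
      num <- tapply(r, leaf_id, sum)
      den <- tapply(h, leaf_id, sum)
      gamma <- numeric(nrow(tr$leaf))
      gamma[as.integer(names(num))] <-
        (K - 1) / K * num / pmax(den, 1e-10)
      tr$leaf <- matrix(gamma, ncol = 1L)
      Fm[, k] <- Fm[, k] + learning_rate * gamma[leaf_id]
      imp <- imp + tr$gain
      round_trees[[k]] <- tr
    }
    trees[[m]] <- round_trees
  }
  structure(list(trees = trees, labels = labels, K = K,
                 learning_rate = learning_rate, importance = imp),
            class = "bleat_gbt")
}

gbt_scores <- function(fit, X) {
  X <- as.matrix(X)
  Fm <- matrix(0, nrow(X), fit$K)
  for (round_trees in fit$trees)
    for (k in seq_len(fit$K))
      Fm[, k] <- Fm[, k] + fit$learning_rate *
        .predict_tree_cpp(round_trees[[k]], X)[, 1L]
  Fm
}

gbt_prob <- function(fit, X) softmax_rows(gbt_scores(fit, X))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- AdaBoost (SAMME) on depth-limited trees -------------------------------

ada_fit <- function(X, y_int, K, n_rounds = 50L, max_depth = 1L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  imp <- numeric(ncol(X))
  for (m in seq_len(n_rounds)) {
    tr <- fit_cart(X, y_int, K, weights = w, max_depth = max_depth,
                   min_leaf = 1L)
    pred <- max.col(.predict_tree_cpp(tr, X), ties.method = "first") - 1L
    err <- sum(w * (pred != y_int)) / sum(w)
    if (err >= 1 - 1 / K) break                       # worse than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y_int))
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    imp <- imp + alpha * tr$gain
    if (err <= 1e-10) break
  }
  list(trees = trees, alphas = alphas, K = K, importance = imp)
}

ada_prob <- function(fit, X) {
  votes <- matrix(0, nrow(X), fit$K)
  for (m in seq_along(fit$trees)) {
    pred <- max.col(.predict_tree_cpp(fit$trees[[m]], X),
                    ties.method = "first")
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + fit$alphas[m]
  }
  s <- rowSums(votes)
  votes / ifelse(s > 0, s, 1)
}
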