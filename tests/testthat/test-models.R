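# shared fixture: separable Gaussian blobs
blob_data <- function(n = 200, K = 4, p = 10, sd = 1, seed = 42) {
  set.seed(seed)
  y <- rep(letters[1:K], length.out = n)
  mu <- matrix(rnorm(K * p, sd = 3), K)
  X <- mu[match(y, letters[1:K]), ] + matrix(rnorm(n * p, sd = sd), n)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

test_that("dummy majority predicts the modal class everywhere", {
  d <- blob_data(n = 10, K = 2)
  y <- c(rep("A", 7), rep("B", 3))
  m <- train_model(model_spec("dummy_majority"), d$X, y)
  expect_equal(unique(predict(m, d$X)), "A")
})

test_that("the MLP separates Gaussian blobs and is deterministic", {
  d <- blob_data(n = 200, K = 4)
  sp <- stratified_split(d$y, 0.25, seed = 1L)
  spec <- model_spec("mlp", hyper = list(max_epochs = 150L), seed = 7L)
  m <- train_model(spec, d$X[sp$train, ], d$y[sp$train])
  acc <- mean(predict(m, d$X[sp$test, ]) == d$y[sp$test])
  expect_gte(acc, 0.95)

  m2 <- train_model(spec, d$X[sp$train, ], d$y[sp$train])
  expect_identical(predict(m, d$X[sp$test, ]),
                   predict(m2, d$X[sp$test, ]))
})

test_that("probability contracts hold across families", {
  d <- blob_data(n = 120, K = 3, p = 6)
  probe <- blob_data(n = 40, K = 3, p = 6, seed = 9)$X
  for (fam in c("mlp", "gradient_boosted_trees", "random_forest",
                "extra_trees", "k_nearest_neighbors", "logistic", "lda",
                "naive_bayes", "linear_svm", "decision_tree")) {
    sp <- model_spec(fam, seed = 3L,
                     hyper = if (fam == "mlp")
                       list(hidden = c(32L, 16L), max_epochs = 60L)
                     else list())
    m <- train_model(sp, d$X, d$y)
    P <- predict(m, probe, type = "prob")
    expect_equal(dim(P), c(40L, 3L), label = fam)
    expect_true(all(is.finite(P)) && all(P >= 0), label = fam)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-6, label = fam)
    cls <- predict(m, probe)
    expect_equal(cls, m$labels[max.col(P, ties.method = "first")],
                 label = fam)
    expect_length(cls, 40L)
  }
})

test_that("training rejects invalid inputs and contract mismatches", {
  d <- blob_data(n = 40, K = 2, p = 4)
  Xb <- d$X; Xb[1, 1] <- NA
  expect_error(train_model(model_spec("mlp"), Xb, d$y), "NaN")
  expect_error(train_model(model_spec("mlp"), d$X, rep("a", 40)),
               "two classes")
  m <- train_model(model_spec("decision_tree"), d$X, d$y)
  Xwrong <- d$X[, c(2, 1, 3, 4)]
  expect_error(predict(m, Xwrong), "contract")
})

test_that("trained models beat the majority baseline across seeds", {
  wins <- vapply(1:5, function(s) {
    d <- blob_data(n = 160, K = 4, p = 8, seed = 200 + s)
    sp <- stratified_split(d$y, 0.25, seed = s)
    m <- train_model(model_spec("gradient_boosted_trees", seed = s),
                     d$X[sp$train, ], d$y[sp$train])
    dm <- train_model(model_spec("dummy_majority", seed = s),
                      d$X[sp$train, ], d$y[sp$train])
    te <- sp$test
    mean(predict(m, d$X[te, ]) == d$y[te]) >
      mean(predict(dm, d$X[te, ]) == d$y[te])
  }, logical(1))
  expect_true(all(wins))
})

test_that("MLP grid search ranks candidates and breaks ties canonically", {
  d <- blob_data(n = 120, K = 3, p = 6)
  one <- list(list(hidden = 16L, max_epochs = 40L))
  best <- grid_search_mlp(d$X, d$y, one, folds = 3L, seed = 2L)
  expect_equal(best$hyper$hidden, 16L)

  # a candidate trained on shuffled labels must lose
  d2 <- blob_data(n = 90, K = 3, p = 6, seed = 5)
  yshuf <- sample(d2$y)
  grids <- list(list(hidden = 16L, max_epochs = 40L),
                list(hidden = 16L, max_epochs = 40L))
  a1 <- grid_search_mlp(d2$X, d2$y, grids[1], folds = 3L, seed = 4L)
  a2 <- grid_search_mlp(d2$X, yshuf, grids[1], folds = 3L, seed = 4L)
  expect_gt(attr(a1, "cv")$cv_accuracy, attr(a2, "cv")$cv_accuracy)

  b1 <- grid_search_mlp(d$X, d$y, grids, folds = 3L, seed = 6L)
  b2 <- grid_search_mlp(d$X, d$y, grids, folds = 3L, seed = 6L)
  expect_identical(attr(b1, "cv"), attr(b2, "cv"))

  expect_error(grid_search_mlp(d$X, d$y, one, folds = 100L), "fold count")
  expect_equal(length(default_mlp_grid()), 360L)
})

test_that("stochastic tuning never falls below the starting spec", {
  d <- blob_data(n = 120, K = 3, p = 6, seed = 31)
  start <- model_spec("gradient_boosted_trees",
                      hyper = list(n_rounds = 30L), seed = 1L)
  space <- list(n_rounds = list(10L, 30L, 60L), max_depth = list(2L, 3L))
  fold_id_seed <- 5L
  tuned <- tune_spec(start, d$X, d$y, space, n_trials = 3L, folds = 3L,
                     seed = fold_id_seed)
  # recompute the start spec's CV accuracy on the same folds
  base <- tune_spec(start, d$X, d$y, space, n_trials = 0L, folds = 3L,
                    seed = fold_id_seed)
  expect_gte(attr(tuned, "cv_accuracy"), attr(base, "cv_accuracy"))
})
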