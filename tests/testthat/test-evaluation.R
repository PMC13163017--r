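test_that("confusion matrix counts and normalization", {
  y <- c("a", "a", "b", "b", "c")
  cm <- confusion(y, y)
  expect_true(all(cm$counts[upper.tri(cm$counts)] == 0))
  expect_equal(unname(diag(cm$counts)), c(2L, 2L, 1L))

  one <- confusion("a", "b", labels = c("a", "b"))
  expect_equal(unname(one$counts["a", "b"]), 1L)
  expect_equal(sum(one$counts), 1L)

  set.seed(8)
  yr <- sample(c("x", "y", "z"), 60, replace = TRUE)
  pr <- sample(c("x", "y", "z"), 60, replace = TRUE)
  nm <- confusion_normalized(confusion(yr, pr))
  expect_equal(unname(rowSums(nm)), rep(1, 3))
  expect_error(confusion(yr, rep("q", 60), labels = c("x", "y", "z")),
               "labels")
})

test_that("metrics match hand-evaluated and degenerate cases", {
  # 2-class counts [[40,10],[20,30]]: Ac 0.70, Pr(e) 0.50, K 0.40
  y <- c(rep("p", 50), rep("q", 50))
  pred <- c(rep("p", 40), rep("q", 10), rep("p", 20), rep("q", 30))
  mx <- eval_metrics(confusion(y, pred))
  expect_equal(mx$accuracy, 0.70)
  expect_equal(mx$kappa, 0.40)

  # perfect 8-class prediction
  yp <- rep(letters[1:8], each = 5)
  mp <- eval_metrics(confusion(yp, yp))
  expect_equal(c(mp$accuracy, mp$precision, mp$recall, mp$f1, mp$kappa),
               rep(1, 5))

  # constant predictor on balanced truth: kappa 0
  yb <- rep(c("u", "v"), 30)
  mc <- suppressMessages(
    eval_metrics(confusion(yb, rep("u", 60), labels = c("u", "v"))))
  expect_equal(mc$kappa, 0)

  expect_error(eval_metrics(confusion(character(0), character(0),
                                      labels = "a")), "empty")
})

test_that("metrics agree with the per-clip brute-force reference", {
  set.seed(14)
  for (rep_i in 1:20) {
    K <- sample(2:6, 1)
    n <- sample(20:200, 1)
    labs <- letters[1:K]
    y <- sample(labs, n, replace = TRUE)
    while (length(unique(y)) < K) y <- sample(labs, n, replace = TRUE)
    pred <- sample(labs, n, replace = TRUE)
    got <- suppressMessages(eval_metrics(confusion(y, pred, labels = labs)))
    ref <- naive_metrics(y, pred)
    for (nm in names(ref))
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-12, label = nm)
    # algebraic identity: support weighting makes weighted recall = accuracy
    expect_equal(got$recall, got$accuracy, tolerance = 1e-12)
    # kappa bounded by accuracy whenever chance agreement is in (0, 1)
    pe <- sum(rowSums(got_counts <- confusion(y, pred, labels = labs)$counts) *
                colSums(got_counts)) / n^2
    if (pe > 0 && pe < 1) expect_lte(got$kappa, got$accuracy + 1e-12)
  }
})

test_that("permutation importance isolates the decisive feature", {
  set.seed(6)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 3] <- 0                                    # constant column
  y <- ifelse(X[, 1] > 0, "hi", "lo")
  m <- train_model(model_spec("decision_tree", seed = 2L), X, y)

  ranks_ok <- vapply(1:5, function(s) {
    pi <- permutation_importance(m, X, y, n_repeats = 3L, seed = s)
    pi$feature[1] == "f1"
  }, logical(1))
  expect_true(all(ranks_ok))

  pi <- permutation_importance(m, X, y, n_repeats = 3L, seed = 1L)
  expect_equal(pi$importance[pi$feature == "f3"], 0)
  expect_identical(pi, permutation_importance(m, X, y, n_repeats = 3L,
                                              seed = 1L))
  pc <- permutation_importance(m, X, y, n_repeats = 2L, seed = 1L,
                               per_class = TRUE)
  expect_true(all(c("recall_drop_hi", "recall_drop_lo") %in% names(pc)))
  expect_error(permutation_importance(m, X, y, n_repeats = 0L),
               "n_repeats")
})
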