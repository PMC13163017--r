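test_that("stratified split allocates test rows by largest remainder", {
  y <- rep(c("a", "b", "c"), times = c(60, 20, 20))
  sp <- stratified_split(y, 0.2, seed = 3L)
  expect_equal(length(sp$test), 20L)
  expect_equal(as.vector(table(y[sp$test])), c(12L, 4L, 4L))
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0L)

  # 20% within one clip per class on awkward counts
  y2 <- rep(letters[1:4], times = c(23, 11, 7, 5))
  sp2 <- stratified_split(y2, 0.2, seed = 1L)
  for (cl in letters[1:4]) {
    n_cl <- sum(y2 == cl)
    expect_lte(abs(sum(y2[sp2$test] == cl) - 0.2 * n_cl), 1)
  }

  expect_identical(stratified_split(y, 0.2, seed = 9L),
                   stratified_split(y, 0.2, seed = 9L))
  expect_error(stratified_split(c("a", "a", "b"), 0.2), "singleton")
  expect_error(stratified_split(y, 1.2), "test_fraction")
})

test_that("SMOTE balances to the majority count with convex rows", {
  set.seed(11)
  X <- matrix(rnorm(28), 14, 2)
  colnames(X) <- c("u", "v")
  y <- c(rep("A", 10), rep("B", 4))
  bal <- smote_balance(X, y, seed = 2L)
  expect_equal(as.vector(table(bal$y)), c(10L, 10L))

  # every synthetic row lies on a segment between two same-class originals
  syn <- which(bal$synthetic)
  orig_B <- X[y == "B", ]
  for (i in syn) {
    z <- bal$X[i, ]
    on_seg <- FALSE
    for (a in 1:4) for (b in 1:4) {
      if (a == b) next
      d <- orig_B[b, ] - orig_B[a, ]
      tpar <- sum((z - orig_B[a, ]) * d) / sum(d * d)
      if (tpar >= -1e-9 && tpar <= 1 + 1e-9 &&
          sqrt(sum((orig_B[a, ] + tpar * d - z)^2)) < 1e-9)
        on_seg <- TRUE
    }
    expect_true(on_seg)
  }

  balanced <- smote_balance(X[1:8, ], rep(c("A", "B"), 4), seed = 1L)
  expect_equal(nrow(balanced$X), 8L)
  expect_false(any(balanced$synthetic))

  expect_error(smote_balance(X, c(rep("A", 13), "B")), "size 1")
})

test_that("z-score standardization follows the population formula", {
  Xc <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f"))
  sc <- fit_scaler(Xc)
  z <- apply_scaler(sc, Xc)
  expect_equal(unname(z[, 1]), c(-1.224744871, 0, 1.224744871),
               tolerance = 1e-8)

  const <- matrix(7, 5, 1, dimnames = list(NULL, "c"))
  expect_equal(unname(apply_scaler(fit_scaler(const), const)[, 1]),
               rep(0, 5))

  set.seed(3)
  Xr <- matrix(rnorm(200, 5, 3), 50, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  Z <- apply_scaler(fit_scaler(Xr), Xr)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(Z^2)) - 1)), 1e-9)

  expect_error(apply_scaler(list(), Xr), "not been fitted")
})

test_that("importance selection recovers planted informative features", {
  # each informative feature is the (noisy) indicator of one class, so
  # every class's trees must consult its own feature
  planted_ok <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 200
    y <- rep(c("a", "b", "c"), length.out = n)
    ind <- sapply(c("a", "b", "c"), function(cl) 2 * (y == cl))
    X <- cbind(ind + matrix(rnorm(n * 3), n), matrix(rnorm(n * 20), n))
    colnames(X) <- paste0("f", 1:23)
    sel <- select_features(X, y, seed = s)
    all(1:3 %in% sel)
  }, logical(1))
  expect_true(all(planted_ok))

  set.seed(101)
  y <- rep(c("a", "b"), 50)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 2] <- ifelse(y == "a", 1, -1) + rnorm(100, sd = 0.1)
  sel <- select_features(X, y, seed = 1L)
  expect_true(all(diff(sel) > 0))            # order-preserving subset
  expect_true(all(sel %in% 1:4))
  expect_error(select_features(X, y, threshold = 1e12), "threshold")
  expect_error(select_features(X, rep("a", 100)), "two classes")
})
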