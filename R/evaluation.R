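#' Confusion matrix
#'
#' `counts[i, j]` is the number of clips with true label `i` predicted as
#' `j`. Row sums equal per-class support.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param labels label order; defaults to the sorted union of `y_true`.
#' @return An object of class `bleat_confusion` with `counts` and `labels`.
#' @export
confusion <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(labels)) labels <- sort(unique(y_true))
  if (!all(y_true %in% labels) || !all(y_pred %in% labels))
    stop("labels outside the declared label set")
  f <- function(v) factor(v, levels = labels)
  counts <- unclass(table(true = f(y_true), predicted = f(y_pred)))
  structure(list(counts = counts, labels = labels),
            class = "bleat_confusion")
}

#' Row-normalized view of a confusion matrix
#' @param cm a `bleat_confusion`.
#' @return Row-stochastic matrix (rows with support 0 stay 0).
#' @export
confusion_normalized <- function(cm) {
  stopifnot(inherits(cm, "bleat_confusion"))
  rs <- rowSums(cm$counts)
  sweep(cm$counts, 1L, ifelse(rs > 0, rs, 1), `/`)
}

#' @export
print.bleat_confusion <- function(x, ...) {
  print(x$counts); invisible(x)
}

#' Weighted multiclass metrics
#'
#' From the confusion matrix: overall accuracy (trace / total); per-class
#' one-vs-rest precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' their harmonic-mean F1; support-weighted averages of the three; and
#' Cohen's kappa `(Pr(a) - Pr(e)) / (1 - Pr(e))` with observed agreement
#' `Pr(a)` equal to accuracy and chance agreement
#' `Pr(e) = sum_c rowsum_c * colsum_c / total^2`. Per-class 0/0 cases
#' (never-predicted classes) are reported as 0 with a logged warning, the
#' prevailing toolkit convention.
#'
#' @param cm a [confusion()] matrix.
#' @return An object of class `bleat_metrics`: `accuracy`, `precision`,
#'   `recall`, `f1`, `kappa` (weighted scalars) plus `per_class` data
#'   frame.
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "bleat_confusion"))
  M <- cm$counts
  total <- sum(M)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(M)
  support <- rowSums(M)
  predicted <- colSums(M)
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      log_line("eval_metrics", c(warning = paste0("zero_", what),
                                 classes = paste(cm$labels[bad],
                                                 collapse = ",")))
    ifelse(bad, 0, num / den)
  }
  prec <- safe_div(tp, predicted, "predicted_support")
  rec <- safe_div(tp, support, "support")
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- support / total
  acc <- sum(tp) / total
  pe <- sum(support * predicted) / total^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  structure(list(
    accuracy = acc,
    precision = sum(wts * prec), recall = sum(wts * rec),
    f1 = sum(wts * f1), kappa = kappa,
    per_class = data.frame(label = cm$labels, precision = prec,
                           recall = rec, f1 = f1, support = support,
                           row.names = NULL)), class = "bleat_metrics")
}

#' @export
print.bleat_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | weighted P %.4f R %.4f F1 %.4f | kappa %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$kappa))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic attribution: the importance of feature `j` is the mean
#' decrease in accuracy over `n_repeats` random shufflings of column `j`
#' of the evaluation matrix. With `per_class = TRUE`, per-class recall
#' decreases are reported as class-conditional importance. Deterministic
#' given the seed; tree families additionally expose their internal gain
#' importance via the fitted object.
#'
#' @param m a trained `bleat_model`.
#' @param X_test,y_test labeled evaluation rows.
#' @param n_repeats shuffles per feature (>= 1).
#' @param seed integer seed.
#' @param per_class also compute per-class recall decreases.
#' @return Data frame sorted by descending importance (`feature`,
#'   `importance`, and optionally one `recall_drop_<class>` column per
#'   class).
#' @export
permutation_importance <- function(m, X_test, y_test, n_repeats = 5L,
                                   seed = 1L, per_class = FALSE) {
  stopifnot(inherits(m, "bleat_model"))
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  X <- as.matrix(X_test)
  y <- as.character(y_test)
  base_pred <- predict(m, X)
  base_acc <- mean(base_pred == y)
  labels <- m$labels
  base_rec <- vapply(labels, function(cl)
    if (any(y == cl)) mean(base_pred[y == cl] == cl) else 0, 0)
  p <- ncol(X)
  imp <- numeric(p)
  rec_drop <- matrix(0, p, length(labels),
                     dimnames = list(NULL, labels))
  with_seed(seed, {
    for (j in seq_len(p)) {
      for (r in seq_len(n_repeats)) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        pred <- predict(m, Xp)
        imp[j] <- imp[j] + (base_acc - mean(pred == y))
        if (per_class) {
          rec <- vapply(labels, function(cl)
            if (any(y == cl)) mean(pred[y == cl] == cl) else 0, 0)
          rec_drop[j, ] <- rec_drop[j, ] + (base_rec - rec)
        }
      }
    }
  })
  out <- data.frame(feature = colnames(X), importance = imp / n_repeats,
                    stringsAsFactors = FALSE)
  if (per_class) {
    rd <- rec_drop / n_repeats
    colnames(rd) <- paste0("recall_drop_", labels)
    out <- cbind(out, rd)
  }
  out[order(-out$importance), , drop = FALSE]
}
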