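# Confusion counts, the five performance measures, and the two baselines.

#' Confusion counts from labels
#'
#' @param truth,pred integer 0/1 vectors of equal length.
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  assert_that(length(truth) == length(pred), "length mismatch")
  list(TP = sum(truth == 1L & pred == 1L),
       FP = sum(truth == 0L & pred == 1L),
       TN = sum(truth == 0L & pred == 0L),
       FN = sum(truth == 1L & pred == 0L))
}

#' Performance measures from confusion counts
#'
#' Accuracy (TP+TN)/total, recall of the positive class (sensitivity, TPR),
#' precision of the positive class (PPV), recall of the negative class
#' (specificity, TNR) and precision of the negative class (NPV). Ratios
#' with a zero denominator are reported as NA, not 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (total > 0).
#' @return an object of class `ki_metrics`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    assert_that(total > 0, "no predictions to score")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    structure(list(accuracy = (TP + TN) / total,
                   recall_pos = ratio(TP, TP + FN),
                   precision_pos = ratio(TP, TP + FP),
                   recall_neg = ratio(TN, TN + FP),
                   precision_neg = ratio(TN, TN + FN),
                   counts = list(TP = TP, FP = FP, TN = TN, FN = FN)),
              class = "ki_metrics")
  })
}

#' @export
print.ki_metrics <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "  NA " else sprintf("%5.1f", 100 * v)
  cat(sprintf("accuracy %s%%  TPR %s%%  PPV %s%%  TNR %s%%  NPV %s%%\n",
              pc(x$accuracy), pc(x$recall_pos), pc(x$precision_pos),
              pc(x$recall_neg), pc(x$precision_neg)))
  invisible(x)
}

#' Majority-class baseline
#'
#' Predicts the more frequent training class everywhere; an exact tie
#' predicts the negative class.
#'
#' @param train_labels integer 0/1 training labels (non-empty).
#' @return an object of class `majority_baseline` with a `predict` method.
#' @export
majority_baseline <- function(train_labels) {
  assert_that(length(train_labels) > 0, "empty training labels")
  lab <- if (sum(train_labels == 1L) > sum(train_labels == 0L)) 1L else 0L
  structure(list(label = lab, rate = mean(train_labels == lab)),
            class = "majority_baseline")
}

#' @param object a `majority_baseline`.
#' @param n number of predictions.
#' @param ... unused.
#' @rdname majority_baseline
#' @export
predict.majority_baseline <- function(object, n, ...) rep(object$label, n)

#' Probability-product baseline for one split
#'
#' Estimates, on the training pairs only, the probability that the test
#' kinase binds (over its training pairs) and that the test inhibitor binds
#' (over its training pairs), multiplies them, and predicts binding iff the
#' product strictly exceeds the threshold. Undefined for hard-case splits,
#' where the test molecules have no training pairs.
#'
#' @param matrix binding matrix.
#' @param split one element of `ki_splits$splits`.
#' @param theta threshold in \[0, 1\].
#' @return list with `pred` (0/1), `p_kin`, `p_inh`, `product`.
#' @export
probability_product_baseline <- function(matrix, split, theta) {
  n <- ncol(matrix)
  tij <- pair_ij(split$test, n)
  ij <- pair_ij(split$train, n)
  kin_rows <- ij[ij[, 1] == tij[1, 1], , drop = FALSE]
  inh_rows <- ij[ij[, 2] == tij[1, 2], , drop = FALSE]
  if (nrow(kin_rows) == 0L || nrow(inh_rows) == 0L)
    stop("probability-product baseline is only possible in non-hard cases",
         call. = FALSE)
  p_kin <- mean(matrix[kin_rows])
  p_inh <- mean(matrix[inh_rows])
  prod <- p_kin * p_inh
  list(pred = as.integer(prod > theta), p_kin = p_kin, p_inh = p_inh,
       product = prod)
}

#' Empirically optimize the probability-product threshold
#'
#' Evaluates every grid value over all splits and returns the threshold
#' maximizing mean accuracy; ties resolve to the smallest threshold.
#'
#' @param matrix binding matrix.
#' @param splits a non-hard `ki_splits`.
#' @param grid candidate thresholds (default 0 to 1 by 0.01).
#' @return the selected threshold.
#' @export
optimize_theta <- function(matrix, splits, grid = seq(0, 1, by = 0.01)) {
  assert_that(length(grid) > 0, "empty threshold grid")
  grid <- sort(grid)
  products <- truth <- numeric(length(splits$splits))
  n <- splits$n
  for (k in seq_along(splits$splits)) {
    s <- splits$splits[[k]]
    products[k] <- probability_product_baseline(matrix, s, 0)$product
    truth[k] <- matrix[pair_ij(s$test, n)]
  }
  acc <- vapply(grid, function(th) mean((products > th) == truth), 0)
  grid[which.max(acc)]
}

#' Replace numeric feature groups by range-bounded random integers
#'
#' The ablation control: every numeric column in the named groups is
#' replaced by i.i.d. uniform random integers between the observed column
#' minimum and maximum; other columns are untouched. Nominal columns in a
#' named group are an error (the ablation is defined for numeric scores).
#'
#' @param ft a `feature_table`.
#' @param groups group tags to randomize.
#' @param seed RNG seed.
#' @return a `feature_table`.
#' @export
randomize_features <- function(ft, groups, seed = 1L) {
  bad <- setdiff(groups, ft$groups)
  assert_that(length(bad) == 0L,
              sprintf("group(s) absent from table: %s",
                      paste(bad, collapse = ",")))
  set.seed(seed)
  for (cn in names(ft$values)[ft$groups %in% groups]) {
    assert_that(ft$types[[cn]] == "numeric",
                sprintf("cannot randomize nominal column '%s'", cn))
    lo <- floor(min(ft$values[[cn]])); hi <- ceiling(max(ft$values[[cn]]))
    pool <- seq(lo, hi)
    ft$values[[cn]] <- as.numeric(
      pool[sample.int(length(pool), nrow(ft$values), replace = TRUE)])
  }
  ft
}
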