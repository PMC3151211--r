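# Preprocessing (nominal-to-binary, min-max normalization) and thin
# wrappers over a CART decision tree (rpart) and an SVM (e1071/libsvm).

#' Classifier specification
#'
#' @param kind `"tree"` (CART via rpart; an open stand-in for C4.5/C5-style
#'   learners, with the minimum leaf support mapped to `minbucket` and
#'   pruning strength to the complexity parameter `cp`) or `"svm"`
#'   (libsvm).
#' @param kernel SVM kernel: `"linear"`, `"quadratic"` (homogeneous
#'   polynomial of degree 2) or `"rbf"`.
#' @param C SVM cost factor (default 1.0).
#' @param min_leaf minimum training instances per tree leaf (default 2).
#' @param cp rpart complexity parameter controlling pruning (default 0.01);
#'   0 disables pruning (the "no global pruning" end of the scale).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("tree", "svm"),
                            kernel = c("linear", "quadratic", "rbf"),
                            C = 1.0, min_leaf = 2L, cp = 0.01) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  assert_that(C > 0, "cost factor C must be positive")
  assert_that(min_leaf >= 1, "min_leaf must be >= 1")
  structure(list(kind = kind, kernel = kernel, C = C,
                 min_leaf = as.integer(min_leaf), cp = cp),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  if (x$kind == "svm")
    cat(sprintf("classifier_spec: svm (%s kernel, C = %g)\n", x$kernel, x$C))
  else
    cat(sprintf("classifier_spec: tree (min_leaf = %d, cp = %g)\n",
                x$min_leaf, x$cp))
  invisible(x)
}

#' Nominal-to-binary encoding of a feature table
#'
#' A 2-category nominal column becomes one 0/1 column (1 for the second
#' category in the declared order); a k>2-category column becomes k
#' indicator columns; numeric columns pass through. Categories outside the
#' declared set (unseen at transform time) yield all-zero indicators with a
#' warning.
#'
#' @param ft a `feature_table`.
#' @return an all-numeric `feature_table` (group tags inherited).
#' @export
encode_nominal <- function(ft) {
  vals <- list(); types <- character(0); groups <- character(0)
  for (cn in names(ft$values)) {
    if (ft$types[[cn]] == "numeric") {
      vals[[cn]] <- ft$values[[cn]]
      types[cn] <- "numeric"; groups[cn] <- ft$groups[[cn]]
      next
    }
    lv <- ft$levels[[cn]]
    x <- ft$values[[cn]]
    unseen <- !(x %in% lv)
    if (any(unseen))
      warning(sprintf("column '%s': %d value(s) outside the declared categories encode as all-zero",
                      cn, sum(unseen)))
    if (length(lv) == 2L) {
      nm <- paste0(cn, "=", lv[2])
      vals[[nm]] <- as.integer(x == lv[2])
      types[nm] <- "numeric"; groups[nm] <- ft$groups[[cn]]
    } else {
      for (l in lv) {
        nm <- paste0(cn, "=", l)
        vals[[nm]] <- as.integer(x == l)
        types[nm] <- "numeric"; groups[nm] <- ft$groups[[cn]]
      }
    }
  }
  feature_table(as.data.frame(vals, check.names = FALSE, optional = TRUE),
                ft$ids, types, groups)
}

#' Min-max normalization fitted on training rows
#'
#' Rescales every numeric column to \[0, 1\] using the training minimum and
#' maximum; constant columns map to 0; transformed values outside the
#' training range are clipped.
#'
#' @param train numeric `feature_table` (or data frame) to fit on.
#' @return an object of class `minmax_scaler`; apply with `predict()`.
#' @export
fit_minmax <- function(train) {
  df <- if (inherits(train, "feature_table")) train$values else train
  lo <- vapply(df, min, 0); hi <- vapply(df, max, 0)
  structure(list(lo = lo, hi = hi, cols = names(df)), class = "minmax_scaler")
}

#' @param object a `minmax_scaler`.
#' @param newdata feature table or data frame with the fitted columns.
#' @param ... unused.
#' @rdname fit_minmax
#' @export
predict.minmax_scaler <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "feature_table")) newdata$values else newdata
  assert_that(all(object$cols %in% names(df)), "columns missing at transform")
  out <- df[, object$cols, drop = FALSE]
  for (cn in object$cols) {
    rng <- object$hi[[cn]] - object$lo[[cn]]
    out[[cn]] <- if (rng == 0) rep(0, nrow(out)) else
      pmin(1, pmax(0, (out[[cn]] - object$lo[[cn]]) / rng))
  }
  out
}

#' Fit a classifier on training pairs and predict test pairs
#'
#' Trees consume nominal columns natively (as factors over the declared
#' categories); SVMs require the caller to encode and normalize first (as
#' [run_experiment()] does). Deterministic under a fixed seed. A
#' single-class training set degrades to a constant predictor with a
#' warning. Scores are class-1 probabilities for trees and signed decision
#' values (threshold 0) for SVMs.
#'
#' @param spec a `classifier_spec`.
#' @param train_x,test_x data frames of features (same columns).
#' @param train_y integer 0/1 labels for the training rows.
#' @param seed RNG seed (default 1).
#' @return list with `labels` (0/1 per test row) and `scores`.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x, seed = 1L) {
  assert_that(nrow(train_x) == length(train_y), "labels must match rows")
  if (length(unique(train_y)) < 2L) {
    warning("single-class training set: constant predictor")
    lab <- unique(train_y)
    return(list(labels = rep(lab, nrow(test_x)),
                scores = rep(if (lab == 1L) 1 else -1, nrow(test_x))))
  }
  set.seed(seed)
  if (spec$kind == "tree") {
    df <- train_x; df$.y <- factor(train_y, levels = c(0L, 1L))
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          minbucket = spec$min_leaf,
                          minsplit = max(2L * spec$min_leaf, 2L),
                          cp = spec$cp, xval = 0))
    prob <- stats::predict(fit, newdata = test_x, type = "prob")[, "1"]
    list(labels = as.integer(prob > 0.5), scores = prob, model = fit)
  } else {
    x <- as.matrix(train_x)
    storage.mode(x) <- "double"
    args <- switch(spec$kernel,
      linear = list(kernel = "linear"),
      quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 0),
      rbf = list(kernel = "radial"))
    fit <- do.call(e1071::svm, c(list(
      x = x, y = factor(train_y, levels = c(0L, 1L)),
      cost = spec$C, scale = FALSE), args))
    pred <- stats::predict(fit, as.matrix(test_x), decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # libsvm orients the decision value by the first training label; flip
    # so positive score means class 1
    if (grepl("^0/", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
    list(labels = as.integer(as.character(pred)), scores = dv, model = fit)
  }
}
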