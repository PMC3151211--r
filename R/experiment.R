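# End-to-end evaluation: featurize a bundle, run a classifier through the
# chosen LOOCV variant with strict leakage control, report metrics.

#' Compute kinase features for a bundle
#'
#' Builds the requested feature groups: `STTK`/`PC` (annotations), `PRO`
#' (PROSITE-style pattern hits), `Apri` (mined frequent sequence patterns,
#' border elements above the size threshold), `glAli`/`locAli` (alignment
#' score vectors), `PSF`/`abPSF` (active-site residues / classes).
#'
#' @param b a `ki_bundle`.
#' @param groups kinase group tags to compute.
#' @param prosite named PROSITE pattern vector (required for `PRO`).
#' @param sm `subst_matrix` for the alignment groups (default PAM120).
#' @param realign realign cut-out frames in `locAli` (default FALSE).
#' @param minsup_frac `Apri` support threshold as a corpus fraction
#'   (default 0.5).
#' @param min_size,max_len `Apri` pattern size limits (defaults 3, 10).
#' @param classmap residue class map for `abPSF`.
#' @return a `feature_table` over the matrix kinases (column-bound groups in
#'   the requested order).
#' @export
kinase_feature_table <- function(b, groups, prosite = NULL,
                                 sm = subst_matrix("PAM120"),
                                 realign = FALSE, minsup_frac = 0.5,
                                 min_size = 3L, max_len = 10L,
                                 classmap = default_classmap()) {
  kin_groups <- c("STTK", "PC", "PRO", "Apri", "glAli", "locAli", "PSF", "abPSF")
  bad <- setdiff(groups, kin_groups)
  assert_that(length(bad) == 0L,
              sprintf("unknown kinase group(s): %s", paste(bad, collapse = ",")))
  kin <- b$kinases[match(rownames(b$matrix), b$kinases$id), ]
  phylo <- NULL
  if (any(c("STTK", "PC") %in% groups)) phylo <- phylo_features(kin)
  parts <- list()
  for (g in groups) {
    parts[[g]] <- switch(g,
      STTK = ft_subset(phylo, groups = "STTK"),
      PC = ft_subset(phylo, groups = "PC"),
      PRO = {
        assert_that(!is.null(prosite), "PRO group needs PROSITE patterns")
        prosite_features(prosite, kin)
      },
      Apri = {
        ps <- mine_frequent(kin$sequence,
                            minsup = max(1L, ceiling(minsup_frac * nrow(kin))),
                            min_size = min_size, max_len = max_len)
        apriori_features(border_elements(ps), kin)
      },
      glAli = score_vector_features(kin, "glAli", sm),
      locAli = {
        frames <- extract_frames(b$msa, conserved_columns(b$msa),
                                 b$active_columns)
        score_vector_features(kin, "locAli", sm, m = b$msa, frames = frames,
                              realign = realign)
      },
      PSF = position_specific_features(b$msa, b$active_columns, ids = kin$id),
      abPSF = position_specific_features(b$msa, b$active_columns,
                                         ids = kin$id, abstract = TRUE,
                                         classmap = classmap))
  }
  do.call(ft_bind, unname(parts))
}

#' Compute inhibitor features for a bundle
#'
#' Builds the requested groups: `PT`/`MS` (annotations), `FTs` (maximal
#' frequent free trees), `CF` (physico-chemical descriptors), `GF`
#' (geometry), `P` (3-point pharmacophores), `KNN` (binding-profile
#' similarities; leakage-sensitive, recomputed per split by
#' [run_experiment()] — here computed from the full matrix for exploratory
#' use).
#'
#' @param b a `ki_bundle`.
#' @param groups inhibitor group tags to compute.
#' @param min_freq `FTs` frequency threshold (default 0.10).
#' @param max_atoms largest free-tree pattern grown (default 8).
#' @param k KNN neighbourhood size (default 3).
#' @param knn_metric `"tanimoto"` or `"common_count"`.
#' @param top_f pharmacophore feature count (default 50).
#' @return a `feature_table` over the matrix inhibitors.
#' @export
inhibitor_feature_table <- function(b, groups, min_freq = 0.10,
                                    max_atoms = 8L, k = 3L,
                                    knn_metric = "tanimoto", top_f = 50L) {
  inh_groups <- c("PT", "MS", "FTs", "KNN", "CF", "GF", "P")
  bad <- setdiff(groups, inh_groups)
  assert_that(length(bad) == 0L,
              sprintf("unknown inhibitor group(s): %s",
                      paste(bad, collapse = ",")))
  ids <- colnames(b$matrix)
  mols <- b$molecules[ids]
  ann <- b$inhibitors[match(ids, b$inhibitors$id), ]
  nominal <- NULL
  if (any(c("PT", "MS") %in% groups)) nominal <- inhibitor_nominal_features(ann)
  parts <- list()
  for (g in groups) {
    parts[[g]] <- switch(g,
      PT = ft_subset(nominal, groups = "PT"),
      MS = ft_subset(nominal, groups = "MS"),
      FTs = freetree_features(
        mine_free_trees(mols, min_freq = min_freq, max_atoms = max_atoms),
        mols),
      KNN = knn_feature_table(b$matrix, k = k, metric = knn_metric),
      CF = chemical_feature_table(mols),
      GF = geometric_feature_table(mols),
      P = pharmacophore_features(mols, top_f = top_f))
  }
  do.call(ft_bind, unname(parts))
}

# split a group list into kinase-side and inhibitor-side tags
split_groups <- function(groups) {
  kin <- intersect(groups, c("STTK", "PC", "PRO", "Apri", "glAli", "locAli",
                             "PSF", "abPSF"))
  inh <- intersect(groups, c("PT", "MS", "FTs", "KNN", "CF", "GF", "P"))
  bad <- setdiff(groups, c(kin, inh))
  assert_that(length(bad) == 0L,
              sprintf("unknown group tag(s): %s", paste(bad, collapse = ",")))
  list(kinase = kin, inhibitor = inh)
}

# feature_table -> modelling data frame; nominal columns become factors
# over their declared categories
ft_to_df <- function(ft, as_factors) {
  df <- ft$values
  if (as_factors)
    for (cn in names(df)) if (ft$types[[cn]] == "nominal")
      df[[cn]] <- factor(df[[cn]], levels = ft$levels[[cn]])
  names(df) <- make.names(names(df), unique = TRUE)
  df
}

#' Run a full leave-one-out evaluation experiment
#'
#' Featurizes the bundle, generates the requested LOOCV splits, and for
#' every split trains the classifier on the training pairs only and
#' predicts the held-out pair. Leakage control: the test pair is asserted
#' absent from training ([check_split()]), KNN features are recomputed per
#' split from the binding matrix with the test kinase's row removed (and
#' zeroed with a warning under the hard case, where no binding information
#' about the test molecules exists), and SVM normalization statistics are
#' fitted on training rows only. Mixed cases run `spec$repeats` seeded
#' repetitions and average the resulting metrics; training metrics pool the
#' re-predicted training pairs of every split.
#'
#' @param b a `ki_bundle`.
#' @param groups feature group tags (kinase and inhibitor side together).
#' @param clf a `classifier_spec`.
#' @param spec a `split_spec`.
#' @param kin_args,inh_args extra arguments for [kinase_feature_table()] /
#'   [inhibitor_feature_table()].
#' @param seed seed for classifier fitting (default `spec$seed`).
#' @param train_metrics also re-predict the training pairs of every split
#'   (default TRUE; disable to halve the runtime of large runs).
#' @return an object of class `ki_eval` with test/train metrics (averaged
#'   over repeats), the majority rate, and per-repeat details.
#' @export
run_experiment <- function(b, groups, clf, spec,
                           kin_args = list(), inh_args = list(),
                           seed = NULL, train_metrics = TRUE) {
  seed <- seed %||% spec$seed
  gs <- split_groups(groups)
  assert_that(length(gs$kinase) > 0 || length(gs$inhibitor) > 0,
              "empty feature group list")
  m <- nrow(b$matrix); n <- ncol(b$matrix)
  kin_ft <- if (length(gs$kinase))
    do.call(kinase_feature_table, c(list(b, gs$kinase), kin_args)) else NULL
  inh_static <- setdiff(gs$inhibitor, "KNN")
  inh_ft <- if (length(inh_static))
    do.call(inhibitor_feature_table, c(list(b, inh_static), inh_args)) else NULL
  use_knn <- "KNN" %in% gs$inhibitor
  knn_metric <- inh_args$knn_metric %||% "tanimoto"
  knn_k <- inh_args$k %||% 3L
  as_factors <- clf$kind == "tree"

  labels <- as.integer(t(b$matrix))  # row-major pair order
  kin_rows <- rep(seq_len(m), each = n)
  inh_rows <- rep(seq_len(n), times = m)
  # static (split-independent) design, built once
  expand <- function(ft, rows) {
    if (is.null(ft)) return(NULL)
    out <- ft
    out$values <- ft$values[rows, , drop = FALSE]
    rownames(out$values) <- NULL
    out$ids <- sprintf("p%d", seq_along(rows))
    out
  }
  static_fts <- Filter(Negate(is.null),
                       list(expand(kin_ft, kin_rows), expand(inh_ft, inh_rows)))
  static_ft <- if (length(static_fts)) do.call(ft_bind, static_fts) else NULL
  static_df <- if (!is.null(static_ft)) {
    if (clf$kind == "svm") {
      enc <- encode_nominal(static_ft)$values
      names(enc) <- make.names(names(enc), unique = TRUE)
      enc
    } else ft_to_df(static_ft, as_factors = TRUE)
  } else data.frame(row.names = seq_len(m * n))
  knn_colnames <- make.names(paste0("knn_", colnames(b$matrix)), unique = TRUE)

  one_repeat <- function(rep_idx) {
    rspec <- spec
    rspec$seed <- spec$seed + rep_idx - 1L
    splits <- make_splits(m, n, rspec)
    test_truth <- test_pred <- integer(length(splits$splits))
    train_truth <- train_pred <- list()
    hard_knn_warned <- FALSE
    for (si in seq_along(splits$splits)) {
      s <- splits$splits[[si]]
      check_split(s, n, spec$case)
      ti <- pair_ij(s$test, n)[1, 1]
      df <- static_df
      if (use_knn) {
        if (spec$case == "hard") {
          if (!hard_knn_warned && rep_idx == 1L) {
            warning("KNN features are undefined in the hard case; emitting zeros")
            hard_knn_warned <- TRUE
          }
          knn_vals <- as.data.frame(
            matrix(0, m * n, n, dimnames = list(NULL, knn_colnames)))
        } else {
          masked <- b$matrix[-ti, , drop = FALSE]  # drop the test kinase row
          assert_that(nrow(masked) == m - 1L, "leakage guard: mask failed")
          kft <- knn_feature_table(masked, k = knn_k, metric = knn_metric)
          knn_vals <- kft$values[inh_rows, , drop = FALSE]
          names(knn_vals) <- knn_colnames
          rownames(knn_vals) <- NULL
        }
        df <- cbind(df, knn_vals)
      }
      train_x <- df[s$train, , drop = FALSE]
      test_x <- df[s$test, , drop = FALSE]
      if (clf$kind == "svm") {
        scaler <- fit_minmax(train_x)
        train_x <- predict(scaler, train_x)
        test_x <- predict(scaler, test_x)
      }
      fp <- suppressWarnings(
        fit_predict(clf, train_x, labels[s$train], test_x, seed = seed))
      test_truth[si] <- labels[s$test]
      test_pred[si] <- fp$labels[1]
      if (train_metrics) {
        tr <- suppressWarnings(
          fit_predict(clf, train_x, labels[s$train], train_x, seed = seed))
        train_truth[[si]] <- labels[s$train]
        train_pred[[si]] <- tr$labels
      }
    }
    list(test = compute_metrics(confusion_counts(test_truth, test_pred)),
         train = if (train_metrics)
           compute_metrics(confusion_counts(unlist(train_truth),
                                            unlist(train_pred))) else NULL)
  }

  reps <- lapply(seq_len(spec$repeats), one_repeat)
  fields <- c("accuracy", "recall_pos", "precision_pos", "recall_neg",
              "precision_neg")
  avg <- function(side) {
    if (is.null(reps[[1]][[side]]))
      return(stats::setNames(as.list(rep(NA_real_, length(fields))), fields))
    stats::setNames(lapply(fields, function(f)
      mean(vapply(reps, function(r) r[[side]][[f]], 0), na.rm = TRUE)),
      fields)
  }
  structure(list(
    case = spec$case, groups = groups, classifier = clf,
    repeats = spec$repeats,
    test = avg("test"), train = avg("train"),
    per_repeat = reps,
    majority_rate = max(mean(b$matrix), 1 - mean(b$matrix)),
    n_pairs = m * n),
    class = "ki_eval")
}

#' @export
print.ki_eval <- function(x, ...) {
  cat(sprintf("ki_eval: %s case, %s, %d repeat(s), %d pairs\n",
              x$case,
              if (x$classifier$kind == "svm")
                sprintf("svm/%s", x$classifier$kernel) else "tree",
              x$repeats, x$n_pairs))
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", 100 * v)
  cat(sprintf(
    "  test : accuracy %s%% (majority %s%%)  TPR %s%%  PPV %s%%  TNR %s%%  NPV %s%%\n",
    pc(x$test$accuracy), pc(x$majority_rate), pc(x$test$recall_pos),
    pc(x$test$precision_pos), pc(x$test$recall_neg), pc(x$test$precision_neg)))
  cat(sprintf("  train: accuracy %s%%\n", pc(x$train$accuracy)))
  invisible(x)
}

#' @export
summary.ki_eval <- function(object, ...) {
  df <- data.frame(
    side = c("test", "train"),
    accuracy = c(object$test$accuracy, object$train$accuracy),
    recall_pos = c(object$test$recall_pos, object$train$recall_pos),
    precision_pos = c(object$test$precision_pos, object$train$precision_pos),
    recall_neg = c(object$test$recall_neg, object$train$recall_neg),
    precision_neg = c(object$test$precision_neg, object$train$precision_neg))
  attr(df, "majority_rate") <- object$majority_rate
  df
}
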