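test_that("split sizes obey the four closed-form formulas for random dimensions", {
  set.seed(13)
  dims <- cbind(m = sample(2:30, 6), n = sample(2:30, 6))
  for (r in seq_len(nrow(dims))) {
    m <- dims[r, "m"]; n <- dims[r, "n"]
    soft <- make_splits(m, n, split_spec("soft"))
    hard <- make_splits(m, n, split_spec("hard"))
    expect_length(soft$splits, m * n)
    expect_true(all(lengths(lapply(soft$splits, `[[`, "train")) == m * n - 1L))
    expect_true(all(lengths(lapply(hard$splits, `[[`, "train")) ==
                      (m - 1L) * (n - 1L)))
    restr <- restrict_to_test_molecules(soft)
    expect_true(all(lengths(lapply(restr$splits, `[[`, "train")) ==
                      (m - 1L) + (n - 1L)))
    f <- 0.4
    mixed <- make_splits(m, n, split_spec("mixed", f, f, repeats = 1L))
    r_k <- round_half_up(f * m); r_i <- round_half_up(f * n)
    expect_true(all(lengths(lapply(mixed$splits, `[[`, "train")) ==
                      (m - 1L) * (n - 1L) + r_k + r_i))
  }
})

test_that("no split leaks the test pair, and hard splits share no molecule", {
  m <- 7L; n <- 5L
  for (case in c("soft", "hard")) {
    sp <- make_splits(m, n, split_spec(case))
    for (s in sp$splits) expect_true(check_split(s, n, case))
  }
  mixed <- make_splits(m, n, split_spec("mixed_mixed", 0.5, 0.25,
                                        repeats = 1L))
  for (s in mixed$splits) {
    expect_true(check_split(s, n, "mixed_mixed"))
    expect_false(anyDuplicated(s$train) > 0)
  }
})

test_that("mixed insertions contain the announced partner counts", {
  n <- 5L
  mixed <- make_splits(6L, n, split_spec("mixed_mixed", kinase_amount = 3L,
                                         inhibitor_amount = 2L,
                                         repeats = 1L, absolute = TRUE))
  for (s in mixed$splits) {
    tij <- kipred:::pair_ij(s$test, n)
    ij <- kipred:::pair_ij(s$train, n)
    with_test_inh <- sum(ij[, 2] == tij[1, 2])
    with_test_kin <- sum(ij[, 1] == tij[1, 1])
    expect_equal(with_test_inh, 3L)  # kinase partners of the test inhibitor
    expect_equal(with_test_kin, 2L)  # inhibitor partners of the test kinase
  }
  # requesting more partners than exist errors
  expect_error(make_splits(6L, n, split_spec("mixed_mixed", 3L, 5L,
                                             absolute = TRUE)),
               "exceeds")
})

test_that("metrics match their definitions and the prevalence identity", {
  mm <- compute_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$recall_pos, 1)
  maj <- compute_metrics(list(TP = 0, FP = 0, TN = 1663, FN = 597))
  expect_equal(round(maj$accuracy, 3), 0.736)
  expect_equal(maj$recall_pos, 0)
  expect_true(is.na(maj$precision_pos))
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "no predictions")
  set.seed(31)
  for (i in 1:10) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    if (Reduce(`+`, cc) == 0) next
    mm <- compute_metrics(cc)
    pi_pos <- (cc$TP + cc$FN) / Reduce(`+`, cc)
    tpr <- if (is.na(mm$recall_pos)) 0 else mm$recall_pos
    tnr <- if (is.na(mm$recall_neg)) 0 else mm$recall_neg
    expect_equal(mm$accuracy, pi_pos * tpr + (1 - pi_pos) * tnr)
  }
})

test_that("majority baseline predicts the dominant class, ties to no-binding", {
  mb <- majority_baseline(c(rep(0L, 1663), rep(1L, 597)))
  expect_equal(mb$label, 0L)
  expect_equal(round(mb$rate, 3), 0.736)
  expect_equal(predict(mb, 3), c(0L, 0L, 0L))
  expect_equal(majority_baseline(rep(1L, 5))$label, 1L)
  expect_equal(majority_baseline(c(0L, 1L))$label, 0L)
})

test_that("probability-product baseline uses training pairs only and a strict threshold", {
  mat <- matrix(c(1L,0L,0L, 0L,1L,0L, 1L,1L,0L), 3, 3, byrow = TRUE,
                dimnames = list(paste0("k", 1:3), paste0("i", 1:3)))
  soft <- make_splits(3L, 3L, split_spec("soft"))
  s11 <- soft$splits[[1]]  # test pair (k1, i1)
  bl <- probability_product_baseline(mat, s11, theta = 0)
  # k1 training pairs: (k1,i2)=0,(k1,i3)=0 -> p_kin = 0
  expect_equal(bl$p_kin, 0)
  # i1 training pairs: (k2,i1)=0,(k3,i1)=1 -> p_inh = 0.5
  expect_equal(bl$p_inh, 0.5)
  expect_equal(bl$pred, 0L)
  # strictness: product == theta predicts no-binding
  s <- soft$splits[[5]]  # test (k2, i2); p_kin over (k2,i1),(k2,i3)
  bl5 <- probability_product_baseline(mat, s, theta = 0)
  expect_equal(bl5$pred, as.integer(bl5$product > 0))
  bl5b <- probability_product_baseline(mat, s, theta = bl5$product)
  expect_equal(bl5b$pred, 0L)
  # hard split errors
  hard <- make_splits(3L, 3L, split_spec("hard"))
  expect_error(probability_product_baseline(mat, hard$splits[[1]], 0.5),
               "non-hard")
  # exhaustive truth table over all 9 pairs for a theta sweep
  for (theta in c(0, 0.2, 0.5)) {
    for (s in soft$splits) {
      got <- probability_product_baseline(mat, s, theta)
      tij <- kipred:::pair_ij(s$test, 3L)
      pk <- mean(mat[tij[1, 1], -tij[1, 2]])
      pi_ <- mean(mat[-tij[1, 1], tij[1, 2]])
      expect_equal(got$pred, as.integer(pk * pi_ > theta))
    }
  }
})

test_that("probability-product baseline is invariant under matrix permutation", {
  set.seed(17)
  mat <- matrix(rbinom(20, 1, 0.4), 5, 4,
                dimnames = list(paste0("k", 1:5), paste0("i", 1:4)))
  storage.mode(mat) <- "integer"
  soft <- make_splits(5L, 4L, split_spec("soft"))
  preds <- vapply(soft$splits, function(s)
    probability_product_baseline(mat, s, 0.3)$pred, 0L)
  pr <- sample(5); pc <- sample(4)
  mat2 <- mat[pr, pc]
  soft2 <- make_splits(5L, 4L, split_spec("soft"))
  preds2 <- vapply(soft2$splits, function(s)
    probability_product_baseline(mat2, s, 0.3)$pred, 0L)
  # prediction for permuted pair (i, j) equals the original pair's
  perm_pred <- matrix(preds, 5, 4, byrow = TRUE)[pr, pc]
  expect_equal(matrix(preds2, 5, 4, byrow = TRUE), perm_pred,
               ignore_attr = TRUE)
})

test_that("theta optimization maximizes mean accuracy with smallest-tie rule", {
  mat <- matrix(0L, 3, 3, dimnames = list(paste0("k", 1:3), paste0("i", 1:3)))
  soft <- make_splits(3L, 3L, split_spec("soft"))
  expect_equal(optimize_theta(mat, soft, grid = c(0.1, 0.5, 0.9)), 0.1)
  expect_equal(optimize_theta(mat, soft, grid = 0.7), 0.7)
  # a matrix where a mid threshold is strictly best: grid evaluation oracle
  mat2 <- matrix(c(1L,1L,0L, 1L,1L,0L, 0L,0L,0L), 3, 3, byrow = TRUE,
                 dimnames = dimnames(mat))
  grid <- seq(0, 1, 0.05)
  accs <- vapply(grid, function(th) {
    mean(vapply(soft$splits, function(s) {
      p <- probability_product_baseline(mat2, s, th)
      as.integer(p$pred == mat2[kipred:::pair_ij(s$test, 3L)])
    }, 0L))
  }, 0)
  expect_equal(optimize_theta(mat2, soft, grid), grid[which.max(accs)])
})

test_that("feature randomization stays in the observed range and is seeded", {
  ft <- feature_table(
    data.frame(s1 = c(3, 3, 3), s2 = c(1, 5, 9), keep = c(2, 4, 8),
               lab = c("a", "b", "a")),
    paste0("e", 1:3),
    c(s1 = "numeric", s2 = "numeric", keep = "numeric", lab = "nominal"),
    c(s1 = "locAli", s2 = "locAli", keep = "CF", lab = "MS"))
  r1 <- randomize_features(ft, "locAli", seed = 1L)
  expect_equal(r1$values$s1, c(3, 3, 3))  # degenerate range stays put
  expect_true(all(r1$values$s2 >= 1 & r1$values$s2 <= 9))
  expect_equal(r1$values$keep, ft$values$keep)
  r1b <- randomize_features(ft, "locAli", seed = 1L)
  expect_identical(r1$values, r1b$values)
  r2 <- randomize_features(ft, "locAli", seed = 2L)
  expect_false(identical(r1$values$s2, r2$values$s2))
  expect_error(randomize_features(ft, "MS", seed = 1L), "nominal")
  expect_error(randomize_features(ft, "KNN", seed = 1L), "absent")
})
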