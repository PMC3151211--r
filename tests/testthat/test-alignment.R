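test_that("global alignment score matches the worked toy examples", {
  smAC <- toy_subst(c("A", "C", "G"), diag = c(4, 9, 0), gap = -1)
  expect_equal(global_align_score("AC", "AC", smAC), 13)
  expect_equal(global_align_score("AC", "AGC", smAC), 12)
  sm2 <- subst_matrix("custom",
                      score = matrix(c(0, -2, -2, 0), 2, 2,
                                     dimnames = list(c("A", "C"), c("A", "C"))),
                      gap = -4)
  expect_equal(global_align_score("A", "C", sm2), -2)
})

test_that("alignment equals exhaustive enumeration on random small instances", {
  set.seed(7)
  letters4 <- c("A", "C", "D", "E")
  sc <- matrix(sample(-3:5, 16, replace = TRUE), 4, 4,
               dimnames = list(letters4, letters4))
  sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
  sm <- subst_matrix("custom", score = sc, gap = -3)
  for (trial in 1:12) {
    a <- paste(sample(letters4, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(letters4, sample(1:6, 1), replace = TRUE), collapse = "")
    want <- oracle_align(a, b, sc, gap = -3)
    expect_equal(global_align_score(a, b, sm), want,
                 info = sprintf("%s vs %s", a, b))
    expect_equal(global_align_score(b, a, sm), want)
  }
})

test_that("self-alignment dominates under the shipped similarity matrices", {
  set.seed(11)
  for (name in c("PAM120", "BLOSUM62")) {
    sm <- subst_matrix(name)
    seqs <- vapply(1:4, function(i)
      paste(sample(rownames(sm$score), 8, replace = TRUE), collapse = ""), "")
    for (a in seqs) for (b in seqs)
      expect_gte(global_align_score(a, a, sm), global_align_score(a, b, sm))
  }
})

test_that("NCBI-format matrix files load as symmetric custom schemes", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy", "  A C", "A 2 -1", "C -1 3"), tf)
  sm <- read_subst_matrix(tf, gap = -2)
  expect_equal(sm$score["A", "C"], -1)
  expect_equal(global_align_score("AC", "AC", sm), 5)
})

test_that("conserved columns use a strict majority threshold, ignoring gaps", {
  m <- msa(paste0("k", 1:5),
           c("KACDE", "KACDQ", "KAC-Q", "KACDQ", "KTCDQ"))
  # col1: K in 5/5 (>4: yes); col2: A 4/5 (>4: no, strict)
  expect_equal(conserved_columns(m, min_count = 4L), c(1L, 3L))
  # col4: D in 4 of the 4 non-gap rows; still needs > min_count of all rows
  expect_true(4L %in% conserved_columns(m, min_count = 3L))
  # fractional default mirrors the more-than-100-of-113 rule
  expect_equal(round_half_up(100 / 113 * 113), 100L)
})

test_that("frames are flanked, merged when close, and require active conserved columns", {
  m <- msa(c("a", "b"), c(strrep("A", 100), strrep("A", 100)))
  f1 <- extract_frames(m, conserved = 10L, active_columns = 10L, flank = 5L)
  expect_equal(length(f1), 1L)
  expect_equal(c(f1[[1]]$start, f1[[1]]$end), c(5L, 15L))
  f2 <- extract_frames(m, conserved = c(10L, 14L), active_columns = c(10L, 14L))
  expect_equal(length(f2), 1L)
  expect_equal(c(f2[[1]]$start, f2[[1]]$end), c(5L, 19L))
  expect_equal(f2[[1]]$conserved, c(10L, 14L))
  expect_equal(extract_frames(m, conserved = 10L, active_columns = 50L),
               list())
  # distant anchors stay disjoint and sorted
  f3 <- extract_frames(m, conserved = c(10L, 40L), active_columns = c(10L, 40L))
  expect_equal(length(f3), 2L)
  expect_true(f3[[1]]$end < f3[[2]]$start)
})

test_that("frame scoring matches column-wise and realigned computations", {
  sm <- toy_subst(c("A", "C", "G", "M", "K", "V"),
                  diag = c(4, 9, 5, 3, 3, 3), gap = -1)
  m <- msa(c("x", "y"), c("A-C", "AGC"))
  frames <- list(list(start = 1L, end = 3L, conserved = 2L))
  expect_equal(frame_pair_score(m, frames, "x", "y", sm, realign = FALSE),
               4 + (-1) + 9)
  expect_equal(frame_pair_score(m, frames, "x", "y", sm, realign = TRUE),
               global_align_score("AC", "AGC", sm))
  # self-score without gaps is the diagonal sum
  m2 <- msa(c("x", "y"), c("ACG", "ACG"))
  expect_equal(frame_pair_score(m2, frames, "x", "x", sm), 4 + 9 + 5)
  # gap-gap columns score zero
  m3 <- msa(c("x", "y"), c("A-C", "A-C"))
  expect_equal(frame_pair_score(m3, frames, "x", "y", sm), 4 + 0 + 9)
})

test_that("score vector features form a symmetric m x m table matching the scorer", {
  kin <- data.frame(id = c("a", "b", "c"),
                    sequence = c("ACA", "ACC", "CCA"))
  sm <- toy_subst(c("A", "C"), diag = c(2, 3), gap = -1)
  ft <- score_vector_features(kin, "glAli", sm)
  expect_equal(dim(ft$values), c(3L, 3L))
  S <- as.matrix(ft$values)
  expect_equal(S, t(S), ignore_attr = TRUE)
  for (i in 1:3) for (j in 1:3)
    expect_equal(unname(S[i, j]),
                 global_align_score(kin$sequence[i], kin$sequence[j], sm))
  expect_true(all(ft$groups == "glAli"))
})

test_that("locAli vectors score the conserved frames only", {
  kin <- data.frame(id = c("a", "b", "c"),
                    sequence = c("AAACG", "AAACG", "AAAGG"))
  m <- msa(kin$id, kin$sequence)
  sm <- toy_subst(c("A", "C", "G"), diag = c(1, 5, 2), off = -1, gap = -2)
  frames <- list(list(start = 4L, end = 5L, conserved = 4L))
  ft <- score_vector_features(kin, "locAli", sm, m = m, frames = frames)
  expect_equal(ft$values[1, 2], 5 + 2)      # CG vs CG
  expect_equal(ft$values[1, 3], -1 + 2)     # CG vs GG
  expect_true(all(ft$groups == "locAli"))
})
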