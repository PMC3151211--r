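test_that("pattern matching treats the wildcard as exactly one residue and ignores multiplicity", {
  expect_true(pattern_matches("AC", "WACW"))
  expect_true(pattern_matches("A.C", "AWC"))
  expect_false(pattern_matches("A.C", "AC"))
  # two occurrences still contribute support 1
  expect_equal(pattern_support("AC", c("ACAC")), 1L)
})

test_that("miner agrees with the brute-force enumeration oracle", {
  corpora <- list(
    list(seqs = c("ACAC", "ACAA", "CCAC"), minsup = 2L, wc = 0L, min_size = 2L),
    list(seqs = c("AWC", "AYC"), minsup = 2L, wc = 1L, min_size = 3L),
    list(seqs = c("MKVLAW", "MKVCAW", "MKVCAY", "QKVCAW"), minsup = 3L,
         wc = 2L, min_size = 2L),
    list(seqs = c("ADADAD", "DADADA"), minsup = 2L, wc = 2L, min_size = 1L))
  for (cs in corpora) {
    got <- mine_frequent(cs$seqs, cs$minsup, max_wildcards = cs$wc,
                         min_size = cs$min_size, max_len = 10L)
    want <- oracle_patterns(cs$seqs, cs$minsup, max_wc = cs$wc,
                            min_size = cs$min_size, max_len = 10L)
    expect_equal(got$pattern, want$pattern)
    expect_equal(got$support, want$support)
  }
})

test_that("miner recovers the documented toy corpus exactly", {
  ps <- mine_frequent(c("ACAC", "ACAA", "CCAC"), minsup = 2L,
                      max_wildcards = 0L, min_size = 2L)
  expect_setequal(ps$pattern, c("AC", "CA", "ACA", "CAC"))
  expect_equal(ps$support[match(c("AC", "CA", "ACA", "CAC"), ps$pattern)],
               c(3L, 3L, 2L, 2L))
  # and a wildcard bridges two variants
  ps2 <- mine_frequent(c("AWC", "AYC"), minsup = 2L, max_wildcards = 1L,
                       min_size = 3L)
  expect_true("A.C" %in% ps2$pattern)
  expect_equal(ps2$support[ps2$pattern == "A.C"], 2L)
})

test_that("minsup above the corpus size and empty corpora give empty sets", {
  expect_equal(nrow(mine_frequent(c("ACA"), minsup = 2L)), 0L)
  expect_equal(nrow(mine_frequent(character(0), minsup = 1L)), 0L)
})

test_that("support is anti-monotone over all mined sub/super-pattern pairs", {
  set.seed(42)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "D", "E"), 10, replace = TRUE), collapse = ""),
    "")
  ps <- mine_frequent(seqs, minsup = 2L, max_wildcards = 2L, min_size = 1L,
                      max_len = 6L)
  for (i in seq_len(nrow(ps))) for (j in seq_len(nrow(ps))) {
    if (i != j && kipred:::is_subpattern(ps$pattern[i], ps$pattern[j]))
      expect_gte(ps$support[i], ps$support[j])
  }
})

test_that("border elements are exactly the maximal patterns", {
  ps <- mine_frequent(c("ACAC", "ACAA", "CCAC"), minsup = 2L,
                      max_wildcards = 0L, min_size = 2L)
  border <- border_elements(ps)
  expect_setequal(border$pattern, c("ACA", "CAC"))
  # no border element is a sub-pattern of another
  for (i in seq_len(nrow(border))) for (j in seq_len(nrow(border)))
    if (i != j)
      expect_false(kipred:::is_subpattern(border$pattern[i],
                                          border$pattern[j]))
  # every frequent pattern is covered by some border element
  for (p in ps$pattern)
    expect_true(any(vapply(border$pattern, function(q)
      kipred:::is_subpattern(p, q), logical(1))))
  # degenerate cases
  single <- mine_frequent("ACD", minsup = 1L, max_wildcards = 0L,
                          min_size = 3L, max_len = 3L)
  expect_equal(border_elements(single)$pattern, single$pattern)
  empty <- mine_frequent(character(0), minsup = 1L)
  expect_equal(nrow(border_elements(empty)), 0L)
})

test_that("apriori presence features are 0/1 per pattern", {
  kin <- data.frame(id = c("k1", "k2"), sequence = c("ACAC", "DDDD"))
  ps <- mine_frequent(c("ACAC", "ACAA", "CCAC"), minsup = 2L,
                      max_wildcards = 0L, min_size = 2L)
  ft <- apriori_features(border_elements(ps), kin)
  expect_equal(unname(unlist(ft$values[1, ])), c(1L, 1L))
  expect_equal(unname(unlist(ft$values[2, ])), c(0L, 0L))
  expect_true(all(ft$groups == "Apri"))
})
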