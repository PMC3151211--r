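test_that("molecular graphs validate their invariants", {
  expect_error(molgraph("C", data.frame(from = 1, to = 1, order = 1)),
               "self-loop")
  expect_error(molgraph(c("C", "O"),
                        data.frame(from = c(1, 2), to = c(2, 1),
                                   order = c(1, 1))), "once")
  expect_error(molgraph(c("C", "O"),
                        data.frame(from = 1, to = 3, order = 1)),
               "out of range")
  expect_error(molgraph(c("C", "C"), data.frame()), "disconnected")
  # implicit hydrogens from standard valences
  eth <- ethanol_graph()
  expect_equal(eth$hcount, c(3L, 2L, 1L))
  # charge adjusts the effective valence
  ammonium <- molgraph(c("C", "N"), data.frame(from = 1, to = 2, order = 1),
                       charges = c(0L, 1L))
  expect_equal(ammonium$hcount, c(3L, 3L))
})

test_that("tree canonical form is invariant under vertex permutation", {
  set.seed(5)
  base_el <- c("C", "C", "N", "O", "C", "S")
  base_bonds <- data.frame(from = c(1, 2, 2, 3, 5),
                           to = c(2, 3, 4, 5, 6),
                           order = c(1, 1, 2, 1, 1))
  ref <- tree_canonical(base_el, base_bonds)
  for (trial in 1:10) {
    perm <- sample(6)
    inv <- order(perm)
    el2 <- base_el[inv]
    b2 <- data.frame(from = perm[base_bonds$from], to = perm[base_bonds$to],
                     order = base_bonds$order)
    expect_equal(tree_canonical(el2, b2), ref)
  }
  # distinct trees get distinct forms
  other <- tree_canonical(base_el, data.frame(from = c(1, 1, 1, 1, 1),
                                              to = 2:6,
                                              order = c(1, 1, 2, 1, 1)))
  expect_false(identical(ref, other))
})

test_that("tree-in-graph containment respects labels, orders and rings", {
  eth <- ethanol_graph()
  cc <- free_tree(c("C", "C"), data.frame(from = 1, to = 2, order = 1))
  co <- free_tree(c("C", "O"), data.frame(from = 1, to = 2, order = 1))
  cdo <- free_tree(c("C", "O"), data.frame(from = 1, to = 2, order = 2))
  expect_true(tree_in_graph(cc, eth))
  expect_true(tree_in_graph(co, eth))
  expect_false(tree_in_graph(cdo, eth))
  # a path matches inside a ring
  expect_true(tree_in_graph(
    free_tree(c("C", "C", "C"),
              data.frame(from = c(1, 2), to = c(2, 3), order = c(2, 1))),
    benzene_graph()))
})

test_that("miner equals the brute-force subgraph enumeration oracle", {
  mk <- function(el, from, to, ord)
    molgraph(el, data.frame(from = from, to = to, order = ord))
  sets <- list(
    list(graphs = list(ethanol_graph(),
                       mk(c("C", "C", "N"), c(1, 2), c(2, 3), c(1, 1))),
         min_freq = 1.0),
    list(graphs = list(ethanol_graph(),
                       mk(c("C", "O", "C", "N"), c(1, 2, 1), c(2, 3, 4),
                          c(1, 1, 1)),
                       mk(c("O", "C", "O"), c(1, 2), c(2, 3), c(1, 2))),
         min_freq = 0.5),
    list(graphs = list(benzene_graph(),
                       mk(c("C", "C", "C", "C"), c(1, 2, 3), c(2, 3, 4),
                          c(2, 1, 2))),
         min_freq = 1.0))
  for (cs in sets) {
    thr <- ceiling(cs$min_freq * length(cs$graphs))
    want <- oracle_frequent_trees(cs$graphs, thr, max_size = 8L)
    got <- mine_free_trees(cs$graphs, min_freq = cs$min_freq,
                           border_only = FALSE, max_atoms = 8L)
    expect_equal(vapply(got, `[[`, "", "canonical"), want)
    # supports agree with direct counting
    for (tr in got)
      expect_equal(tr$support,
                   sum(vapply(cs$graphs, function(g) tree_in_graph(tr, g),
                              logical(1))))
  }
})

test_that("the documented two-molecule border example gives C-C", {
  graphs <- list(ethanol_graph(),
                 molgraph(c("C", "C", "N"),
                          data.frame(from = c(1, 2), to = c(2, 3),
                                     order = c(1, 1))))
  border <- mine_free_trees(graphs, min_freq = 1.0)
  expect_equal(length(border), 1L)
  expect_equal(border[[1]]$size, 2L)
  expect_equal(border[[1]]$elements, c("C", "C"))
})

test_that("border elements are maximal and cover every frequent tree", {
  gen <- small_bundle()
  graphs <- gen$bundle$molecules[1:4]
  all_freq <- mine_free_trees(graphs, min_freq = 0.5, border_only = FALSE,
                              max_atoms = 5L)
  border <- mine_free_trees(graphs, min_freq = 0.5, border_only = TRUE,
                            max_atoms = 5L)
  border_canon <- vapply(border, `[[`, "", "canonical")
  expect_true(all(border_canon %in% vapply(all_freq, `[[`, "", "canonical")))
  for (i in seq_along(border)) for (j in seq_along(border))
    if (i != j)
      expect_false(border[[i]]$size < border[[j]]$size &&
                     kipred:::tree_in_tree(border[[i]], border[[j]]))
  for (tr in all_freq)
    expect_true(any(vapply(border, function(bd)
      tr$canonical == bd$canonical || kipred:::tree_in_tree(tr, bd),
      logical(1))))
})

test_that("free-tree support is anti-monotone under extension", {
  gen <- small_bundle()
  graphs <- gen$bundle$molecules[1:5]
  trees <- mine_free_trees(graphs, min_freq = 0.2, border_only = FALSE,
                           max_atoms = 4L)
  for (a in trees) for (b in trees)
    if (a$size < b$size && kipred:::tree_in_tree(a, b))
      expect_gte(a$support, b$support)
})

test_that("mining degenerates gracefully", {
  expect_equal(mine_free_trees(list()), list())
  g <- ethanol_graph()
  # single molecule: its own spanning tree is the border element
  border <- mine_free_trees(list(g), min_freq = 1.0)
  expect_equal(length(border), 1L)
  expect_equal(border[[1]]$canonical,
               tree_canonical(g$elements, g$bonds))
  # threshold too high for any pattern
  g2 <- molgraph("S", data.frame())
  expect_equal(mine_free_trees(list(g, g2), min_freq = 1.0), list())
})

test_that("free-tree features flag pattern presence per molecule", {
  graphs <- list(a = ethanol_graph(),
                 b = molgraph(c("C", "N"),
                              data.frame(from = 1, to = 2, order = 1)))
  pats <- list(free_tree(c("C", "O"), data.frame(from = 1, to = 2, order = 1)),
               free_tree(c("C", "N"), data.frame(from = 1, to = 2, order = 1)))
  ft <- freetree_features(pats, graphs)
  expect_equal(unname(as.matrix(ft$values)),
               matrix(c(1L, 0L, 0L, 1L), 2, 2), ignore_attr = TRUE)
  expect_true(all(ft$groups == "FTs"))
})
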