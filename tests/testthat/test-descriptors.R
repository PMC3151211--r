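test_that("chemical descriptors match hand-computed values on small molecules", {
  eth <- chemical_descriptors(ethanol_graph())
  expect_equal(unname(eth["mw"]), 2 * 12.011 + 15.999 + 6 * 1.008,
               tolerance = 1e-6)
  expect_equal(unname(eth["hbd"]), 1)
  expect_equal(unname(eth["hba"]), 1)
  expect_equal(unname(eth["rotb"]), 0)  # both bonds are terminal
  methane <- chemical_descriptors(molgraph("C", data.frame()))
  expect_equal(unname(methane[c("hbd", "hba", "rotb")]), c(0, 0, 0))
  benz <- chemical_descriptors(benzene_graph())
  expect_equal(unname(benz["rotb"]), 0)  # ring bonds are not rotatable
  expect_equal(unname(benz["ring_bonds"]), 6)
  # butane: only the central C-C bond has two non-terminal ends
  butane <- molgraph(rep("C", 4),
                     data.frame(from = 1:3, to = 2:4, order = rep(1, 3)))
  expect_equal(unname(chemical_descriptors(butane)["rotb"]), 1)
  expect_error(chemical_descriptors(ethanol_graph(), which = "nope"),
               "unknown descriptor")
})

test_that("geometric descriptors: diameter, bounding box, degenerate cases", {
  chain4 <- molgraph(rep("C", 4),
                     data.frame(from = 1:3, to = 2:4, order = rep(1, 3)))
  gd <- geometric_descriptors(chain4)
  expect_equal(unname(gd["diameter"]), 3)
  expect_equal(unname(gd["n_atoms"]), 4)
  square <- molgraph(rep("C", 4),
                     data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
                                order = rep(1, 4)),
                     coords = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  gs <- geometric_descriptors(square)
  expect_equal(unname(gs["length2d"]), 1, tolerance = 1e-9)
  expect_equal(unname(gs["width2d"]), 1, tolerance = 1e-9)
  single <- geometric_descriptors(molgraph("C", data.frame()))
  expect_equal(unname(single), c(0, 0, 0, 0, 1))
  # coordinate-free layout is deterministic
  g1 <- geometric_descriptors(chain4)
  g2 <- geometric_descriptors(chain4)
  expect_identical(g1, g2)
})

test_that("pharmacophore triples enumerate role atoms with sorted keys", {
  # 5-atom chain: HBD (N-H), POS (N+), HBA (carbonyl O): N-C-[N+]-C=O
  chain <- molgraph(c("N", "C", "N", "C", "O"),
                    data.frame(from = 1:4, to = 2:5,
                               order = c(1, 1, 1, 2)),
                    charges = c(0L, 0L, 1L, 0L, 0L))
  keys <- kipred:::pharm_triplets(chain)
  expect_length(keys, 1L)
  # oracle: roles sorted (HBA, HBD, POS), distances N-N+=2, N-O=4, N+-O=2
  # binned with edges {3,5,7}: 1, 2, 1 -> sorted 1,1,2
  expect_equal(keys, "HBA|HBD|POS:1|1|2")
  # four role atoms yield choose(4,3) triples
  four <- molgraph(c("O", "C", "O", "C", "O", "C", "O"),
                   data.frame(from = 1:6, to = 2:7, order = rep(1, 6)))
  expect_length(kipred:::pharm_triplets(four), choose(4, 3))
  # fewer than three role atoms: nothing
  expect_length(kipred:::pharm_triplets(ethanol_graph()), 0L)
})

test_that("pharmacophore keys are invariant under atom reordering", {
  el <- c("N", "C", "N", "C", "O")
  bonds <- data.frame(from = 1:4, to = 2:5, order = c(1, 1, 1, 2))
  ref <- sort(kipred:::pharm_triplets(
    molgraph(el, bonds, charges = c(0L, 0L, 1L, 0L, 0L))))
  perm <- c(5, 3, 1, 2, 4)  # new index of old atom v is perm[v]
  inv <- order(perm)
  got <- sort(kipred:::pharm_triplets(
    molgraph(el[inv],
             data.frame(from = perm[bonds$from], to = perm[bonds$to],
                        order = bonds$order),
             charges = c(0L, 0L, 1L, 0L, 0L)[inv])))
  expect_equal(got, ref)
})

test_that("pharmacophore feature table counts triplets, zero-filling role-poor molecules", {
  mols <- list(
    rich = molgraph(c("N", "C", "N", "C", "O"),
                    data.frame(from = 1:4, to = 2:5,
                               order = c(1, 1, 1, 2)),
                    charges = c(0L, 0L, 1L, 0L, 0L)),
    poor = ethanol_graph())
  ft <- pharmacophore_features(mols)
  expect_equal(nrow(ft$values), 2L)
  expect_equal(sum(ft$values[2, ]), 0)
  expect_equal(sum(ft$values[1, ]), 1)
  expect_true(all(ft$groups == "P"))
})

test_that("tanimoto matches set arithmetic and its boundary contracts", {
  x <- c(1, 1, 1, 0, 1, 1)
  y <- c(1, 1, 0, 1, 0, 1)
  a <- sum(x); b <- sum(y); cc <- sum(x & y)
  expect_equal(tanimoto(a, b, cc), cc / (a + b - cc))
  expect_equal(tanimoto(5, 4, 3), 0.5)
  expect_equal(tanimoto(3, 3, 3), 1)
  expect_equal(tanimoto(2, 3, 0), 0)
  expect_equal(tanimoto(0, 0, 0), 0)
  expect_error(tanimoto(2, 2, 3), "common count")
  # symmetry and bounds over random profiles
  set.seed(9)
  for (i in 1:20) {
    p <- rbinom(8, 1, 0.5); q <- rbinom(8, 1, 0.5)
    t1 <- tanimoto(sum(p), sum(q), sum(p & q))
    expect_equal(t1, tanimoto(sum(q), sum(p), sum(p & q)))
    expect_gte(t1, 0); expect_lte(t1, 1)
    if (sum(p) > 0 && t1 == 1) expect_equal(p, q)
  }
})

test_that("KNN binding features keep at most k nonzero entries, never the target", {
  mat <- matrix(c(1,1,0,0, 1,1,0,0, 1,0,1,0, 0,0,0,1, 0,1,1,0), 5, 4,
                byrow = TRUE,
                dimnames = list(paste0("k", 1:5), paste0("i", 1:4)))
  storage.mode(mat) <- "integer"
  v <- knn_binding_features(mat, "i1", k = 2L)
  expect_equal(unname(v["i1"]), 0)
  expect_lte(sum(v != 0), 2L)
  # exhaustive similarity ranking as the oracle
  sims <- vapply(2:4, function(j) {
    cc <- sum(mat[, 1] & mat[, j])
    tanimoto(sum(mat[, 1]), sum(mat[, j]), cc)
  }, 0)
  top2 <- order(-sims)[1:2]
  expect_equal(unname(v[1 + top2]), sims[top2])
  # identical profile ranks first with similarity 1
  mat2 <- cbind(mat, i5 = mat[, "i1"])
  v2 <- knn_binding_features(mat2, "i1", k = 2L)
  expect_equal(unname(v2["i5"]), 1)
  # k >= n keeps every other inhibitor as a neighbour (entries equal the
  # similarities themselves, which may legitimately be 0)
  v3 <- knn_binding_features(mat, "i1", k = 10L)
  expect_equal(unname(v3[2:4]), sims)
})

test_that("inhibitor nominal features pass annotations through and demand them", {
  ann <- data.frame(id = c("i1", "i2"),
                    primary_target = c("KDR", "KDR"),
                    structure_cluster = c("C1", "C2"))
  ft <- inhibitor_nominal_features(ann)
  expect_equal(dim(ft$values), c(2L, 2L))
  expect_equal(unname(ft$groups), c("PT", "MS"))
  ann$primary_target[2] <- ""
  expect_error(inhibitor_nominal_features(ann), "i2")
})
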