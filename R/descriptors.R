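# Inhibitor descriptors: physico-chemical counts, 2D geometry, topological
# 3-point pharmacophores, binding-profile similarity (Tanimoto / common
# count) and KNN features, and the two nominal annotation features.

#' Physico-chemical descriptors of a molecule
#'
#' This package's own descriptor engine over the hydrogen-suppressed graph:
#' `mw` (molecular weight incl. implicit hydrogens), `hbd` (N/O with at
#' least one attached H), `hba` (N/O with non-positive formal charge),
#' `rotb` (rotatable bonds: single, acyclic, both ends non-terminal),
#' `heavy_atoms`, `hetero_atoms` (non-carbon heavy atoms), `ring_bonds`.
#' The descriptor list is fixed by `which`.
#'
#' @param g a `molgraph`.
#' @param which descriptor subset, default all seven.
#' @return named numeric vector.
#' @export
chemical_descriptors <- function(g, which = CHEMICAL_DESCRIPTOR_NAMES) {
  bad <- setdiff(which, CHEMICAL_DESCRIPTOR_NAMES)
  assert_that(length(bad) == 0L,
              sprintf("unknown descriptor(s): %s", paste(bad, collapse = ",")))
  deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = length(g$elements))
  ring <- mol_ring_bonds(g)
  vals <- c(
    mw = sum(ATOMIC_MASS[g$elements]) + sum(g$hcount) * ATOMIC_MASS[["H"]],
    hbd = sum(g$elements %in% c("N", "O") & g$hcount >= 1L),
    hba = sum(g$elements %in% c("N", "O") & g$charges <= 0L),
    rotb = if (nrow(g$bonds)) sum(g$bonds$order == 1 & !ring &
                                  deg[g$bonds$from] >= 2L &
                                  deg[g$bonds$to] >= 2L) else 0L,
    heavy_atoms = length(g$elements),
    hetero_atoms = sum(g$elements != "C"),
    ring_bonds = sum(ring))
  vals[which]
}

CHEMICAL_DESCRIPTOR_NAMES <- c("mw", "hbd", "hba", "rotb", "heavy_atoms",
                               "hetero_atoms", "ring_bonds")

#' Geometric descriptors of a molecule
#'
#' `diameter` (largest topological bond-count distance), `length2d` and
#' `width2d` (extents of the principal-axis-aligned bounding box of the 2D
#' coordinates), `lw_ratio` (length/width, 0 when width is 0) and
#' `n_atoms`. Molecules without stored coordinates get a deterministic
#' layout by classical multidimensional scaling of the topological distance
#' matrix.
#'
#' @param g a `molgraph`.
#' @return named numeric vector of the five descriptors.
#' @export
geometric_descriptors <- function(g) {
  n <- length(g$elements)
  if (n == 1L)
    return(c(diameter = 0, length2d = 0, width2d = 0, lw_ratio = 0,
             n_atoms = 1))
  D <- mol_distances(g)
  diam <- max(D[is.finite(D)])
  xy <- g$coords
  if (is.null(xy)) {
    xy <- stats::cmdscale(D, k = 2)
    if (ncol(xy) < 2L) xy <- cbind(xy, 0)
  }
  ctr <- scale(xy, scale = FALSE)
  pc <- stats::prcomp(ctr, center = FALSE)
  proj <- ctr %*% pc$rotation
  if (ncol(proj) < 2L) proj <- cbind(proj, 0)
  len <- diff(range(proj[, 1])); wid <- diff(range(proj[, 2]))
  if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
  c(diameter = diam, length2d = len, width2d = wid,
    lw_ratio = if (wid > 0) len / wid else 0, n_atoms = n)
}

#' Assign pharmacophore roles to atoms
#'
#' Priority order POS > NEG > HBD > HBA: positively/negatively charged
#' atoms by formal charge sign, then N/O with at least one attached H as
#' donors, then remaining N/O as acceptors. Atoms without a role get NA.
#'
#' @param g a `molgraph`.
#' @return character vector over `{"POS","NEG","HBD","HBA",NA}` per atom.
#' @export
pharmacophore_roles <- function(g) {
  role <- rep(NA_character_, length(g$elements))
  role[g$elements %in% c("N", "O")] <- "HBA"
  role[g$elements %in% c("N", "O") & g$hcount >= 1L] <- "HBD"
  role[g$charges < 0L] <- "NEG"
  role[g$charges > 0L] <- "POS"
  role
}

# default bin edges: distances 1-2 -> bin 1, 3-4 -> 2, 5-6 -> 3, >=7 -> 4
PHARMACOPHORE_BIN_STARTS <- c(3, 5, 7)

pharm_triplets <- function(g, bin_starts = PHARMACOPHORE_BIN_STARTS) {
  role <- pharmacophore_roles(g)
  atoms <- which(!is.na(role))
  if (length(atoms) < 3L) return(character(0))
  D <- mol_distances(g)
  keys <- character(0)
  combs <- utils::combn(atoms, 3L)
  for (k in seq_len(ncol(combs))) {
    a <- combs[, k]
    roles <- sort(role[a])
    d <- sort(findInterval(c(D[a[1], a[2]], D[a[1], a[3]], D[a[2], a[3]]),
                           bin_starts) + 1L)
    keys <- c(keys, paste0(paste(roles, collapse = "|"), ":",
                           paste(d, collapse = "|")))
  }
  keys
}

#' 3-point pharmacophore count features
#'
#' Enumerates all unordered triples of role-bearing atoms per molecule,
#' keys each triple by its lexicographically sorted roles and sorted binned
#' topological (bond-count) distances, and emits per-molecule counts. The
#' feature columns are the `top_f` most frequent triplet keys over the
#' corpus (ties broken alphabetically); molecules with fewer than three
#' role atoms get an all-zero row.
#'
#' @param mols named list of `molgraph` objects.
#' @param bin_starts left edges of distance bins 2..k (default
#'   `c(3, 5, 7)`, i.e. bins 1-2, 3-4, 5-6, >=7).
#' @param top_f number of feature columns kept (default 50).
#' @return a `feature_table`, group `P`.
#' @export
pharmacophore_features <- function(mols, bin_starts = PHARMACOPHORE_BIN_STARTS,
                                   top_f = 50L) {
  per_mol <- lapply(mols, pharm_triplets, bin_starts = bin_starts)
  counts <- sort(table(unlist(per_mol)), decreasing = TRUE)
  keys <- names(counts)
  if (length(keys) > 1L)  # stable order: frequency desc, then key
    keys <- keys[order(-as.integer(counts), names(counts))]
  keys <- utils::head(keys, top_f)
  vals <- as.data.frame(lapply(keys, function(key)
    vapply(per_mol, function(tk) sum(tk == key), 0)))
  names(vals) <- paste0("p_", gsub("[|:]", "_", keys))
  if (length(keys) == 0L) vals <- data.frame(row.names = seq_along(mols))
  rownames(vals) <- NULL
  feature_table(vals, names(mols),
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("P", ncol(vals)), names(vals)))
}

#' Tanimoto coefficient from profile counts
#'
#' `c / (a + b - c)` for two binary profiles with `a` and `b` ones and `c`
#' common ones; defined as 0 for two all-zero profiles.
#'
#' @param a,b numbers of ones in each profile.
#' @param c number of common ones (`c <= min(a, b)`).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b, c) {
  assert_that(c <= min(a, b), "common count cannot exceed either profile")
  assert_that(all(c(a, b, c) >= 0), "counts must be non-negative")
  if (a + b - c == 0) return(0)
  c / (a + b - c)
}

profile_similarity <- function(x, y, metric) {
  cc <- sum(x == 1L & y == 1L)
  if (metric == "common_count") cc else tanimoto(sum(x), sum(y), cc)
}

#' Binding-profile KNN features for one inhibitor
#'
#' Similarity of the target inhibitor's binding profile (its binding-matrix
#' column) to every other inhibitor's, with all but the k most similar
#' zeroed; the target's own entry is 0. Ties at the k-th rank are broken by
#' inhibitor column order. Under leakage-controlled evaluation the caller
#' passes a matrix with the test information masked (e.g. the test kinase's
#' row removed).
#'
#' @param matrix binding matrix.
#' @param target inhibitor id or column index.
#' @param k neighbourhood size (default 3); `k >= n` keeps all others.
#' @param metric `"tanimoto"` or `"common_count"`.
#' @return named numeric vector of length `ncol(matrix)`.
#' @export
knn_binding_features <- function(matrix, target, k = 3L,
                                 metric = c("tanimoto", "common_count")) {
  metric <- match.arg(metric)
  check_binding_matrix(matrix)
  j <- if (is.character(target)) match(target, colnames(matrix)) else
    as.integer(target)
  assert_that(!is.na(j) && j >= 1L && j <= ncol(matrix),
              "target inhibitor not found")
  n <- ncol(matrix)
  sims <- vapply(seq_len(n), function(jj)
    if (jj == j) -Inf else
      profile_similarity(matrix[, j], matrix[, jj], metric), 0)
  out <- numeric(n)
  others <- setdiff(seq_len(n), j)
  top <- others[order(-sims[others], others)][seq_len(min(k, n - 1L))]
  out[top] <- sims[top]
  stats::setNames(out, colnames(matrix))
}

#' KNN feature table for all inhibitors
#'
#' @inheritParams knn_binding_features
#' @return a `feature_table` with `ncol(matrix)` numeric columns, group
#'   `KNN`.
#' @export
knn_feature_table <- function(matrix, k = 3L,
                              metric = c("tanimoto", "common_count")) {
  metric <- match.arg(metric)
  ids <- colnames(matrix)
  vals <- as.data.frame(t(vapply(ids, function(id)
    knn_binding_features(matrix, id, k = k, metric = metric),
    numeric(ncol(matrix)))))
  names(vals) <- paste0("knn_", ids)
  rownames(vals) <- NULL
  feature_table(vals, ids,
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("KNN", ncol(vals)), names(vals)))
}

#' Inhibitor nominal features (primary target, structural cluster)
#'
#' @param inhibitors data frame `id, primary_target, structure_cluster`.
#' @return a `feature_table`: `PT` and `MS` nominal columns.
#' @export
inhibitor_nominal_features <- function(inhibitors) {
  for (col in c("primary_target", "structure_cluster")) {
    bad <- is.na(inhibitors[[col]]) | !nzchar(inhibitors[[col]])
    if (any(bad))
      stop(sprintf("missing '%s' annotation for inhibitor(s): %s", col,
                   paste(inhibitors$id[bad], collapse = ",")), call. = FALSE)
  }
  feature_table(data.frame(primary_target = inhibitors$primary_target,
                           structure_cluster = inhibitors$structure_cluster,
                           stringsAsFactors = FALSE),
                inhibitors$id,
                c(primary_target = "nominal", structure_cluster = "nominal"),
                c(primary_target = "PT", structure_cluster = "MS"))
}

#' Chemical/geometric feature tables over a molecule list
#'
#' @param mols named list of `molgraph` objects.
#' @param which descriptor subset for the chemical table.
#' @return a `feature_table` (group `CF` or `GF`).
#' @export
chemical_feature_table <- function(mols, which = CHEMICAL_DESCRIPTOR_NAMES) {
  vals <- as.data.frame(t(vapply(mols, chemical_descriptors,
                                 numeric(length(which)), which = which)))
  names(vals) <- paste0("cf_", which)
  rownames(vals) <- NULL
  feature_table(vals, names(mols),
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("CF", ncol(vals)), names(vals)))
}

#' @rdname chemical_feature_table
#' @export
geometric_feature_table <- function(mols) {
  vals <- as.data.frame(t(vapply(mols, geometric_descriptors, numeric(5))))
  names(vals) <- paste0("gf_", c("diameter", "length2d", "width2d",
                                 "lw_ratio", "n_atoms"))
  rownames(vals) <- NULL
  feature_table(vals, names(mols),
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("GF", ncol(vals)), names(vals)))
}
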