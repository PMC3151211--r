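# Maximal frequent free trees: unrooted, connected, acyclic substructures
# of molecular graphs, matched by element symbol and bond order, with
# support counted once per molecule via subgraph isomorphism.
#
# Mining internals carry patterns as (elements, 3-column bond matrix,
# supporting-molecule set); anti-monotonicity lets every extension be
# counted on its parent's supporters only.

as_bond_matrix <- function(bonds) {
  if (is.matrix(bonds)) return(bonds)
  cbind(from = as.integer(bonds$from), to = as.integer(bonds$to),
        order = as.numeric(bonds$order))
}

#' Construct a free-tree pattern
#'
#' @param elements element symbols per pattern vertex.
#' @param bonds data frame or matrix `from, to, order`; must form a tree.
#' @param support optional per-molecule support count.
#' @return an object of class `free_tree` with its canonical form attached.
#' @export
free_tree <- function(elements, bonds, support = NA_integer_) {
  bm <- as_bond_matrix(bonds)
  n <- length(elements)
  assert_that(nrow(bm) == n - 1L, "a tree on n vertices has n-1 edges")
  g <- molgraph(elements,
                data.frame(from = bm[, 1], to = bm[, 2], order = bm[, 3]),
                require_connected = TRUE)  # connectivity + n-1 edges => acyclic
  structure(list(elements = as.character(elements), bonds = g$bonds,
                 size = n, support = as.integer(support),
                 canonical = tree_canonical(g$elements, bm)),
            class = "free_tree")
}

#' @export
print.free_tree <- function(x, ...) {
  cat(sprintf("free_tree: %d atoms, support %s, %s\n", x$size,
              ifelse(is.na(x$support), "?", x$support), x$canonical))
  invisible(x)
}

tree_adjacency <- function(elements, bonds) {
  bm <- as_bond_matrix(bonds)
  n <- length(elements)
  adj <- rep(list(integer(0)), n); ord <- rep(list(numeric(0)), n)
  for (b in seq_len(nrow(bm))) {
    i <- bm[b, 1]; j <- bm[b, 2]; o <- bm[b, 3]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nbr = adj, order = ord)
}

# centroid(s) of a tree: repeatedly strip leaves; 1 or 2 vertices remain
tree_centroids <- function(n, adj) {
  if (n == 1L) return(1L)
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  remaining <- n
  leaves <- which(deg <= 1L)
  while (remaining > 2L) {
    nxt <- integer(0)
    for (v in leaves) {
      alive[v] <- FALSE; remaining <- remaining - 1L
      for (w in adj[[v]]) if (alive[w]) {
        deg[w] <- deg[w] - 1L
        if (deg[w] == 1L) nxt <- c(nxt, w)
      }
    }
    leaves <- nxt
  }
  which(alive)
}

#' Canonical string of a labelled free tree
#'
#' Isomorphic trees map to the same string: the tree is rooted at each of
#' its (at most two) centroids, encoded by recursively sorting child
#' encodings, and the lexicographically smaller result is taken.
#'
#' @param elements element symbols per vertex.
#' @param bonds tree edges: data frame or matrix `from, to, order`.
#' @return character canonical form.
#' @export
tree_canonical <- function(elements, bonds) {
  n <- length(elements)
  if (n == 1L) return(elements[1])
  ad <- tree_adjacency(elements, bonds)
  enc <- function(v, parent) {
    kids <- ad$nbr[[v]]; ords <- ad$order[[v]]
    keep <- kids != parent
    kids <- kids[keep]; ords <- ords[keep]
    if (length(kids) == 0L) return(elements[v])
    sub <- sort(vapply(seq_along(kids), function(k)
      paste0(format(ords[k]), enc(kids[k], v)), ""))
    paste0(elements[v], "(", paste(sub, collapse = ","), ")")
  }
  min(vapply(tree_centroids(n, ad$nbr), function(r) enc(r, 0L), ""))
}

#' Is a free tree contained in a molecular graph?
#'
#' Backtracking search for an injective mapping of pattern vertices to
#' molecule atoms preserving element symbols and bond orders (the pattern
#' edges must be molecule bonds; the image may carry extra bonds, so a
#' tree can match inside a ring).
#'
#' @param tree a `free_tree` (or list with `elements` and `bonds`).
#' @param g a `molgraph`.
#' @return logical.
#' @export
tree_in_graph <- function(tree, g) {
  tree_in_graph_adj(tree$elements, as_bond_matrix(tree$bonds),
                    g$elements, mol_adjacency(g))
}

tree_in_graph_adj <- function(pel, pbonds, gel, gad) {
  np <- length(pel); ng <- length(gel)
  if (np > ng) return(FALSE)
  pad <- tree_adjacency(pel, pbonds)
  # visit pattern vertices in DFS order so each new vertex attaches to a
  # mapped parent
  order <- integer(np); parent <- integer(np); pord <- numeric(np)
  seen <- logical(np)
  stack <- 1L; seen[1] <- TRUE; k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; order[k] <- v
    for (idx in seq_along(pad$nbr[[v]])) {
      w <- pad$nbr[[v]][idx]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v; pord[w] <- pad$order[[v]][idx]
        stack <- c(stack, w)
      }
    }
  }
  map <- integer(np); used <- logical(ng)
  match_from <- function(step) {
    if (step > np) return(TRUE)
    v <- order[step]
    if (step == 1L) {
      for (a in seq_len(ng)) {
        if (!used[a] && gel[a] == pel[v]) {
          map[v] <<- a; used[a] <<- TRUE
          if (match_from(step + 1L)) return(TRUE)
          used[a] <<- FALSE
        }
      }
    } else {
      pa <- map[parent[v]]
      nbrs <- gad$nbr[[pa]]; ords <- gad$order[[pa]]
      for (idx in seq_along(nbrs)) {
        a <- nbrs[idx]
        if (!used[a] && ords[idx] == pord[v] && gel[a] == pel[v]) {
          map[v] <<- a; used[a] <<- TRUE
          if (match_from(step + 1L)) return(TRUE)
          used[a] <<- FALSE
        }
      }
    }
    FALSE
  }
  match_from(1L)
}

#' Mine (maximal) frequent free trees from molecular graphs
#'
#' Levelwise pattern growth: frequent single atoms are extended one
#' labelled leaf at a time, duplicates are removed by canonical form, and
#' support is counted once per molecule by subgraph isomorphism (restricted
#' to the parent pattern's supporting molecules). With `border_only` the
#' result keeps only border elements — frequent trees with no frequent
#' proper super-tree.
#'
#' @param graphs list of `molgraph` objects.
#' @param min_freq minimum frequency as a fraction of molecules (default
#'   0.10); the support threshold is `ceiling(min_freq * length(graphs))`.
#' @param border_only return only maximal patterns (default TRUE).
#' @param max_atoms largest pattern size grown (default 8).
#' @return list of `free_tree` objects with supports, sorted by canonical
#'   form.
#' @export
mine_free_trees <- function(graphs, min_freq = 0.10, border_only = TRUE,
                            max_atoms = 8L) {
  assert_that(min_freq > 0 && min_freq <= 1, "min_freq must be in (0, 1]")
  if (length(graphs) == 0L) return(list())
  thr <- ceiling(min_freq * length(graphs))
  gels <- lapply(graphs, `[[`, "elements")
  gads <- lapply(graphs, mol_adjacency)
  count_support <- function(pel, pbonds, candidates) {
    candidates[vapply(candidates, function(gi)
      tree_in_graph_adj(pel, pbonds, gels[[gi]], gads[[gi]]), logical(1))]
  }
  vertex_labels <- sort(unique(unlist(gels)))
  edge_labels <- sort(unique(unlist(lapply(graphs, function(g) g$bonds$order))))
  # labelled-edge triples occurring anywhere: extensions outside this set
  # cannot match and are skipped
  seen_triples <- unique(unlist(lapply(graphs, function(g) {
    if (nrow(g$bonds) == 0L) return(character(0))
    e1 <- g$elements[g$bonds$from]; e2 <- g$elements[g$bonds$to]
    c(paste(e1, e2, g$bonds$order), paste(e2, e1, g$bonds$order))
  })))
  empty_bonds <- cbind(from = integer(0), to = integer(0), order = numeric(0))
  level <- list()
  for (el in vertex_labels) {
    supp <- count_support(el, empty_bonds, seq_along(graphs))
    if (length(supp) >= thr)
      level[[el]] <- list(elements = el, bonds = empty_bonds,
                          supporters = supp, canonical = el)
  }
  all_frequent <- level
  size <- 1L
  while (length(level) > 0L && size < max_atoms) {
    nxt <- list()
    tried <- new.env(parent = emptyenv())
    for (tr in level) {
      ns <- length(tr$elements)
      for (v in seq_len(ns)) for (el in vertex_labels)
        for (eo in edge_labels) {
          if (!(paste(tr$elements[v], el, eo) %in% seen_triples)) next
          cel <- c(tr$elements, el)
          cbonds <- rbind(tr$bonds, c(v, ns + 1L, eo))
          canon <- tree_canonical(cel, cbonds)
          if (!is.null(tried[[canon]])) next
          tried[[canon]] <- TRUE
          supp <- count_support(cel, cbonds, tr$supporters)
          if (length(supp) >= thr)
            nxt[[canon]] <- list(elements = cel, bonds = cbonds,
                                 supporters = supp, canonical = canon)
        }
    }
    all_frequent <- c(all_frequent, nxt)
    level <- nxt
    size <- size + 1L
  }
  trees <- all_frequent
  if (border_only && length(trees) > 1L) {
    sizes <- vapply(trees, function(t) length(t$elements), 0L)
    keep <- rep(TRUE, length(trees))
    for (i in seq_along(trees)) {
      for (j in seq_along(trees)) {
        if (sizes[i] < sizes[j] &&
            tree_in_graph_adj(trees[[i]]$elements, trees[[i]]$bonds,
                              trees[[j]]$elements,
                              tree_adjacency(trees[[j]]$elements,
                                             trees[[j]]$bonds))) {
          keep[i] <- FALSE; break
        }
      }
    }
    trees <- trees[keep]
  }
  trees <- trees[order(vapply(trees, `[[`, "", "canonical"))]
  unname(lapply(trees, function(t)
    free_tree(t$elements, t$bonds, support = length(t$supporters))))
}

# containment between two trees: a tree is a graph, reuse the matcher
tree_in_tree <- function(small, big) {
  tree_in_graph_adj(small$elements, as_bond_matrix(small$bonds),
                    big$elements,
                    tree_adjacency(big$elements, big$bonds))
}

#' Free-tree presence features
#'
#' One 0/1 numeric column per mined pattern (group `FTs`).
#'
#' @param patterns list of `free_tree` objects.
#' @param mols named list of `molgraph` objects.
#' @return a `feature_table` over the molecule ids.
#' @export
freetree_features <- function(patterns, mols) {
  vals <- as.data.frame(lapply(patterns, function(tr)
    vapply(mols, function(g) as.integer(tree_in_graph(tr, g)), 0L)))
  names(vals) <- sprintf("ft_%03d", seq_along(patterns))
  if (length(patterns) == 0L)
    vals <- data.frame(row.names = seq_along(mols))
  rownames(vals) <- NULL
  feature_table(vals, names(mols),
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("FTs", ncol(vals)), names(vals)))
}
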