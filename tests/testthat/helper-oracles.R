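# Independent brute-force oracles used to validate the miners and the
# alignment scorer on small inputs, plus tiny fixture builders.

# --- frequent sequence patterns -------------------------------------------
# Enumerate every candidate pattern as a substring of some corpus sequence
# with <= max_wc interior positions wildcarded (any frequent pattern must
# match at least one sequence, so this enumeration is complete), then count
# support by sliding-window matching (no regex machinery).
oracle_patterns <- function(seqs, minsup, max_wc = 2L, min_size = 1L,
                            max_len = 10L) {
  match_one <- function(pat, s) {
    ps <- strsplit(pat, "")[[1]]; ss <- strsplit(s, "")[[1]]
    lp <- length(ps); ls <- length(ss)
    if (lp > ls) return(FALSE)
    for (off in 0:(ls - lp))
      if (all(ps == "." | ps == ss[(off + 1):(off + lp)])) return(TRUE)
    FALSE
  }
  cands <- character(0)
  for (s in seqs) {
    ss <- strsplit(s, "")[[1]]
    L <- length(ss)
    for (i in seq_len(L)) for (len in 1:min(max_len, L - i + 1)) {
      sub <- ss[i:(i + len - 1)]
      interior <- if (len > 2) 2:(len - 1) else integer(0)
      for (k in 0:min(max_wc, length(interior))) {
        # index into `interior` to dodge combn's scalar-as-sequence rule
        combos <- if (k == 0) list(integer(0)) else
          lapply(asplit(utils::combn(seq_along(interior), k), 2),
                 function(idx) interior[idx])
        for (wc in combos) {
          p <- sub; p[wc] <- "."
          cands <- c(cands, paste(p, collapse = ""))
        }
      }
    }
  }
  cands <- unique(cands)
  sup <- vapply(cands, function(p) sum(vapply(seqs, function(s)
    match_one(p, s), logical(1))), 0L)
  keep <- sup >= minsup & nchar(cands) >= min_size
  out <- data.frame(pattern = cands[keep], support = unname(sup[keep]),
                    stringsAsFactors = FALSE)
  out[order(nchar(out$pattern), out$pattern), ]
}

# --- global alignment ------------------------------------------------------
# Plain recursion over all monotone alignments (no DP table); feasible for
# lengths <= 6.
oracle_align <- function(a, b, score, gap) {
  as_ <- strsplit(a, "")[[1]]; bs <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L) return(j * gap)
    if (j == 0L) return(i * gap)
    max(rec(i - 1L, j - 1L) + score[as_[i], bs[j]],
        rec(i - 1L, j) + gap,
        rec(i, j - 1L) + gap)
  }
  rec(length(as_), length(bs))
}

# --- connected acyclic subgraphs ------------------------------------------
# All sub-trees of a molecular graph up to max_size vertices, grown by
# attaching one incident edge to a new vertex at a time (adding an edge to
# an in-set vertex would close a cycle). Returned as canonical strings;
# canonicalization itself is exercised separately by permutation tests.
oracle_subtree_canonicals <- function(g, max_size = 8L) {
  n <- length(g$elements)
  bonds <- g$bonds
  out <- new.env(parent = emptyenv())
  visited <- new.env(parent = emptyenv())
  grow <- function(vset, eset) {
    # dedup on the embedding, not the canonical form: distinct embeddings
    # of one form can extend to different supersets
    emb <- paste(c(vset, ";", eset), collapse = ",")
    if (!is.null(visited[[emb]])) return(invisible())
    visited[[emb]] <- TRUE
    key <- tree_canonical(g$elements[vset],
                          cbind(match(bonds$from[eset], vset),
                                match(bonds$to[eset], vset),
                                bonds$order[eset]))
    out[[key]] <- TRUE
    if (length(vset) >= max_size) return(invisible())
    for (e in seq_len(nrow(bonds))) {
      if (e %in% eset) next
      fu <- bonds$from[e] %in% vset; tu <- bonds$to[e] %in% vset
      if (fu && tu) next  # would close a cycle
      if (!fu && !tu) next
      newv <- if (fu) bonds$to[e] else bonds$from[e]
      grow(sort(c(vset, newv)), sort(c(eset, e)))
    }
  }
  for (v in seq_len(n)) grow(v, integer(0))
  ls(out)
}

# frequent canonicals over a molecule list at a support threshold
oracle_frequent_trees <- function(graphs, thr, max_size = 8L) {
  sets <- lapply(graphs, oracle_subtree_canonicals, max_size = max_size)
  tab <- table(unlist(lapply(sets, unique)))
  sort(names(tab)[tab >= thr])
}

# --- misc fixtures ---------------------------------------------------------
toy_subst <- function(letters, diag, off = 0, gap = -1) {
  s <- matrix(off, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(s) <- diag
  subst_matrix("custom", score = s, gap = gap)
}

# ethanol: C-C-O
ethanol_graph <- function() {
  molgraph(c("C", "C", "O"),
           data.frame(from = c(1, 2), to = c(2, 3), order = c(1, 1)))
}

# benzene (kekulized)
benzene_graph <- function() {
  molgraph(rep("C", 6),
           data.frame(from = 1:6, to = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
}

small_bundle <- function(m = 10L, n = 6L, signal = 1, seed = 7L) {
  generate_bundle(synth_spec(m = m, n = n, seq_len = 50L,
                             n_active_columns = 6L, n_anchor_columns = 3L,
                             signal = signal, seed = seed))
}
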