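# Frequent amino-acid sequence patterns with interior wildcards.
#
# Patterns are fixed-length contiguous motifs written as strings over the
# residue alphabet plus "." for a wildcard matching exactly one arbitrary
# residue. Wildcards are restricted to at most `max_wildcards` interior
# positions; leading/trailing wildcards carry no information and are never
# reported. Support is counted once per sequence.

WILDCARD <- "."

#' Does a sequence pattern occur in a sequence?
#'
#' The wildcard `.` matches exactly one arbitrary residue. Multiple
#' occurrences within one sequence count as a single match (support is
#' per-sequence, not per-occurrence).
#'
#' @param pattern pattern string over residues and `.`.
#' @param sequence amino-acid string.
#' @return logical.
#' @export
pattern_matches <- function(pattern, sequence) {
  grepl(pattern, sequence, perl = TRUE)
}

pattern_support <- function(pattern, seqs) sum(grepl(pattern, seqs, perl = TRUE))

n_wildcards <- function(p) nchar(p) - nchar(gsub(".", "", p, fixed = TRUE))

#' Mine frequent sequence patterns (levelwise search with pattern merging)
#'
#' A levelwise (APriori-style) search over fixed-length motifs: level-one
#' candidates are the single symbols, and two frequent length-k patterns
#' whose overlapping (k-1)-suffix/prefix agree merge into a length-(k+1)
#' candidate. Candidates exceeding the wildcard budget are discarded before
#' counting. Internally the search carries patterns with boundary wildcards
#' (they are needed for the merge step to reach every motif); the result
#' keeps only patterns whose first and last symbol are residues.
#'
#' @param seqs character vector of sequences (the corpus).
#' @param minsup minimum per-sequence support count (>= 1).
#' @param max_wildcards wildcard budget per pattern (default 2).
#' @param min_size minimum reported pattern length (default 3).
#' @param max_len maximum pattern length searched (default 10).
#' @return an object of class `pattern_set`: data frame `pattern`, `support`
#'   with attributes `minsup` and `corpus_size`.
#' @export
mine_frequent <- function(seqs, minsup, max_wildcards = 2L, min_size = 3L,
                          max_len = 10L) {
  assert_that(minsup >= 1, "minsup must be >= 1")
  assert_that(min_size >= 1, "min_size must be >= 1")
  if (length(seqs) == 0L || minsup > length(seqs))
    return(pattern_set(character(0), integer(0), minsup, length(seqs)))
  check_residues(seqs)
  alphabet <- sort(unique(unlist(strsplit(seqs, ""))))
  if (max_wildcards > 0L) alphabet <- c(alphabet, WILDCARD)
  frequent <- list()  # per level: named support vectors
  level <- vapply(alphabet, pattern_support, 0L, seqs = seqs)
  level <- level[level >= minsup]
  k <- 1L
  while (length(level) > 0L && k < max_len) {
    frequent[[k]] <- level
    pats <- names(level)
    # merge join: suffix(p) == prefix(q) on k-1 symbols
    suffix <- substring(pats, 2L)
    candidates <- character(0)
    by_prefix <- split(pats, substring(pats, 1L, k - 1L))
    if (k == 1L) {
      candidates <- as.vector(outer(pats, pats, paste0))
    } else {
      for (p in pats) {
        qs <- by_prefix[[substring(p, 2L)]]
        if (!is.null(qs))
          candidates <- c(candidates, paste0(p, substring(qs, k)))
      }
    }
    candidates <- unique(candidates)
    candidates <- candidates[vapply(candidates, n_wildcards, 0) <= max_wildcards]
    if (length(candidates) == 0L) break
    sup <- vapply(candidates, pattern_support, 0L, seqs = seqs)
    level <- sup[sup >= minsup]
    k <- k + 1L
  }
  if (length(level) > 0L && k <= max_len) frequent[[k]] <- level
  all_sup <- unlist(unname(frequent))
  if (is.null(all_sup)) all_sup <- integer(0)
  pats <- names(all_sup)
  keep <- nchar(pats) >= min_size &
    substring(pats, 1L, 1L) != WILDCARD &
    substring(pats, nchar(pats)) != WILDCARD
  pattern_set(pats[keep], unname(all_sup[keep]), minsup, length(seqs))
}

pattern_set <- function(patterns, support, minsup, corpus_size) {
  ord <- order(nchar(patterns), patterns)
  structure(data.frame(pattern = patterns[ord],
                       support = as.integer(support[ord]),
                       stringsAsFactors = FALSE),
            minsup = as.integer(minsup), corpus_size = as.integer(corpus_size),
            class = c("pattern_set", "data.frame"))
}

# is p a (not necessarily proper) sub-pattern of q: p matches inside q,
# with a wildcard in p matching anything in q (incl. q's own wildcards)
is_subpattern <- function(p, q) {
  lp <- nchar(p); lq <- nchar(q)
  if (lp > lq) return(FALSE)
  ps <- strsplit(p, "")[[1]]
  qs <- strsplit(q, "")[[1]]
  for (off in 0:(lq - lp)) {
    seg <- qs[(off + 1):(off + lp)]
    if (all(ps == WILDCARD | ps == seg)) return(TRUE)
  }
  FALSE
}

#' Reduce a pattern set to its border elements
#'
#' Border elements are the most specific patterns that are still frequent:
#' patterns with no proper super-pattern in the set. A pattern p is a
#' sub-pattern of q when p occurs contiguously inside q, treating a wildcard
#' in p as matching any symbol of q.
#'
#' @param ps a `pattern_set` (closed under the miner's notion of frequency).
#' @return a `pattern_set` containing only the maximal patterns.
#' @export
border_elements <- function(ps) {
  pats <- ps$pattern
  n <- length(pats)
  if (n <= 1L) return(ps)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is_subpattern(pats[i], pats[j])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pattern_set(pats[keep], ps$support[keep],
              attr(ps, "minsup"), attr(ps, "corpus_size"))
}

#' Frequent-pattern presence features
#'
#' One 0/1 numeric column per pattern (group `Apri`): 1 when the pattern
#' occurs in the kinase sequence.
#'
#' @param ps a `pattern_set` (typically border elements).
#' @param kinases data frame with `id` and `sequence`.
#' @return a `feature_table`.
#' @export
apriori_features <- function(ps, kinases) {
  pats <- ps$pattern
  vals <- as.data.frame(lapply(pats, function(p)
    as.integer(grepl(p, kinases$sequence, perl = TRUE))))
  cols <- paste0("apri_", gsub(".", "x", pats, fixed = TRUE))
  names(vals) <- make.unique(cols)
  if (length(pats) == 0L) vals <- data.frame(row.names = seq_len(nrow(kinases)))
  feature_table(vals, kinases$id,
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("Apri", ncol(vals)), names(vals)))
}
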