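# Global alignment scores, conserved-column detection, frame extraction and
# frame-restricted scoring with or without realignment.

#' Substitution scoring scheme
#'
#' Wraps a residue substitution table with a linear gap penalty (uniform
#' cost for gap opening and extension, applied per gap position). The
#' standard PAM120 and BLOSUM62 integer tables ship with Biostrings.
#'
#' @param name `"PAM120"`, `"BLOSUM62"`, or `"custom"` (then `score` is
#'   required).
#' @param score residue x residue integer matrix (symmetric, dimnames).
#' @param gap penalty added per gap position; must be <= 0. Defaults: -8
#'   for PAM120, -4 for BLOSUM62 (required for custom tables).
#' @return an object of class `subst_matrix`.
#' @export
subst_matrix <- function(name = c("PAM120", "BLOSUM62", "custom"),
                         score = NULL, gap = NULL) {
  name <- match.arg(name)
  if (name != "custom") {
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    full <- env[[name]]
    score <- full[AA_LETTERS, AA_LETTERS]
    gap <- gap %||% switch(name, PAM120 = -8, BLOSUM62 = -4)
  } else {
    assert_that(!is.null(score) && !is.null(gap),
                "custom scheme needs a score table and a gap penalty")
  }
  score <- as.matrix(score)
  assert_that(identical(rownames(score), colnames(score)) &&
              isTRUE(all.equal(score, t(score), check.attributes = FALSE)),
              "substitution table must be symmetric with matching dimnames")
  assert_that(gap <= 0, "gap penalty must be <= 0")
  structure(list(name = name, score = score, gap = as.numeric(gap)),
            class = "subst_matrix")
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat(sprintf("subst_matrix: %s over %d letters, gap %g per position\n",
              x$name, nrow(x$score), x$gap))
  invisible(x)
}

#' Read a substitution table in NCBI matrix text format
#'
#' @param path whitespace-separated table with a header row of residue
#'   letters; `#` lines are comments.
#' @param gap linear gap penalty (<= 0).
#' @return a `subst_matrix` (name `"custom"`).
#' @export
read_subst_matrix <- function(path, gap) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, row.names = 1)
  subst_matrix("custom", score = as.matrix(tab), gap = gap)
}

check_letters <- function(sm, seqs) {
  letters <- unique(unlist(strsplit(seqs, "")))
  bad <- setdiff(letters, rownames(sm$score))
  assert_that(length(bad) == 0L,
              sprintf("residue(s) absent from substitution table: %s",
                      paste(bad, collapse = ",")))
}

#' Optimal global alignment score (Needleman-Wunsch, linear gaps)
#'
#' Score of the optimal alignment of two sequences over their full length
#' under the scheme's substitution table and per-position gap penalty.
#' Symmetric in its sequence arguments.
#'
#' @param a,b non-empty sequences.
#' @param sm a `subst_matrix`.
#' @return numeric score.
#' @export
global_align_score <- function(a, b, sm) {
  assert_that(nchar(a) > 0 && nchar(b) > 0, "sequences must be non-empty")
  check_letters(sm, c(a, b))
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sm$score,
    gapOpening = 0, gapExtension = -sm$gap, scoreOnly = TRUE))
}

#' Find highly conserved MSA columns
#'
#' A column is conserved when a single residue letter (gaps excluded)
#' occurs in strictly more than the threshold number of rows. With neither
#' threshold given, the count defaults to `round(0.885 * nrow)`, the
#' fraction corresponding to the classic "more than 100 of 113" rule, so
#' alignments of any depth behave comparably.
#'
#' @param m an `msa`.
#' @param min_count absolute strict-threshold count (takes precedence).
#' @param min_frac fractional threshold of rows (default 100/113).
#' @return sorted integer vector of 1-based conserved column indices.
#' @export
conserved_columns <- function(m, min_count = NULL, min_frac = 100 / 113) {
  nrows <- length(m$ids)
  thr <- if (!is.null(min_count)) min_count else round_half_up(min_frac * nrows)
  assert_that(thr >= 1 && thr <= nrows,
              "conservation threshold must lie in [1, rows]")
  mat <- msa_matrix(m)
  hit <- vapply(seq_len(m$width), function(cc) {
    res <- mat[, cc]
    res <- res[res != "-"]
    length(res) > 0L && max(table(res)) > thr
  }, logical(1))
  which(hit)
}

#' Extract conserved frames around active-site columns
#'
#' Keeps the conserved columns that lie in the active center, spans a
#' window of `flank` columns on each side of every such column (clipped to
#' the MSA), and merges overlapping or adjacent windows into single frames.
#'
#' @param m an `msa`.
#' @param conserved conserved column indices (e.g. [conserved_columns()]).
#' @param active_columns active-center column indices.
#' @param flank window half-width in columns (default 5).
#' @return list of frames, each `list(start, end, conserved)`; disjoint and
#'   sorted. Empty when no conserved column is active.
#' @export
extract_frames <- function(m, conserved, active_columns, flank = 5L) {
  assert_that(flank >= 0, "flank must be >= 0")
  anchors <- sort(intersect(as.integer(conserved), as.integer(active_columns)))
  if (length(anchors) == 0L) return(list())
  start <- pmax(1L, anchors - as.integer(flank))
  end <- pmin(m$width, anchors + as.integer(flank))
  frames <- list()
  cur_s <- start[1]; cur_e <- end[1]; cur_c <- anchors[1]
  for (i in seq_along(anchors)[-1]) {
    if (start[i] <= cur_e + 1L) {  # overlap or adjacency: merge
      cur_e <- max(cur_e, end[i])
      cur_c <- c(cur_c, anchors[i])
    } else {
      frames[[length(frames) + 1L]] <- list(start = cur_s, end = cur_e,
                                            conserved = cur_c)
      cur_s <- start[i]; cur_e <- end[i]; cur_c <- anchors[i]
    }
  }
  frames[[length(frames) + 1L]] <- list(start = cur_s, end = cur_e,
                                        conserved = cur_c)
  frames
}

#' Conserved-frame pair score between two kinases
#'
#' Each frame is matched with the corresponding frame of the second
#' sequence and scored; frame scores are summed. Without realignment the
#' frames are scored column-wise as cut from the MSA: a residue-gap column
#' incurs the gap penalty, a gap-gap column scores 0. With realignment the
#' cut-out frame substrings are degapped and scored by their optimal global
#' alignment.
#'
#' @param m an `msa`.
#' @param frames frame list from [extract_frames()].
#' @param i,j MSA row ids (or 1-based row indices).
#' @param sm a `subst_matrix`.
#' @param realign logical (default FALSE).
#' @return numeric total score over all frames.
#' @export
frame_pair_score <- function(m, frames, i, j, sm, realign = FALSE) {
  row_of <- function(k) {
    if (is.character(k)) {
      idx <- match(k, m$ids)
      assert_that(!is.na(idx), sprintf("kinase '%s' absent from MSA", k))
      idx
    } else as.integer(k)
  }
  ri <- strsplit(m$rows[row_of(i)], "")[[1]]
  rj <- strsplit(m$rows[row_of(j)], "")[[1]]
  total <- 0
  for (fr in frames) {
    cols <- fr$start:fr$end
    a <- ri[cols]; b <- rj[cols]
    if (realign) {
      sa <- paste(a[a != "-"], collapse = "")
      sb <- paste(b[b != "-"], collapse = "")
      total <- total +
        if (nchar(sa) == 0L && nchar(sb) == 0L) 0
        else if (nchar(sa) == 0L) sm$gap * nchar(sb)
        else if (nchar(sb) == 0L) sm$gap * nchar(sa)
        else global_align_score(sa, sb, sm)
    } else {
      check_letters(sm, gsub("-", "", paste0(c(a, b), collapse = "")))
      for (k in seq_along(cols)) {
        total <- total +
          if (a[k] == "-" && b[k] == "-") 0
          else if (a[k] == "-" || b[k] == "-") sm$gap
          else sm$score[a[k], b[k]]
      }
    }
  }
  total
}

#' Pairwise alignment-score feature vectors
#'
#' Represents each kinase by its vector of alignment scores against every
#' reference kinase (the classic m-dimensional alignment profile). Mode
#' `glAli` scores full sequences globally; mode `locAli` scores the
#' conserved frames only (optionally realigned), following the field's
#' naming even though the frame score is MSA-restricted rather than a local
#' alignment.
#'
#' @param kinases data frame with `id`, `sequence`.
#' @param mode `"glAli"` or `"locAli"`.
#' @param sm a `subst_matrix`.
#' @param m an `msa` (required for `locAli`).
#' @param frames frame list (required for `locAli`).
#' @param realign realign cut-out frames before scoring (`locAli` only).
#' @return a `feature_table` with one numeric column per reference kinase.
#' @export
score_vector_features <- function(kinases, mode = c("glAli", "locAli"),
                                  sm, m = NULL, frames = NULL,
                                  realign = FALSE) {
  mode <- match.arg(mode)
  ids <- kinases$id
  nk <- length(ids)
  S <- matrix(0, nk, nk)
  if (mode == "glAli") {
    check_letters(sm, kinases$sequence)
    for (i in seq_len(nk)) for (j in i:nk) {
      S[i, j] <- S[j, i] <-
        global_align_score(kinases$sequence[i], kinases$sequence[j], sm)
    }
  } else {
    assert_that(!is.null(m) && !is.null(frames),
                "locAli mode needs the MSA and its frames")
    rows <- match(ids, m$ids)
    assert_that(!anyNA(rows), "kinase absent from MSA")
    for (i in seq_len(nk)) for (j in i:nk) {
      S[i, j] <- S[j, i] <-
        frame_pair_score(m, frames, rows[i], rows[j], sm, realign = realign)
    }
  }
  prefix <- if (mode == "glAli") "glali_" else "locali_"
  vals <- as.data.frame(S)
  names(vals) <- paste0(prefix, ids)
  feature_table(vals, ids,
                stats::setNames(rep("numeric", nk), names(vals)),
                stats::setNames(rep(mode, nk), names(vals)))
}
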