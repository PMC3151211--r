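# PROSITE-style pattern matching (supported subset).
#
# Supported elements, dash-separated: residue letters, x (any residue),
# [ABC] (alternatives), {ABC} (exclusions), each optionally repeated as
# e(n) or e(n,m); anchors < (N-terminus) and > (C-terminus); an optional
# trailing period. Anything else is rejected loudly.

prosite_to_regex <- function(pattern) {
  p <- trimws(pattern)
  p <- sub("\\.$", "", p)
  anchor_start <- startsWith(p, "<")
  if (anchor_start) p <- substring(p, 2L)
  anchor_end <- endsWith(p, ">")
  if (anchor_end) p <- substring(p, 1L, nchar(p) - 1L)
  toks <- strsplit(p, "-", fixed = TRUE)[[1]]
  assert_that(length(toks) > 0L && all(nzchar(toks)),
              sprintf("empty element in PROSITE pattern '%s'", pattern))
  one <- function(tok) {
    rep_re <- "\\((\\d+)(,(\\d+))?\\)$"
    reps <- ""
    m <- regexpr(rep_re, tok)
    if (m > 0) {
      spec <- regmatches(tok, m)
      tok <- substring(tok, 1L, m - 1L)
      nums <- regmatches(spec, gregexpr("\\d+", spec))[[1]]
      reps <- if (length(nums) == 2L) sprintf("{%s,%s}", nums[1], nums[2])
              else sprintf("{%s}", nums[1])
    }
    body <-
      if (tok == "x") "."
      else if (grepl("^[A-Z]$", tok) && tok %in% AA_LETTERS) tok
      else if (grepl("^\\[[A-Z]+\\]$", tok)) tok
      else if (grepl("^\\{[A-Z]+\\}$", tok))
        paste0("[^", substring(tok, 2L, nchar(tok) - 1L), "]")
      else stop(sprintf("unsupported PROSITE element '%s' in pattern '%s'",
                        tok, pattern), call. = FALSE)
    paste0(body, reps)
  }
  core <- paste0(vapply(toks, one, ""), collapse = "")
  paste0(if (anchor_start) "^" else "", core, if (anchor_end) "$" else "")
}

#' Match PROSITE-style patterns against sequences as 0/1 features
#'
#' @param patterns named character vector of PROSITE-syntax patterns (names
#'   become feature names; unnamed patterns are numbered).
#' @param kinases data frame with `id` and `sequence`.
#' @return a `feature_table` of 0/1 numeric columns, group `PRO`.
#' @export
prosite_features <- function(patterns, kinases) {
  ids <- names(patterns) %||% sprintf("PS%03d", seq_along(patterns))
  if (is.null(names(patterns))) names(patterns) <- ids
  ids[!nzchar(ids)] <- sprintf("PS%03d", which(!nzchar(ids)))
  regexes <- vapply(patterns, prosite_to_regex, "")
  vals <- as.data.frame(lapply(regexes, function(re)
    as.integer(grepl(re, kinases$sequence, perl = TRUE))))
  cols <- make.unique(paste0("pro_", ids))
  names(vals) <- cols
  if (length(patterns) == 0L)
    vals <- data.frame(row.names = seq_len(nrow(kinases)))
  feature_table(vals, kinases$id,
                stats::setNames(rep("numeric", ncol(vals)), names(vals)),
                stats::setNames(rep("PRO", ncol(vals)), names(vals)))
}

#' Read a PROSITE-style pattern file (`ID<TAB>pattern` per line)
#'
#' @param path text file; `#` lines are comments.
#' @return named character vector of patterns.
#' @export
read_prosite_patterns <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(parts) >= 2L),
              "each line must be 'ID<TAB>pattern'")
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}
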