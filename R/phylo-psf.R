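# Phylogeny-derived nominal features and position-specific (active-site)
# residue features.

#' Default physico-chemical residue class map
#'
#' Five classes over the 20 residues: hydrophobic (A V L I M C), aromatic
#' (F W Y), polar (S T N Q G P), positive (K R H), negative (D E). Used by
#' the abstract position-specific features; override with a residue->class
#' file for other groupings.
#'
#' @return named character vector, residue letter -> class label.
#' @export
default_classmap <- function() {
  cm <- c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
          I = "hydrophobic", M = "hydrophobic", C = "hydrophobic",
          F = "aromatic", W = "aromatic", Y = "aromatic",
          S = "polar", T = "polar", N = "polar", Q = "polar",
          G = "polar", P = "polar",
          K = "positive", R = "positive", H = "positive",
          D = "negative", E = "negative")
  check_classmap(cm)
}

check_classmap <- function(cm) {
  assert_that(setequal(names(cm), AA_LETTERS),
              "class map must cover exactly the 20 residues")
  cm
}

#' Read a residue class map from TSV (`residue<TAB>class` per line)
#'
#' @param path TSV file without header.
#' @return named character vector covering the 20 residues.
#' @export
read_classmap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  check_classmap(stats::setNames(df[[2]], df[[1]]))
}

#' Phylogeny nominal features (STTK class, kinase group, kinase family)
#'
#' One `STTK` column (Ser/Thr vs Tyr vs other) and two `PC` columns (the
#' phylogenetic group and family), all nominal. Unseen category labels are
#' accepted as new categories.
#'
#' @param kinases data frame with `id`, `sttk`, `group`, `family`.
#' @return a `feature_table`.
#' @export
phylo_features <- function(kinases) {
  for (col in c("sttk", "group", "family")) {
    bad <- is.na(kinases[[col]]) | !nzchar(kinases[[col]])
    if (any(bad))
      stop(sprintf("missing '%s' annotation for kinase(s): %s", col,
                   paste(kinases$id[bad], collapse = ",")), call. = FALSE)
  }
  feature_table(data.frame(sttk = kinases$sttk, group = kinases$group,
                           family = kinases$family,
                           stringsAsFactors = FALSE),
                kinases$id,
                c(sttk = "nominal", group = "nominal", family = "nominal"),
                c(sttk = "STTK", group = "PC", family = "PC"))
}

#' Position-specific active-site features from the MSA
#'
#' One nominal column per active-site MSA column: the residue the kinase
#' shows at that column (a gap `-` is its own category), or — in the
#' abstract variant — the residue's physico-chemical class.
#'
#' @param m an `msa`.
#' @param active_columns 1-based MSA column indices (within MSA width).
#' @param ids kinase ids to featurize (default: all MSA rows); each must be
#'   an MSA row.
#' @param abstract map residues through `classmap` (group becomes `abPSF`).
#' @param classmap residue -> class map (default [default_classmap()]).
#' @return a `feature_table`, group `PSF` or `abPSF`.
#' @export
position_specific_features <- function(m, active_columns, ids = NULL,
                                       abstract = FALSE,
                                       classmap = default_classmap()) {
  assert_that(all(active_columns >= 1 & active_columns <= m$width),
              "active columns outside MSA width")
  ids <- ids %||% m$ids
  missing <- setdiff(ids, m$ids)
  assert_that(length(missing) == 0L,
              sprintf("kinase(s) absent from MSA: %s",
                      paste(missing, collapse = ",")))
  mat <- msa_matrix(m)[match(ids, m$ids), , drop = FALSE]
  active_columns <- sort(unique(as.integer(active_columns)))
  vals <- as.data.frame(lapply(active_columns, function(cc) {
    res <- mat[, cc]
    if (abstract) ifelse(res == "-", "-", unname(classmap[res])) else res
  }), stringsAsFactors = FALSE)
  prefix <- if (abstract) "abpsf_" else "psf_"
  names(vals) <- paste0(prefix, active_columns)
  grp <- if (abstract) "abPSF" else "PSF"
  feature_table(vals, ids,
                stats::setNames(rep("nominal", ncol(vals)), names(vals)),
                stats::setNames(rep(grp, ncol(vals)), names(vals)))
}
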