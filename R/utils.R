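#' @keywords internal
"_PACKAGE"

# The 20 standard amino-acid one-letter codes.
AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

# Feature group tags admitted in feature tables (kinase groups then
# inhibitor groups, following the field's shorthand).
FEATURE_GROUPS <- c("STTK","PC","PRO","Apri","glAli","locAli","PSF","abPSF",
                    "PT","MS","FTs","KNN","CF","GF","P")

#' Round half away from zero
#'
#' Commercial-rounding used when converting mixed-case fractions to pair
#' counts (0.5 rounds up), so that 50% of 113 gives 57.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# validate a vector of sequences over the amino-acid alphabet
check_residues <- function(seqs, ids = names(seqs)) {
  for (i in seq_along(seqs)) {
    letters <- strsplit(seqs[[i]], "")[[1]]
    bad <- setdiff(unique(letters), AA_LETTERS)
    if (length(bad) > 0L) {
      stop(sprintf("illegal residue letter(s) %s in record '%s'",
                   paste(bad, collapse = ","),
                   if (is.null(ids)) i else ids[[i]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
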