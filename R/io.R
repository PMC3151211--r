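#' Read kinase sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id.
#' Sequences are validated against the 20-letter amino-acid alphabet.
#'
#' @param path FASTA file.
#' @return data frame with columns `id` and `sequence`, in file order.
#' @export
read_sequences <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop(sprintf(
                    "malformed FASTA '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(set) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  seqs <- as.character(set)
  assert_that(!anyDuplicated(ids), "duplicate sequence ids in FASTA")
  check_residues(seqs, ids)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path aligned FASTA; all rows must have equal length. Gaps are `-`.
#' @return an object of class `msa`: list with `ids` and `rows` (aligned
#'   strings) plus `width`.
#' @export
read_msa <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  assert_that(length(set) > 0L, "empty MSA")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  rows <- as.character(set)
  msa(ids, unname(rows))
}

#' Construct an MSA object
#'
#' @param ids unique row ids.
#' @param rows equal-length aligned sequences over residues and `-`.
#' @return an object of class `msa`.
#' @export
msa <- function(ids, rows) {
  assert_that(length(ids) == length(rows), "one id per row")
  assert_that(!anyDuplicated(ids), "MSA ids must be unique")
  w <- unique(nchar(rows))
  assert_that(length(w) == 1L, "MSA rows must have equal length")
  check_residues(gsub("-", "", rows), ids)
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 width = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", length(x$ids), x$width))
  invisible(x)
}

# character matrix view of an MSA (rows x columns)
msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, ""))
}

#' Read a binary kinase x inhibitor binding matrix from CSV
#'
#' Header row holds inhibitor ids; first column holds kinase ids; cells must
#' be 0 (no binding) or 1 (binding), with no missing entries.
#'
#' @param path CSV file.
#' @return integer matrix with kinase rownames and inhibitor colnames.
#' @export
read_binding_matrix <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  assert_that(ncol(df) >= 2L && nrow(df) >= 1L, "binding matrix CSV is empty")
  kin <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- kin
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
    v <- mat[i, j]
    if (is.na(v) || !(v %in% c("0", "1")))
      stop(sprintf("non-binary cell '%s' at kinase '%s', inhibitor '%s'",
                   v, rownames(mat)[i], colnames(mat)[j]), call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  check_binding_matrix(mat)
  mat
}

#' Validate a binding matrix
#'
#' @param mat integer matrix, dimnames required, entries 0/1.
#' @return the matrix, invisibly, after validation.
#' @export
check_binding_matrix <- function(mat) {
  assert_that(is.matrix(mat), "binding matrix must be a matrix")
  assert_that(!is.null(rownames(mat)) && !is.null(colnames(mat)),
              "binding matrix needs kinase rownames and inhibitor colnames")
  assert_that(!anyDuplicated(rownames(mat)) && !anyDuplicated(colnames(mat)),
              "binding matrix ids must be unique")
  assert_that(!anyNA(mat) && all(mat %in% c(0L, 1L)),
              "binding matrix entries must be 0/1 with no missing cells")
  invisible(mat)
}

#' Write a binding matrix as CSV
#'
#' @param mat binding matrix.
#' @param path output file.
#' @export
write_binding_matrix <- function(mat, path) {
  check_binding_matrix(mat)
  df <- data.frame(kinase = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read kinase annotations (TSV: id, sttk, group, family)
#'
#' @param path TSV with header `id sttk group family`.
#' @return data frame.
#' @export
read_kinase_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("id", "sttk", "group", "family")
  assert_that(all(need %in% names(df)),
              sprintf("kinase annotation TSV needs columns: %s",
                      paste(need, collapse = ", ")))
  df[, need]
}

#' Read inhibitor annotations (TSV: id, primary_target, structure_cluster)
#'
#' @param path TSV with header `id primary_target structure_cluster`.
#' @return data frame.
#' @export
read_inhibitor_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("id", "primary_target", "structure_cluster")
  assert_that(all(need %in% names(df)),
              sprintf("inhibitor annotation TSV needs columns: %s",
                      paste(need, collapse = ", ")))
  df[, need]
}

#' Read active-site MSA columns (one 1-based column index per line)
#'
#' @param path single-column TSV/text file of 1-based MSA column indices.
#' @return sorted integer vector.
#' @export
read_active_columns <- function(path) {
  v <- scan(path, what = integer(), quiet = TRUE, comment.char = "#")
  assert_that(all(v >= 1L), "active-site columns must be 1-based positive")
  sort(unique(as.integer(v)))
}

#' Assemble kinase-inhibitor pair instances
#'
#' Each kinase feature row is concatenated with each inhibitor feature row,
#' in row-major order (all inhibitors of kinase 1, then kinase 2, ...), and
#' labelled from the binding matrix. Pair ids are `kinaseId|inhibitorId`.
#'
#' @param kin_features `feature_table` covering every matrix kinase.
#' @param inh_features `feature_table` covering every matrix inhibitor.
#' @param matrix binding matrix.
#' @return an object of class `pair_table`: list with `kinase_id`,
#'   `inhibitor_id`, `label` (0/1 integer) and `features` (a
#'   `feature_table` over the pair ids).
#' @export
assemble_pairs <- function(kin_features, inh_features, matrix) {
  check_binding_matrix(matrix)
  kin_ids <- rownames(matrix)
  inh_ids <- colnames(matrix)
  miss_k <- setdiff(kin_ids, kin_features$ids)
  miss_i <- setdiff(inh_ids, inh_features$ids)
  assert_that(length(miss_k) == 0L,
              sprintf("kinases missing from feature table: %s",
                      paste(miss_k, collapse = ",")))
  assert_that(length(miss_i) == 0L,
              sprintf("inhibitors missing from feature table: %s",
                      paste(miss_i, collapse = ",")))
  m <- length(kin_ids); n <- length(inh_ids)
  krow <- rep(seq_len(m), each = n)
  irow <- rep(seq_len(n), times = m)
  kf <- ft_subset(kin_features, kin_ids)
  inf <- ft_subset(inh_features, inh_ids)
  vals <- cbind(kf$values[krow, , drop = FALSE],
                inf$values[irow, , drop = FALSE])
  pair_ids <- paste(kin_ids[krow], inh_ids[irow], sep = "|")
  feats <- feature_table(vals, pair_ids,
                         c(kf$types, inf$types), c(kf$groups, inf$groups),
                         c(kf$levels, inf$levels))
  structure(list(kinase_id = kin_ids[krow], inhibitor_id = inh_ids[irow],
                 label = as.integer(matrix[cbind(krow, irow)]),
                 features = feats),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("pair_table: %d pairs (%d binding), %d features\n",
              length(x$label), sum(x$label), ncol(x$features$values)))
  invisible(x)
}

#' Read a dataset bundle directory
#'
#' Expects the file layout written by [write_bundle()]: `sequences.fasta`,
#' `msa.fasta`, `kinase_annotations.tsv`, `active_columns.tsv`,
#' `inhibitors.smi` (or `.sdf`), `inhibitor_annotations.tsv`, `matrix.csv`.
#'
#' @param dir bundle directory.
#' @return an object of class `ki_bundle`.
#' @export
read_bundle <- function(dir) {
  seqs <- read_sequences(file.path(dir, "sequences.fasta"))
  ann <- read_kinase_annotations(file.path(dir, "kinase_annotations.tsv"))
  kin <- merge(seqs, ann, by = "id", sort = FALSE)
  assert_that(nrow(kin) == nrow(seqs), "annotation missing for some kinase")
  molfile <- file.path(dir, "inhibitors.smi")
  if (!file.exists(molfile)) molfile <- file.path(dir, "inhibitors.sdf")
  bundle(kinases = kin,
         msa = read_msa(file.path(dir, "msa.fasta")),
         active_columns = read_active_columns(file.path(dir, "active_columns.tsv")),
         molecules = read_molecules(molfile),
         inhibitors = read_inhibitor_annotations(
           file.path(dir, "inhibitor_annotations.tsv")),
         matrix = read_binding_matrix(file.path(dir, "matrix.csv")))
}

#' Construct a dataset bundle
#'
#' @param kinases data frame `id, sequence, sttk, group, family`.
#' @param msa an `msa` covering every kinase id.
#' @param active_columns 1-based MSA column indices of the active site.
#' @param molecules named list of `molgraph` objects (names = inhibitor ids).
#' @param inhibitors data frame `id, primary_target, structure_cluster`.
#' @param matrix binding matrix over the same ids.
#' @return an object of class `ki_bundle`.
#' @export
bundle <- function(kinases, msa, active_columns, molecules, inhibitors, matrix) {
  check_binding_matrix(matrix)
  assert_that(all(rownames(matrix) %in% kinases$id), "matrix kinase missing")
  assert_that(all(rownames(matrix) %in% msa$ids), "kinase missing from MSA")
  assert_that(all(colnames(matrix) %in% names(molecules)),
              "matrix inhibitor missing a structure")
  assert_that(all(colnames(matrix) %in% inhibitors$id),
              "matrix inhibitor missing annotation")
  assert_that(all(active_columns >= 1 & active_columns <= msa$width),
              "active columns outside MSA")
  structure(list(kinases = kinases, msa = msa,
                 active_columns = as.integer(active_columns),
                 molecules = molecules, inhibitors = inhibitors,
                 matrix = matrix),
            class = "ki_bundle")
}

#' @export
print.ki_bundle <- function(x, ...) {
  cat(sprintf("ki_bundle: %d kinases x %d inhibitors, %.1f%% binding\n",
              nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix)))
  invisible(x)
}
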