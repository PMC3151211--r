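#' Typed feature tables
#'
#' A `feature_table` is the common currency of the package: a data frame of
#' named features for a set of entities (kinases, inhibitors or pairs), in
#' which every column is declared `numeric` or `nominal` and carries a group
#' tag (`STTK`, `PC`, `PRO`, `Apri`, `glAli`, `locAli`, `PSF`, `abPSF`, `PT`,
#' `MS`, `FTs`, `KNN`, `CF`, `GF` or `P`). Nominal columns are stored as
#' character and carry an explicit category set, which the nominal-to-binary
#' encoder needs to produce a stable column layout.
#'
#' @param values data frame of feature values; row order defines entity order.
#' @param ids character vector of entity ids (unique), one per row.
#' @param types named character vector, one of `"numeric"`/`"nominal"` per
#'   column of `values`.
#' @param groups named character vector of group tags per column.
#' @param levels optional named list of category sets for nominal columns;
#'   defaults to the observed values.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, ids, types, groups, levels = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE, optional = TRUE)
  assert_that(length(ids) == nrow(values), "one id per row required")
  assert_that(!anyDuplicated(ids), "entity ids must be unique")
  assert_that(!anyDuplicated(names(values)), "column names must be unique")
  assert_that(all(names(values) %in% names(types)) &&
              all(names(values) %in% names(groups)),
              "every column needs a type and a group tag")
  types <- types[names(values)]
  groups <- groups[names(values)]
  assert_that(all(types %in% c("numeric", "nominal")),
              "types must be 'numeric' or 'nominal'")
  assert_that(all(groups %in% FEATURE_GROUPS),
              sprintf("unknown group tag(s): %s",
                      paste(setdiff(groups, FEATURE_GROUPS), collapse = ",")))
  lv <- list()
  for (cn in names(values)) {
    if (types[[cn]] == "nominal") {
      values[[cn]] <- as.character(values[[cn]])
      lv[[cn]] <- if (!is.null(levels) && !is.null(levels[[cn]]))
        as.character(levels[[cn]]) else sort(unique(values[[cn]]))
    } else {
      values[[cn]] <- as.numeric(values[[cn]])
    }
  }
  rownames(values) <- NULL
  structure(list(ids = as.character(ids), values = values,
                 types = types, groups = groups, levels = lv),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d entities x %d features\n",
              length(x$ids), ncol(x$values)))
  tab <- table(factor(x$groups, levels = unique(x$groups)))
  cat("  groups:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) c(length(x$ids), ncol(x$values))

#' Column-bind feature tables for the same entities
#'
#' @param ... feature tables sharing identical entity ids, in order.
#' @return a single `feature_table`.
#' @export
ft_bind <- function(...) {
  fts <- list(...)
  fts <- fts[!vapply(fts, is.null, logical(1))]
  assert_that(length(fts) > 0L, "nothing to bind")
  ids <- fts[[1]]$ids
  for (ft in fts) assert_that(identical(ft$ids, ids),
                              "feature tables must share entity ids")
  feature_table(do.call(cbind, lapply(fts, `[[`, "values")), ids,
                do.call(c, lapply(fts, `[[`, "types")),
                do.call(c, lapply(fts, `[[`, "groups")),
                do.call(c, lapply(fts, `[[`, "levels")))
}

#' Subset a feature table
#'
#' @param ft a `feature_table`.
#' @param ids entity ids to keep (default all), in the requested order.
#' @param groups group tags to keep (default all).
#' @return a `feature_table`.
#' @export
ft_subset <- function(ft, ids = NULL, groups = NULL) {
  ids <- ids %||% ft$ids
  miss <- setdiff(ids, ft$ids)
  assert_that(length(miss) == 0L,
              sprintf("ids absent from feature table: %s",
                      paste(miss, collapse = ",")))
  rows <- match(ids, ft$ids)
  keep <- if (is.null(groups)) names(ft$values) else
    names(ft$values)[ft$groups %in% groups]
  feature_table(ft$values[rows, keep, drop = FALSE], ids,
                ft$types[keep], ft$groups[keep], ft$levels[keep])
}

#' Write a feature table as CSV with a two-line header
#'
#' Line one holds `id` plus the column names; line two holds empty id cell
#' plus `type:group` declarations, keeping the nominal/numeric typing that
#' the classifier preprocessing needs explicit on disk.
#'
#' @param ft a `feature_table`.
#' @param path output file.
#' @export
write_feature_table <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  esc <- function(x) {
    x <- as.character(x)
    need <- grepl('[",\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  writeLines(paste(c("id", esc(names(ft$values))), collapse = ","), con)
  writeLines(paste(c("", paste0(ft$types, ":", ft$groups)), collapse = ","), con)
  vals <- ft$values
  for (cn in names(vals)) {
    vals[[cn]] <- if (ft$types[[cn]] == "numeric")
      formatC(vals[[cn]], format = "g", digits = 17) else esc(vals[[cn]])
  }
  body <- do.call(paste, c(list(esc(ft$ids)), vals, sep = ","))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV file with the two-line header.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 2,
                         colClasses = "character")
  cols <- as.character(hdr[1, -1])
  decl <- strsplit(as.character(hdr[2, -1]), ":", fixed = TRUE)
  types <- vapply(decl, `[`, "", 1)
  groups <- vapply(decl, `[`, "", 2)
  names(types) <- names(groups) <- cols
  body <- utils::read.csv(path, header = FALSE, skip = 2,
                          colClasses = "character",
                          col.names = c("id", cols), check.names = FALSE)
  vals <- body[, -1, drop = FALSE]
  for (cn in cols) if (types[[cn]] == "numeric") vals[[cn]] <- as.numeric(vals[[cn]])
  feature_table(vals, body$id, types, groups)
}
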