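# Molecular graphs: hydrogen-suppressed, undirected, atom/bond labelled.

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3)
ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                 F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
                 B = 10.81, H = 1.008)

#' Construct a molecular graph
#'
#' Heavy atoms only; hydrogens are implicit. Bond order 1, 2, 3 or 1.5
#' (aromatic). The attached-hydrogen count per atom is derived from standard
#' valences adjusted by formal charge unless given explicitly.
#'
#' @param elements character vector of element symbols.
#' @param bonds data frame / matrix with columns `from`, `to`, `order`; each
#'   undirected bond listed once, no self-loops.
#' @param charges integer formal charges per atom (default 0).
#' @param hcount optional explicit attached-H counts.
#' @param coords optional numeric matrix of 2D coordinates (n x 2).
#' @param require_connected error when the graph is disconnected (default
#'   TRUE; inhibitor structures must be single molecules).
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(elements, bonds, charges = NULL, hcount = NULL,
                     coords = NULL, require_connected = TRUE) {
  n <- length(elements)
  assert_that(n >= 1L, "molecule needs at least one atom")
  assert_that(all(elements %in% names(STANDARD_VALENCE)),
              sprintf("unsupported element(s): %s",
                      paste(setdiff(elements, names(STANDARD_VALENCE)),
                            collapse = ",")))
  charges <- as.integer(charges %||% rep(0L, n))
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    names(bonds)[1:3] <- c("from", "to", "order")
    bonds$from <- as.integer(bonds$from); bonds$to <- as.integer(bonds$to)
    bonds$order <- as.numeric(bonds$order)
    assert_that(all(bonds$from >= 1 & bonds$from <= n &
                    bonds$to >= 1 & bonds$to <= n), "bond endpoint out of range")
    assert_that(all(bonds$from != bonds$to), "self-loop bond")
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    assert_that(!anyDuplicated(key), "each bond must be listed once")
    assert_that(all(bonds$order %in% c(1, 2, 3, 1.5)),
                "bond order must be 1, 2, 3 or 1.5 (aromatic)")
  } else {
    bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  }
  if (is.null(hcount)) {
    bsum <- numeric(n)
    for (b in seq_len(nrow(bonds))) {
      bsum[bonds$from[b]] <- bsum[bonds$from[b]] + bonds$order[b]
      bsum[bonds$to[b]] <- bsum[bonds$to[b]] + bonds$order[b]
    }
    eff <- STANDARD_VALENCE[elements]
    eff <- ifelse(elements == "C", eff - abs(charges), eff + charges)
    hcount <- pmax(0L, round(eff - bsum))
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    assert_that(nrow(coords) == n && ncol(coords) == 2,
                "coords must be n x 2")
  }
  g <- structure(list(elements = as.character(elements), bonds = bonds,
                      charges = charges, hcount = as.integer(hcount),
                      coords = coords),
                 class = "molgraph")
  if (require_connected && n > 1L)
    assert_that(mol_is_connected(g), "molecular graph is disconnected")
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("molgraph: %d heavy atoms (%s), %d bonds%s\n",
              length(x$elements),
              paste(sort(unique(x$elements)), collapse = ""),
              nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 2D coords"))
  invisible(x)
}

# adjacency list: for each atom, data frame of (nbr, order)
mol_adjacency <- function(g) {
  n <- length(g$elements)
  adj <- rep(list(integer(0)), n)
  ord <- rep(list(numeric(0)), n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$from[b]; j <- g$bonds$to[b]; o <- g$bonds$order[b]
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nbr = adj, order = ord)
}

mol_is_connected <- function(g) {
  n <- length(g$elements)
  if (n <= 1L) return(TRUE)
  adj <- mol_adjacency(g)$nbr
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    new <- adj[[v]][!seen[adj[[v]]]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# all-pairs topological (bond-count) distances via BFS; Inf if unreachable
mol_distances <- function(g) {
  n <- length(g$elements)
  adj <- mol_adjacency(g)$nbr
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
    }
    D[s, ] <- d
  }
  D
}

# bonds that lie on no cycle (bridges), by removal+connectivity test;
# molecules are tiny so the quadratic approach is fine
mol_ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  ring <- logical(nb)
  for (b in seq_len(nb)) {
    g2 <- g
    g2$bonds <- g$bonds[-b, , drop = FALSE]
    # bond is in a ring iff its endpoints stay connected without it
    i <- g$bonds$from[b]; j <- g$bonds$to[b]
    adj <- mol_adjacency(g2)$nbr
    seen <- logical(length(g$elements)); seen[i] <- TRUE; queue <- i
    while (length(queue) && !seen[j]) {
      v <- queue[1]; queue <- queue[-1]
      new <- adj[[v]][!seen[adj[[v]]]]
      seen[new] <- TRUE; queue <- c(queue, new)
    }
    ring[b] <- seen[j]
  }
  ring
}

V2000_CHARGE <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L,
                  "5" = -1L, "6" = -2L, "7" = -3L)

# convert one ChemmineR SDF object to a molgraph
sdf_to_molgraph <- function(sdf, with_coords = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- if ("C6" %in% colnames(ab))
    V2000_CHARGE[as.character(ab[, "C6"])] else rep(0L, nrow(ab))
  # bond-free entries surface as a degenerate all-zero block
  if (!is.null(bb) && (ncol(bb) < 3L || all(bb == 0))) bb <- NULL
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(from = integer(), to = integer(), order = numeric())
  } else {
    ord <- as.numeric(bb[, 3])
    ord[ord == 4] <- 1.5  # V2000 aromatic code
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = ord)
  }
  coords <- if (with_coords) unname(ab[, c("C1", "C2"), drop = FALSE]) else NULL
  if (!is.null(coords) && all(coords == 0)) coords <- NULL
  molgraph(elements, bonds, charges = unname(charges), coords = coords)
}

#' Read inhibitor structures from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line (`SMILES[ whitespace id]`); ids
#' default to `mol<i>`. SDF 2D coordinates are kept when present. Every
#' molecule must parse and be connected. Parsing is delegated to
#' ChemmineR/OpenBabel; aromatic rings arrive kekulized.
#'
#' @param path `.smi`/`.smiles` or `.sdf` file.
#' @return named list of `molgraph` objects, in file order.
#' @export
read_molecules <- function(path) {
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(sprintf("package '%s' is required to parse molecule files", pkg),
           call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles", "txt")) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(structure(list(), names = character()))
    parts <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(parts, `[`, "", 1)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%d", i), "")
    names(smi) <- ids
    sdfs <- tryCatch(ChemmineR::smiles2sdf(smi),
                     error = function(e) stop(sprintf(
                       "failed to parse SMILES file '%s': %s",
                       path, conditionMessage(e)), call. = FALSE))
    # SMILES conversion lays molecules out; treat coords as absent
    out <- lapply(seq_along(ids), function(i)
      tryCatch(sdf_to_molgraph(sdfs[[i]], with_coords = FALSE),
               error = function(e) stop(sprintf(
                 "molecule %d ('%s'): %s", i, ids[i], conditionMessage(e)),
                 call. = FALSE)))
  } else {
    sdfs <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfs)
    ids[!nzchar(ids)] <- sprintf("mol%d", which(!nzchar(ids)))
    out <- lapply(seq_along(ids), function(i)
      tryCatch(sdf_to_molgraph(sdfs[[i]], with_coords = TRUE),
               error = function(e) stop(sprintf(
                 "molecule %d ('%s'): %s", i, ids[i], conditionMessage(e)),
                 call. = FALSE)))
  }
  assert_that(!anyDuplicated(ids), "duplicate molecule ids")
  names(out) <- ids
  out
}

#' Write molecular graphs as a SMILES file
#'
#' Only acyclic (and kekulized) graphs are supported; this is the writer the
#' synthetic-molecule generator uses. Branches are emitted depth-first from
#' atom 1.
#'
#' @param mols named list of `molgraph` objects.
#' @param path output `.smi` file (`SMILES<space>id` per line).
#' @export
write_smiles <- function(mols, path) {
  lines <- vapply(seq_along(mols), function(i)
    paste(molgraph_to_smiles(mols[[i]]), names(mols)[i]), "")
  writeLines(lines, path)
  invisible(path)
}

molgraph_to_smiles <- function(g) {
  n <- length(g$elements)
  ring <- mol_ring_bonds(g)
  assert_that(!any(ring), "SMILES writer supports acyclic molecules only")
  adj <- mol_adjacency(g)
  bond_sym <- function(o) switch(as.character(o), "1" = "", "2" = "=", "3" = "#",
                                 stop("unsupported bond order for SMILES"))
  atom_sym <- function(v) {
    el <- g$elements[v]
    if (g$charges[v] != 0) {
      sgn <- if (g$charges[v] > 0) "+" else "-"
      rep <- if (abs(g$charges[v]) > 1) abs(g$charges[v]) else ""
      hs <- if (g$hcount[v] > 0) paste0("H", if (g$hcount[v] > 1) g$hcount[v] else "") else ""
      paste0("[", el, hs, sgn, rep, "]")
    } else el
  }
  emit <- function(v, parent) {
    nbrs <- adj$nbr[[v]]; ords <- adj$order[[v]]
    keep <- nbrs != (parent %||% 0L)
    nbrs <- nbrs[keep]; ords <- ords[keep]
    parts <- character(0)
    for (k in seq_along(nbrs)) {
      sub <- paste0(bond_sym(ords[k]), emit(nbrs[k], v))
      parts <- c(parts, sub)
    }
    if (length(parts) == 0L) return(atom_sym(v))
    branches <- if (length(parts) > 1)
      paste0(vapply(parts[-length(parts)], function(p) paste0("(", p, ")"), ""),
             collapse = "") else ""
    paste0(atom_sym(v), branches, parts[length(parts)])
  }
  emit(1L, NULL)
}
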