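# Complex structure container and PDB input.
#
# A `complex_structure` is a list with:
#   atoms    - data.frame: key, chain, resno, insert, resid, aa, role,
#              elety, element, x, y, z (one row per heavy atom kept)
#   residues - data.frame: key, chain, resno, insert, resid, aa, role,
#              nonstandard (one row per residue, in file order)
#   antigen_chains / antibody_chains - character vectors
# Residue keys are "chain:resno:insert" (insert empty when absent).

residue_key <- function(chain, resno, insert) {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = ":")
}

guess_element <- function(elety, elesy = NULL) {
  known <- names(vdw_radii())
  ele <- rep(NA_character_, length(elety))
  if (!is.null(elesy)) {
    es <- toupper(trimws(elesy))
    ok <- !is.na(es) & es %in% known
    ele[ok] <- es[ok]
  }
  miss <- is.na(ele)
  if (any(miss)) {
    first <- toupper(substr(gsub("[0-9']", "", trimws(elety[miss])), 1, 1))
    ele[miss] <- first
  }
  ele
}

#' Load an antigen-antibody complex from a PDB file
#'
#' Reads the named chains only, keeping standard `ATOM` records: hetero
#' groups and waters are excluded, and where alternate conformations are
#' present only the first-listed conformer of each atom is kept. Residue
#' order follows file order.
#'
#' @param path path to a PDB-format file.
#' @param antigen_chains,antibody_chains character vectors of chain
#'   identifiers; the two sets must be nonempty and disjoint, and every named
#'   chain must occur in the file.
#' @return an object of class `complex_structure`.
#' @examples
#' cx <- make_complex(complex_recipe(seed = 1))
#' st <- load_complex(cx$path, cx$antigen_chains, cx$antibody_chains)
#' st
#' @export
load_complex <- function(path, antigen_chains, antibody_chains) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  antigen_chains <- unique(as.character(antigen_chains))
  antibody_chains <- unique(as.character(antibody_chains))
  if (length(antigen_chains) == 0 || length(antibody_chains) == 0)
    stop("antigen_chains and antibody_chains must both be nonempty")
  overlap <- intersect(antigen_chains, antibody_chains)
  if (length(overlap) > 0)
    stop("chain sets overlap: ", paste(overlap, collapse = ", "))

  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]

  wanted <- c(antigen_chains, antibody_chains)
  missing_chains <- setdiff(wanted, unique(at$chain))
  if (length(missing_chains) > 0)
    stop("chain(s) not present in file: ",
         paste(missing_chains, collapse = ", "))
  at <- at[at$chain %in% wanted, , drop = FALSE]

  # first-listed conformer: drop later duplicates of the same named atom
  key <- residue_key(at$chain, at$resno, at$insert)
  at <- at[!duplicated(paste(key, at$elety)), , drop = FALSE]
  if (nrow(at) == 0) stop("no residues left after filtering")

  key <- residue_key(at$chain, at$resno, at$insert)
  role <- ifelse(at$chain %in% antigen_chains, "antigen", "antibody")
  elesy <- if ("elesy" %in% names(at)) at$elesy else NULL

  atoms <- data.frame(
    key = key, chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid, aa = aa_three_to_one(at$resid), role = role,
    elety = trimws(at$elety), element = guess_element(at$elety, elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  new_complex_structure(atoms, antigen_chains, antibody_chains)
}

new_complex_structure <- function(atoms, antigen_chains, antibody_chains) {
  first <- !duplicated(atoms$key)
  residues <- data.frame(
    key = atoms$key[first], chain = atoms$chain[first],
    resno = atoms$resno[first], insert = atoms$insert[first],
    resid = atoms$resid[first], aa = atoms$aa[first],
    role = atoms$role[first],
    nonstandard = atoms$aa[first] == "X",
    stringsAsFactors = FALSE
  )
  if (any(residues$nonstandard))
    warning(sum(residues$nonstandard),
            " nonstandard residue(s); they are kept for geometry but",
            " contribute nothing to physicochemical lookups")
  structure(
    list(atoms = atoms, residues = residues,
         antigen_chains = antigen_chains,
         antibody_chains = antibody_chains),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("Antigen-antibody complex structure\n")
  cat("  antigen chains: ", paste(x$antigen_chains, collapse = ", "),
      " (", sum(x$residues$role == "antigen"), " residues)\n", sep = "")
  cat("  antibody chains: ", paste(x$antibody_chains, collapse = ", "),
      " (", sum(x$residues$role == "antibody"), " residues)\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

#' Representative point of a residue
#'
#' The unweighted arithmetic mean of the residue's atom coordinates.
#'
#' @param coords numeric matrix (atoms x 3) of atom coordinates.
#' @return numeric 3-vector.
#' @export
residue_point <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) == 0) stop("residue has no atoms")
  colMeans(coords)
}

#' Representative points of every residue in a structure
#'
#' @param structure a `complex_structure`.
#' @return numeric matrix (residues x 3), row names = residue keys, rows in
#'   residue (file) order.
#' @export
residue_points <- function(structure) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sums <- rowsum(xyz, group = a$key, reorder = FALSE)
  n <- as.vector(table(factor(a$key, levels = rownames(sums))))
  pts <- sums / n
  colnames(pts) <- c("x", "y", "z")
  pts[structure$residues$key, , drop = FALSE]
}

atom_coords <- function(structure, keys = NULL) {
  a <- structure$atoms
  if (!is.null(keys)) a <- a[a$key %in% keys, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
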