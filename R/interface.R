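# Surface calling, epitope/paratope assignment by SASA loss, unit patches.

#' Surface residues of a molecule
#'
#' A residue is on the surface when its isolated-molecule SASA exceeds the
#' threshold (strictly).
#'
#' @param sasa a `sasa_table`.
#' @param threshold SASA threshold in Angstrom^2 (default 1.0).
#' @return character vector of residue keys.
#' @export
surface_residues <- function(sasa, threshold = 1.0) {
  sasa$key[sasa$sasa_isolated > threshold]
}

#' Epitope and paratope assignment from SASA loss on binding
#'
#' Surface residues (isolated SASA > `surface_threshold`) that lose more
#' than `delta_threshold` of SASA when the complex forms are classified as
#' epitope on the antigen side and paratope on the antibody side.
#'
#' An empty epitope or paratope is returned, not an error; the annotation's
#' `empty` flag marks it so fingerprint stages can reject it explicitly.
#'
#' @param structure a `complex_structure`.
#' @param sasa the matching `sasa_table` from [compute_sasa()].
#' @param delta_threshold SASA-loss threshold in Angstrom^2 (default 1.0).
#' @param surface_threshold surface-calling threshold in Angstrom^2
#'   (default 1.0).
#' @return an `interface_annotation`: list with character-vector fields
#'   `surface_antigen`, `surface_antibody`, `epitope`, `paratope`, a named
#'   numeric `delta_sasa` over all surface residues, and logical `empty`.
#' @export
detect_epitope_paratope <- function(structure, sasa, delta_threshold = 1.0,
                                    surface_threshold = 1.0) {
  surf <- sasa$sasa_isolated > surface_threshold
  buried <- surf & (sasa$delta > delta_threshold)
  ann <- list(
    surface_antigen = sasa$key[surf & sasa$role == "antigen"],
    surface_antibody = sasa$key[surf & sasa$role == "antibody"],
    epitope = sasa$key[buried & sasa$role == "antigen"],
    paratope = sasa$key[buried & sasa$role == "antibody"],
    delta_sasa = stats::setNames(sasa$delta[surf], sasa$key[surf])
  )
  ann$empty <- length(ann$epitope) == 0 || length(ann$paratope) == 0
  class(ann) <- "interface_annotation"
  ann
}

#' @export
print.interface_annotation <- function(x, ...) {
  cat("Interface annotation\n")
  cat("  surface: ", length(x$surface_antigen), " antigen / ",
      length(x$surface_antibody), " antibody residues\n", sep = "")
  cat("  epitope: ", length(x$epitope), "  paratope: ",
      length(x$paratope), if (x$empty) "  [EMPTY INTERFACE]", "\n", sep = "")
  invisible(x)
}

#' Enumerate epitope unit patches
#'
#' A unit patch is an unordered triple of epitope surface residues whose
#' three pairwise representative-point distances are all within `cutoff`
#' (inclusive). Each patch carries the centroid of its three points.
#' Patches are sorted lexicographically by their residue keys.
#'
#' @param epitope_points numeric matrix (residues x 3) with residue keys as
#'   row names.
#' @param cutoff pairwise distance cutoff in Angstrom (default 4.0).
#' @return list with `keys` (n x 3 character matrix, keys sorted within each
#'   row) and `centroids` (n x 3 numeric matrix); zero-row matrices when no
#'   patch exists.
#' @export
unit_patches <- function(epitope_points, cutoff = 4.0) {
  keys <- rownames(epitope_points)
  n <- nrow(epitope_points)
  empty <- list(keys = matrix(character(0), 0, 3),
                centroids = matrix(numeric(0), 0, 3,
                                   dimnames = list(NULL, c("x", "y", "z"))))
  if (n < 3) return(empty)

  ord <- order(keys)
  pts <- epitope_points[ord, , drop = FALSE]
  keys <- keys[ord]
  d <- as.matrix(stats::dist(pts))
  close <- d <= cutoff

  rows_k <- list(); rows_c <- list(); m <- 0
  for (i in 1:(n - 2)) {
    js <- which(close[i, ] & seq_len(n) > i)
    if (length(js) < 2) next
    for (a in seq_len(length(js) - 1)) {
      j <- js[a]
      ks <- js[js > j & close[j, js]]
      for (k in ks) {
        m <- m + 1
        rows_k[[m]] <- keys[c(i, j, k)]
        rows_c[[m]] <- colMeans(pts[c(i, j, k), , drop = FALSE])
      }
    }
  }
  if (m == 0) return(empty)
  out <- list(keys = do.call(rbind, rows_k),
              centroids = do.call(rbind, rows_c))
  colnames(out$centroids) <- c("x", "y", "z")
  out
}

#' Write an interface annotation as TSV
#'
#' One row per surface residue with its role (`surface`, `epitope` or
#' `paratope`) and SASA loss.
#'
#' @param annotation an `interface_annotation`.
#' @param sasa the matching `sasa_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, sasa, path) {
  keys <- c(annotation$surface_antigen, annotation$surface_antibody)
  df <- as.data.frame(sasa)[match(keys, sasa$key),
                            c("key", "chain", "resno", "insert", "aa")]
  df$role <- ifelse(df$key %in% annotation$epitope, "epitope",
                    ifelse(df$key %in% annotation$paratope, "paratope",
                           "surface"))
  df$delta_sasa <- annotation$delta_sasa[df$key]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
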