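# Per-side protein fingerprints: an 80-bit cylinder-model structure block
# plus a 30-value shell-model physicochemical block, and the MLPD
# (multiplication of ligand and protein descriptors) cross-term.

new_fingerprint <- function(values, layout, side, coverage = NULL) {
  structure(values, layout = layout, side = side, coverage = coverage,
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("Fingerprint [", attr(x, "side"), "], length ", length(x), ", ",
      sum(x != 0), " nonzero\n", sep = "")
  lay <- attr(x, "layout")
  for (nm in names(lay))
    cat("  ", nm, ": positions ", min(lay[[nm]]), "-", max(lay[[nm]]),
        "\n", sep = "")
  if (!is.null(attr(x, "coverage")))
    cat("  cylinder coverage: ", format(attr(x, "coverage")), "\n", sep = "")
  invisible(x)
}

#' Cylinder-model grid parameters
#'
#' The default grid — 20 Angstrom rotating radius in 2 Angstrom pixels, 0-40
#' Angstrom along the interface axis in 5 Angstrom pixels — has 10 x 8 = 80
#' cells.
#'
#' @param radius rotating-plane radius, Angstrom.
#' @param r_pixel radial pixel, Angstrom.
#' @param z_min,z_max axial extent, Angstrom.
#' @param z_pixel axial pixel, Angstrom.
#' @param mode `"binary"` (cell occupied or not, default) or `"count"`
#'   (number of points per cell).
#' @return a `cylinder_params` list.
#' @export
cylinder_params <- function(radius = 20, r_pixel = 2, z_min = 0, z_max = 40,
                            z_pixel = 5, mode = c("binary", "count")) {
  mode <- match.arg(mode)
  nr <- radius / r_pixel
  nz <- (z_max - z_min) / z_pixel
  stopifnot(nr > 0, nz > 0, nr == round(nr), nz == round(nz))
  structure(list(radius = radius, r_pixel = r_pixel, z_min = z_min,
                 z_max = z_max, z_pixel = z_pixel, mode = mode,
                 nr = as.integer(nr), nz = as.integer(nz)),
            class = "cylinder_params")
}

#' Cylinder-model structure fingerprint
#'
#' Each point is mapped to cylindrical coordinates in the frame and binned
#' on the (radius x height) grid; cells are half-open, points with
#' `r >= radius` or `z` outside `[z_min, z_max)` are dropped. The vector is
#' height-major: cell `(r_bin, z_bin)` sits at position
#' `z_bin * (radius/r_pixel) + r_bin` (0-based). The fraction of input
#' points that landed inside the cylinder is attached as attribute
#' `coverage`.
#'
#' @param points numeric matrix (n x 3) of the side's points: antibody
#'   surface-residue points, or antigen unit-patch centroids.
#' @param frame an `interaction_frame` oriented toward the side being
#'   fingerprinted.
#' @param params a [cylinder_params()] list.
#' @return a `fingerprint` of length `nr * nz` (80 under defaults).
#' @export
structure_fingerprint <- function(points, frame, params = cylinder_params()) {
  points <- rbind(points)
  vec <- numeric(params$nr * params$nz)
  names(vec) <- paste0("cyl_z", rep(seq_len(params$nz) - 1,
                                    each = params$nr),
                       "_r", rep(seq_len(params$nr) - 1, params$nz))
  coverage <- NaN
  if (nrow(points) > 0) {
    cc <- cyl_coord(points, frame)
    inside <- cc$r < params$radius & cc$z >= params$z_min &
      cc$z < params$z_max
    coverage <- mean(inside)
    if (any(inside)) {
      r_bin <- floor(cc$r[inside] / params$r_pixel)
      z_bin <- floor((cc$z[inside] - params$z_min) / params$z_pixel)
      idx <- z_bin * params$nr + r_bin + 1
      counts <- tabulate(idx, nbins = length(vec))
      vec[] <- if (params$mode == "binary") as.numeric(counts > 0) else counts
    }
  }
  side <- if (identical(frame$orient, "paratope")) "antibody" else "antigen"
  new_fingerprint(vec, list(structure = seq_along(vec)), side,
                  coverage = coverage)
}

#' Shell-model parameters
#'
#' Defaults: 2 Angstrom shells out to 20 Angstrom (10 layers) and the three
#' AAindex scales of [aaindex_default()], giving a 30-value fingerprint.
#'
#' @param pixel shell thickness, Angstrom.
#' @param max_radius outer radius, Angstrom (multiple of `pixel`).
#' @param properties character vector of AAindex identifiers.
#' @return a `shell_params` list.
#' @export
shell_params <- function(pixel = 2, max_radius = 20,
                         properties = c("ARGP820101", "FAUJ880109",
                                        "FAUJ880108")) {
  nl <- max_radius / pixel
  stopifnot(pixel > 0, nl > 0, nl == round(nl), length(properties) >= 1)
  structure(list(pixel = pixel, max_radius = max_radius,
                 properties = properties, n_layers = as.integer(nl)),
            class = "shell_params")
}

#' Shell-model physicochemical fingerprint
#'
#' Items (residues on the antibody side, unit patches on the antigen side)
#' are assigned to concentric shells around the side's geometric center.
#' For each property the encoding is the per-layer arithmetic mean of the
#' item values; an item's value is the mean AAindex value of its amino
#' acids (a single residue, or the three residues of a patch). Nonstandard
#' residues have no AAindex value and contribute nothing. Empty layers
#' encode 0. The vector is property-major: property `p` occupies positions
#' `[n_layers * p, n_layers * (p+1))`.
#'
#' @param points numeric matrix (n x 3) of item positions.
#' @param aa list of character vectors: the amino acid(s) of each item.
#' @param center numeric 3-vector (Cp for the antibody side, Ce for the
#'   antigen side).
#' @param params a [shell_params()] list.
#' @param aaindex named list of AAindex scales, as [aaindex_default()].
#' @return a `fingerprint` of length `n_layers * length(properties)` (30
#'   under defaults).
#' @export
physchem_fingerprint <- function(points, aa, center, params = shell_params(),
                                 aaindex = aaindex_default()) {
  missing_props <- setdiff(params$properties, names(aaindex))
  if (length(missing_props) > 0)
    stop("unknown AAindex propert(ies): ",
         paste(missing_props, collapse = ", "))
  points <- rbind(points)
  nl <- params$n_layers
  vec <- numeric(nl * length(params$properties))
  names(vec) <- paste0("pc_", rep(params$properties, each = nl), "_L",
                       rep(seq_len(nl) - 1, length(params$properties)))
  n <- nrow(points)
  if (n > 0) {
    stopifnot(length(aa) == n)
    layer <- shell_index(points, center, params$pixel, params$max_radius)
    for (p in seq_along(params$properties)) {
      scale <- aaindex[[params$properties[p]]]
      val <- vapply(aa, function(a) {
        v <- scale[a]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1))
      for (l in seq_len(nl) - 1) {
        sel <- !is.na(layer) & layer == l & !is.na(val)
        if (any(sel)) vec[(p - 1) * nl + l + 1] <- mean(val[sel])
      }
    }
  }
  new_fingerprint(vec, list(physchem = seq_along(vec)), side = NULL)
}

#' Per-side protein fingerprint (structure + physicochemical blocks)
#'
#' Builds the full 110-length fingerprint of one side of the interface:
#' the 80-bit cylinder-model block followed by the 30-value shell-model
#' block.
#'
#' Antibody side: the frame is oriented toward the paratope; cylinder
#' points are the antibody surface-residue points (or paratope residues
#' only, see `antibody_points`); shell items are the same residues around
#' center Cp. Antigen side: the frame is oriented toward the epitope;
#' cylinder points are the epitope unit-patch centroids; shell items are
#' the unit patches (value = mean AAindex of the three residues) around
#' center Ce.
#'
#' @param side `"antibody"` or `"antigen"`.
#' @param structure a `complex_structure`.
#' @param annotation an `interface_annotation` with a nonempty interface.
#' @param cyl a [cylinder_params()] list.
#' @param shell a [shell_params()] list.
#' @param aaindex AAindex table, as [aaindex_default()].
#' @param antibody_points `"surface"` (all antibody surface residues,
#'   default) or `"paratope"` (paratope residues only).
#' @param antigen_centers `"residues"` (default: Ce and C from epitope
#'   residue points) or `"patches"` (recompute the antigen-side frame with
#'   unit-patch centroids standing in for the epitope points).
#' @param patch_cutoff unit-patch distance cutoff, Angstrom.
#' @return a `fingerprint` of length 110 with layout blocks `structure`
#'   and `physchem`.
#' @export
protein_fingerprint <- function(side = c("antibody", "antigen"), structure,
                                annotation, cyl = cylinder_params(),
                                shell = shell_params(),
                                aaindex = aaindex_default(),
                                antibody_points = c("surface", "paratope"),
                                antigen_centers = c("residues", "patches"),
                                patch_cutoff = 4.0) {
  side <- match.arg(side)
  antibody_points <- match.arg(antibody_points)
  antigen_centers <- match.arg(antigen_centers)
  if (annotation$empty)
    stop("empty interface: no ", side, " fingerprint can be computed")
  pts <- residue_points(structure)
  aa_of <- stats::setNames(structure$residues$aa, structure$residues$key)

  if (side == "antibody") {
    frame <- build_frame(annotation, pts, "paratope")
    keys <- if (antibody_points == "surface") annotation$surface_antibody
            else annotation$paratope
    cyl_pts <- pts[keys, , drop = FALSE]
    item_pts <- cyl_pts
    item_aa <- as.list(aa_of[keys])
    center <- frame$Cp
  } else {
    frame <- build_frame(annotation, pts, "epitope")
    patches <- unit_patches(pts[annotation$epitope, , drop = FALSE],
                            cutoff = patch_cutoff)
    if (nrow(patches$keys) == 0)
      warning("antigen side has no unit patches; ",
              "structure and physicochemical blocks are all zero")
    if (antigen_centers == "patches" && nrow(patches$keys) > 0) {
      Ce <- geometric_center(patches$centroids)
      Cp <- frame$Cp
      C <- geometric_center(rbind(patches$centroids,
                                  pts[annotation$paratope, , drop = FALSE]))
      axis <- Ce - Cp
      frame <- structure(list(Ce = Ce, Cp = Cp, C = C,
                              z_axis = axis / sqrt(sum(axis^2)),
                              orient = "epitope"),
                         class = "interaction_frame")
    }
    cyl_pts <- patches$centroids
    item_pts <- patches$centroids
    item_aa <- lapply(seq_len(nrow(patches$keys)),
                      function(i) unname(aa_of[patches$keys[i, ]]))
    center <- frame$Ce
  }

  fs <- structure_fingerprint(cyl_pts, frame, cyl)
  fp <- physchem_fingerprint(item_pts, item_aa, center, shell, aaindex)
  vec <- c(unclass(fs), unclass(fp))
  attributes(vec) <- list(names = c(names(fs), names(fp)))
  new_fingerprint(vec,
                  layout = list(structure = seq_along(fs),
                                physchem = length(fs) + seq_along(fp)),
                  side = side, coverage = attr(fs, "coverage"))
}

#' MLPD cross-term: flattened outer product of the two side fingerprints
#'
#' Position `i * length(fag) + j` (0-based) holds `fab[i] * fag[j]`
#' (0-based indices), i.e. the antibody index is the major one. Two
#' 110-length inputs give the conventional 12100-length proteochemometric
#' cross-term.
#'
#' @param fab,fag the antibody- and antigen-side fingerprints (equal
#'   lengths).
#' @return a `fingerprint` of length `length(fab) * length(fag)`.
#' @export
mlpd_cross_term <- function(fab, fag) {
  if (length(fab) != length(fag))
    stop("fingerprint lengths differ: ", length(fab), " vs ", length(fag))
  vec <- as.vector(t(outer(as.numeric(fab), as.numeric(fag))))
  names(vec) <- paste0("mlpd_", rep(seq_along(fab) - 1, each = length(fag)),
                       "_", rep(seq_along(fag) - 1, length(fab)))
  new_fingerprint(vec, list(mlpd = seq_along(vec)), side = "cross")
}

#' Write fingerprints as a TSV feature table
#'
#' @param fps named list (complex id -> `fingerprint`); all must share one
#'   layout.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(fps, path) {
  mat <- do.call(rbind, lapply(fps, as.numeric))
  colnames(mat) <- names(fps[[1]])
  df <- data.frame(complex_id = names(fps), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
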