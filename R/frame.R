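# Interaction interface coordinate system: epitope/paratope centers, the
# oriented interface axis, cylindrical coordinates, radial shell layers.

#' Geometric center (componentwise mean) of a point set
#'
#' @param points numeric matrix (n x 3) or a single 3-vector.
#' @return numeric 3-vector.
#' @export
geometric_center <- function(points) {
  points <- rbind(points)
  if (nrow(points) == 0) stop("no points")
  colMeans(points)
}

#' Build the interaction coordinate frame
#'
#' `Ce` is the geometric center of the epitope residue points, `Cp` of the
#' paratope points, and `C` of their union (all interface residues). The
#' interface axis is the unit vector along `Cp - Ce`, with its sign chosen
#' so that it points toward the requested side; the virtual interface plane
#' passes through `C` with this axis as its normal.
#'
#' @param annotation an `interface_annotation` with nonempty epitope and
#'   paratope.
#' @param points numeric matrix of residue representative points with
#'   residue keys as row names (must cover all epitope/paratope keys).
#' @param orient_toward `"paratope"` (antibody-side fingerprints) or
#'   `"epitope"` (antigen side).
#' @return an `interaction_frame`: list with `Ce`, `Cp`, `C` (3-vectors,
#'   Angstrom), unit `z_axis`, and `orient`.
#' @export
build_frame <- function(annotation, points, orient_toward = c("paratope",
                                                              "epitope")) {
  orient_toward <- match.arg(orient_toward)
  if (annotation$empty)
    stop("empty epitope or paratope: no interface frame can be built")
  epi <- points[annotation$epitope, , drop = FALSE]
  par <- points[annotation$paratope, , drop = FALSE]
  Ce <- geometric_center(epi)
  Cp <- geometric_center(par)
  C <- geometric_center(rbind(epi, par))
  axis <- Cp - Ce
  len <- sqrt(sum(axis^2))
  if (len < 1e-6) stop("degenerate frame: |Cp - Ce| < 1e-6 A")
  z <- axis / len
  if (orient_toward == "epitope") z <- -z
  structure(list(Ce = Ce, Cp = Cp, C = C, z_axis = z,
                 orient = orient_toward),
            class = "interaction_frame")
}

#' @export
print.interaction_frame <- function(x, ...) {
  fmt <- function(v) sprintf("(%.2f, %.2f, %.2f)", v[1], v[2], v[3])
  cat("Interaction frame (z toward ", x$orient, ")\n", sep = "")
  cat("  Ce = ", fmt(x$Ce), "  Cp = ", fmt(x$Cp), "  C = ", fmt(x$C), "\n",
      sep = "")
  cat("  z  = ", fmt(x$z_axis), "\n", sep = "")
  invisible(x)
}

#' Cylindrical coordinates of points in an interaction frame
#'
#' Height `z` is the signed projection of `point - C` on the interface
#' axis; radius `r` is the distance from the axis. The angular coordinate
#' is deliberately discarded: the fingerprint's rotating plane sweeps all
#' angles.
#'
#' @param points numeric matrix (n x 3) or a 3-vector.
#' @param frame an `interaction_frame`.
#' @return data.frame with columns `r` (>= 0) and `z` (both Angstrom).
#' @export
cyl_coord <- function(points, frame) {
  points <- rbind(points)
  rel <- sweep(points, 2, frame$C)
  z <- as.vector(rel %*% frame$z_axis)
  radial <- rel - outer(z, frame$z_axis)
  data.frame(r = sqrt(rowSums(radial^2)), z = z)
}

#' Radial shell layer of points around a center
#'
#' Concentric shells of thickness `pixel` partition distances
#' `[0, max_radius)` into `max_radius / pixel` half-open layers
#' (0-based); distances at or beyond `max_radius` return `NA` (out of
#' range). Defaults give 10 layers of 2 Angstrom out to 20 Angstrom.
#'
#' @param points numeric matrix (n x 3) or a 3-vector.
#' @param center numeric 3-vector.
#' @param pixel shell thickness in Angstrom (default 2).
#' @param max_radius outer radius in Angstrom (default 20); must be a
#'   positive multiple of `pixel`.
#' @return integer vector of 0-based layer indices, `NA` when out of range.
#' @export
shell_index <- function(points, center, pixel = 2.0, max_radius = 20.0) {
  stopifnot(pixel > 0, max_radius > 0)
  points <- rbind(points)
  d <- sqrt(rowSums(sweep(points, 2, center)^2))
  layer <- floor(d / pixel)
  layer[d >= max_radius] <- NA_integer_
  as.integer(layer)
}

#' Serialize an interaction frame to JSON
#'
#' @param frame an `interaction_frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(
    list(Ce = unname(frame$Ce), Cp = unname(frame$Cp), C = unname(frame$C),
         z_axis = unname(frame$z_axis), orient = frame$orient),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
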