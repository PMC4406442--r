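# Solvent-accessible surface area by Shrake-Rupley sphere sampling.
#
# Sample points are generated once on a Fibonacci (golden-spiral) lattice
# and oriented along the principal axes of the atom cloud being processed,
# with an axis sign fixed by moments of the cloud itself. Because the
# lattice then co-rotates with the molecule, SASA values are exactly
# invariant under rigid motion (up to floating point), not merely up to
# sampling noise.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  y <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - y^2))
  theta <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(theta), y, r * sin(theta))
}

# Rotation that maps the canonical frame onto the cloud's principal axes.
# Sign convention: third moment along each axis, falling back to an
# index-weighted projection for (near-)symmetric clouds; both quantities
# co-rotate with the cloud, so the returned frame does too.
principal_frame <- function(xyz) {
  if (nrow(xyz) < 2) return(diag(3))
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors
  for (k in 1:3) {
    proj <- xc %*% ev[, k]
    s <- sum(proj^3)
    if (abs(s) < 1e-9) s <- sum(proj * seq_along(proj))
    if (s < 0) ev[, k] <- -ev[, k]
  }
  # enforce a right-handed frame so this is a pure rotation
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  ev
}

element_radii <- function(elements) {
  tab <- vdw_radii()
  r <- tab[elements]
  if (anyNA(r)) {
    unknown <- unique(elements[is.na(r)])
    warning("no van der Waals radius for element(s) ",
            paste(unknown, collapse = ", "), "; using 1.8 A")
    r[is.na(r)] <- 1.8
  }
  unname(r)
}

# Per-atom SASA for one atom set. Returns numeric vector (A^2).
# `frame` fixes the sample-lattice orientation; passing the same frame to
# the complex and isolated runs makes per-point accessibility comparable,
# so removing the partner can only ever free sample points (exact burial
# non-negativity).
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960,
                          frame = principal_frame(xyz)) {
  n <- nrow(xyz)
  if (n == 0) return(numeric(0))
  sphere <- fibonacci_sphere(n_points) %*% t(frame)
  rp <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rp[i] + rp)^2 & d2 > 0)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rp[i]^2
      next
    }
    pts <- sphere * rp[i]
    pts <- cbind(pts[, 1] + xyz[i, 1], pts[, 2] + xyz[i, 2],
                 pts[, 3] + xyz[i, 3])
    acc <- rep(TRUE, n_points)
    for (j in nb[order(d2[nb])]) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 > rp[j]^2)
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rp[i]^2 * mean(acc)
  }
  out
}

#' Per-residue SASA in the complex and in each isolated molecule
#'
#' Computes Shrake-Rupley solvent-accessible surface area for every atom,
#' once with all chains present (`sasa_complex`) and once per molecule with
#' the partner removed (`sasa_isolated`: antigen chains alone, antibody
#' chains alone), then sums atoms within each residue. Identical sampling
#' settings are used for both runs, so the burial
#' `delta = sasa_isolated - sasa_complex` is internally consistent.
#'
#' @param structure a `complex_structure`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return a `sasa_table`: data.frame with one row per residue and columns
#'   `key`, `chain`, `resno`, `insert`, `aa`, `role`, `sasa_complex`,
#'   `sasa_isolated`, `delta` (Angstrom^2).
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- element_radii(a$element)

  frame <- principal_frame(xyz)
  atom_cx <- shrake_rupley(xyz, radii, probe_radius, n_points, frame)
  atom_iso <- numeric(nrow(a))
  for (side in c("antigen", "antibody")) {
    idx <- which(a$role == side)
    atom_iso[idx] <- shrake_rupley(xyz[idx, , drop = FALSE], radii[idx],
                                   probe_radius, n_points, frame)
  }

  keyf <- factor(a$key, levels = structure$residues$key)
  res <- structure$residues
  out <- data.frame(
    key = res$key, chain = res$chain, resno = res$resno,
    insert = res$insert, aa = res$aa, role = res$role,
    sasa_complex = as.vector(tapply(atom_cx, keyf, sum)),
    sasa_isolated = as.vector(tapply(atom_iso, keyf, sum)),
    stringsAsFactors = FALSE
  )
  out$delta <- out$sasa_isolated - out$sasa_complex
  class(out) <- c("sasa_table", "data.frame")
  out
}

#' Write a SASA table as TSV
#'
#' @param sasa a `sasa_table` from [compute_sasa()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(sasa, path) {
  utils::write.table(as.data.frame(sasa), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
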