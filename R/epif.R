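# Epitope-paratope interaction fingerprint (EPIF): 15 interaction bits per
# epitope residue, aggregated over 10 radial shells around the interface
# center into a 150-bit vector.

#' Names and pairing of the 15 per-residue interaction bits
#'
#' Bit 1 (`any`) flags any atomic contact. Bits 2-13 are six
#' (type, strength) pairs — backbone, sidechain, polar, hydrophobic,
#' aromatic, charged — where the strength bit can only be set when its type
#' bit is. Bits 14-15 flag contact with a paratope residue bearing a
#' side-chain hydrogen-bond donor / acceptor (presence only, no strength
#' bit).
#'
#' @return character vector of the 15 bit names, in order.
#' @export
interaction_bit_names <- function() {
  c("any",
    "backbone_e", "backbone_s", "sidechain_e", "sidechain_s",
    "polar_e", "polar_s", "hydrophobic_e", "hydrophobic_s",
    "aromatic_e", "aromatic_s", "charged_e", "charged_s",
    "hbond_donor", "hbond_acceptor")
}

#' EPIF parameters
#'
#' @param distance_cutoff atom-atom contact cutoff, Angstrom (default 4).
#' @param count_cutoff_charged contacting-residue count needed for the
#'   charged strength bit (default 1; electrostatics are strong enough that
#'   one salt-bridge partner counts).
#' @param count_cutoff_other count needed for the other five strength bits
#'   (default 4, the median per-residue contact count in antigen-antibody
#'   interfaces).
#' @param shell_pixel,shell_max_radius shell layering around the interface
#'   center C (defaults: 2 and 20 Angstrom, i.e. 10 layers).
#' @param aggregate `"or"` (default; layers are bitwise OR over their
#'   residues) or `"sum"` (per-layer bit counts).
#' @return an `epif_params` list.
#' @export
epif_params <- function(distance_cutoff = 4.0, count_cutoff_charged = 1L,
                        count_cutoff_other = 4L, shell_pixel = 2.0,
                        shell_max_radius = 20.0,
                        aggregate = c("or", "sum")) {
  stopifnot(distance_cutoff > 0, count_cutoff_charged >= 1,
            count_cutoff_other >= 1)
  structure(list(distance_cutoff = distance_cutoff,
                 count_cutoff_charged = as.integer(count_cutoff_charged),
                 count_cutoff_other = as.integer(count_cutoff_other),
                 shell_pixel = shell_pixel,
                 shell_max_radius = shell_max_radius,
                 aggregate = match.arg(aggregate)),
            class = "epif_params")
}

# Pairwise contact of one epitope residue against each paratope residue.
# Returns per-paratope-residue logicals: any/backbone/sidechain contact.
contact_modes <- function(epi_xyz, para_atoms, cutoff) {
  keys <- unique(para_atoms$key)
  out <- matrix(FALSE, length(keys), 3,
                dimnames = list(keys, c("any", "backbone", "sidechain")))
  cut2 <- cutoff^2
  for (k in keys) {
    pa <- para_atoms[para_atoms$key == k, , drop = FALSE]
    pxyz <- as.matrix(pa[, c("x", "y", "z")])
    # min squared distance from each paratope atom to any epitope atom
    d2 <- apply(pxyz, 1, function(p)
      min((epi_xyz[, 1] - p[1])^2 + (epi_xyz[, 2] - p[2])^2 +
            (epi_xyz[, 3] - p[3])^2))
    touch <- d2 <= cut2
    bb <- pa$elety %in% BACKBONE_ATOMS
    out[k, ] <- c(any(touch), any(touch & bb), any(touch & !bb))
  }
  out
}

#' Per-epitope-residue 15-bit interaction fingerprint
#'
#' A paratope residue is "in contact" when any of its atoms lies within
#' `distance_cutoff` of any atom of the epitope residue. Bit 1 (`any`)
#' records at least one contact; when it is 0 all other bits are 0.
#' Backbone / sidechain type bits require the contact to run through a
#' backbone (N, CA, C, O, OXT) / non-backbone atom of the paratope residue;
#' polar, hydrophobic, aromatic and charged type bits require a contacting
#' paratope residue of that class; the two H-bond bits require a contacting
#' residue whose side chain can donate / accept a hydrogen bond. Each
#' strength bit is set when its type bit is set and the number of distinct
#' contacting paratope residues of that type reaches the count cutoff
#' (charged: 1, others: 4 by default).
#'
#' @param epi_xyz numeric matrix (atoms x 3) of the epitope residue's atoms.
#' @param para_atoms data.frame of paratope atoms with columns `key`,
#'   `aa`, `elety`, `x`, `y`, `z` (as in `complex_structure$atoms`).
#' @param params an [epif_params()] list.
#' @param classes residue class table, as [residue_classes()].
#' @return named integer vector of 15 bits (0/1).
#' @export
residue_interaction_bits <- function(epi_xyz, para_atoms,
                                     params = epif_params(),
                                     classes = residue_classes()) {
  bits <- stats::setNames(integer(15), interaction_bit_names())
  if (nrow(para_atoms) == 0) return(bits)
  cm <- contact_modes(rbind(epi_xyz), para_atoms, params$distance_cutoff)
  touching <- rownames(cm)[cm[, "any"]]
  if (length(touching) == 0) return(bits)
  bits["any"] <- 1L

  aa_of <- para_atoms$aa[match(rownames(cm), para_atoms$key)]
  in_class <- function(cl) {
    ok <- rownames(classes)[classes[[cl]]]
    cm[, "any"] & aa_of %in% ok
  }
  counts <- c(
    backbone = sum(cm[, "backbone"]),
    sidechain = sum(cm[, "sidechain"]),
    polar = sum(in_class("polar")),
    hydrophobic = sum(in_class("hydrophobic")),
    aromatic = sum(in_class("aromatic")),
    charged = sum(in_class("charged"))
  )
  for (ty in names(counts)) {
    if (counts[ty] >= 1) bits[paste0(ty, "_e")] <- 1L
    need <- if (ty == "charged") params$count_cutoff_charged
            else params$count_cutoff_other
    if (counts[ty] >= need) bits[paste0(ty, "_s")] <- 1L
  }
  if (sum(in_class("hbond_donor")) >= 1) bits["hbond_donor"] <- 1L
  if (sum(in_class("hbond_acceptor")) >= 1) bits["hbond_acceptor"] <- 1L
  bits
}

#' 150-bit epitope-paratope interaction fingerprint
#'
#' Computes the 15-bit interaction vector of every epitope residue, assigns
#' each residue to a radial shell around the interface center C (10 layers
#' of 2 Angstrom by default; residues beyond 20 Angstrom are dropped), and
#' aggregates each layer by bitwise OR (or per-bit sums in `"sum"` mode).
#' The vector is layer-major: layer `l` occupies positions
#' `[15 l, 15 (l+1))`.
#'
#' @param structure a `complex_structure`.
#' @param annotation an `interface_annotation` with nonempty epitope and
#'   paratope.
#' @param center interface center C; taken from `frame$C` when a frame is
#'   given, or computed via [build_frame()] when `NULL`.
#' @param params an [epif_params()] list.
#' @param classes residue class table, as [residue_classes()].
#' @return a `fingerprint` of length 150 with attribute `per_residue`: the
#'   epitope-residue x 15 bit matrix it was aggregated from.
#' @export
epif <- function(structure, annotation, center = NULL,
                 params = epif_params(), classes = residue_classes()) {
  if (annotation$empty)
    stop("empty epitope or paratope: no EPIF can be computed")
  pts <- residue_points(structure)
  if (is.null(center))
    center <- build_frame(annotation, pts, "paratope")$C
  para_atoms <- structure$atoms[structure$atoms$key %in% annotation$paratope,
                                , drop = FALSE]
  n_layers <- as.integer(params$shell_max_radius / params$shell_pixel)

  per_res <- matrix(0L, length(annotation$epitope), 15,
                    dimnames = list(annotation$epitope,
                                    interaction_bit_names()))
  for (k in annotation$epitope) {
    exyz <- atom_coords(structure, k)
    per_res[k, ] <- residue_interaction_bits(exyz, para_atoms, params,
                                             classes)
  }
  layer <- shell_index(pts[annotation$epitope, , drop = FALSE], center,
                       params$shell_pixel, params$shell_max_radius)

  vec <- numeric(15 * n_layers)
  names(vec) <- paste0("epif_L", rep(seq_len(n_layers) - 1, each = 15), "_",
                       rep(interaction_bit_names(), n_layers))
  for (l in seq_len(n_layers) - 1) {
    rows <- which(!is.na(layer) & layer == l)
    if (length(rows) == 0) next
    agg <- colSums(per_res[rows, , drop = FALSE])
    if (params$aggregate == "or") agg <- as.numeric(agg > 0)
    vec[l * 15 + seq_len(15)] <- agg
  }
  out <- new_fingerprint(vec, list(epif = seq_along(vec)),
                         side = "interaction")
  attr(out, "per_residue") <- per_res
  out
}
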