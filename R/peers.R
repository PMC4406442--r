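# Peer descriptors the fingerprints are benchmarked against: pairwise
# sequence-identity panels and a 41-feature backbone geometry summary.

#' Amino-acid sequence of selected chains
#'
#' @param structure a `complex_structure`.
#' @param chains chain identifiers (default: all chains, file order).
#' @return single character string of one-letter codes (`X` for
#'   nonstandard residues).
#' @export
chain_sequence <- function(structure, chains = NULL) {
  res <- structure$residues
  if (!is.null(chains)) res <- res[res$chain %in% chains, , drop = FALSE]
  paste(res$aa, collapse = "")
}

#' Read a similarity panel from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return data.frame with columns `id` and `seq`.
#' @export
read_panel_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate ids in panel FASTA")
  data.frame(id = ids, seq = as.character(set), stringsAsFactors = FALSE)
}

#' Global-alignment percent identity
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with gap open 11 /
#' extend 1, reported as identities / alignment length x 100 (gap columns
#' count toward the length).
#'
#' @param a,b amino-acid sequences (character strings).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(s1 == s2 & s1 != "-") / length(s1)
}

#' Sequence-similarity descriptor against a reference panel
#'
#' Entry `k` is the global-alignment percent identity between `seq` and
#' panel sequence `k`; with the study-style panel of all antigens (or all
#' antibodies) in a data set this yields the panel-sized similarity
#' descriptor. A precomputed identity row (e.g. from external BLAST runs)
#' can be supplied instead via `precomputed`.
#'
#' @param seq amino-acid sequence (character string).
#' @param panel data.frame with columns `id`, `seq` (see
#'   [read_panel_fasta()]).
#' @param precomputed optional named numeric vector of identities covering
#'   every panel id; returned (reordered) as-is when given.
#' @return named numeric vector of length `nrow(panel)`.
#' @export
sequence_similarity_descriptor <- function(seq, panel, precomputed = NULL) {
  if (is.null(precomputed)) {
    if (!nzchar(seq)) stop("empty query sequence")
    if (nrow(panel) == 0) stop("empty panel")
  }
  if (!is.null(precomputed)) {
    if (!all(panel$id %in% names(precomputed)))
      stop("precomputed identities do not cover the panel")
    return(precomputed[panel$id])
  }
  stats::setNames(
    vapply(panel$seq, function(s) pairwise_identity(seq, s), numeric(1)),
    panel$id)
}

vec_angle <- function(u, v) {
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

circ_hist <- function(theta, bins = 12) {
  if (length(theta) == 0) return(numeric(bins))
  idx <- floor((theta + pi) / (2 * pi / bins)) + 1
  idx[idx > bins] <- 1  # theta == pi wraps to the first bin
  tabulate(idx, bins) / length(theta)
}

resultant_length <- function(theta) {
  if (length(theta) == 0) return(0)
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' 41-feature backbone geometry descriptor
#'
#' Summarizes covalent backbone geometry: mean and standard deviation of
#' the N-CA, CA-C, C-O and peptide C-N(next) bond lengths (8 features) and
#' of the N-CA-C, CA-C-N(next) and C-N(next)-CA(next) bond angles (6);
#' 12-bin circular histograms (relative frequencies) of the phi and psi
#' dihedrals (24); and the circular mean resultant length of phi, psi and
#' omega (3). Consecutive-residue terms require adjacent residues of the
#' same chain joined by a peptide bond (C-N distance < 2.5 Angstrom).
#' Angles are in radians; a standard deviation over fewer than 2 values
#' is 0.
#'
#' @param structure a `complex_structure`.
#' @return named numeric vector of length 41 (class `geometry_descriptor`).
#' @export
geometry_descriptor <- function(structure) {
  res <- structure$residues
  a <- structure$atoms
  get_atom <- function(key, name) {
    i <- which(a$key == key & a$elety == name)
    if (length(i) == 0) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  bb <- lapply(res$key, function(k)
    list(N = get_atom(k, "N"), CA = get_atom(k, "CA"),
         C = get_atom(k, "C"), O = get_atom(k, "O")))
  complete <- vapply(bb, function(b)
    !any(vapply(b, is.null, logical(1))), logical(1))
  if (sum(complete) < 3)
    stop("need at least 3 residues with complete backbone atoms")

  b_nca <- c(); b_cac <- c(); b_co <- c(); b_cn <- c()
  a_ncac <- c(); a_cacn <- c(); a_cnca <- c()
  phi <- c(); psi <- c(); omega <- c()
  dlen <- function(u, v) sqrt(sum((u - v)^2))

  for (i in seq_len(nrow(res))) {
    if (!complete[i]) next
    b <- bb[[i]]
    b_nca <- c(b_nca, dlen(b$N, b$CA))
    b_cac <- c(b_cac, dlen(b$CA, b$C))
    b_co <- c(b_co, dlen(b$C, b$O))
    a_ncac <- c(a_ncac, vec_angle(b$N - b$CA, b$C - b$CA))
    j <- i + 1
    linked <- j <= nrow(res) && complete[j] &&
      res$chain[j] == res$chain[i] &&
      dlen(bb[[j]]$N, b$C) < 2.5
    if (!linked) next
    nb <- bb[[j]]
    b_cn <- c(b_cn, dlen(b$C, nb$N))
    a_cacn <- c(a_cacn, vec_angle(b$CA - b$C, nb$N - b$C))
    a_cnca <- c(a_cnca, vec_angle(b$C - nb$N, nb$CA - nb$N))
    psi <- c(psi, dihedral(b$N, b$CA, b$C, nb$N))
    omega <- c(omega, dihedral(b$CA, b$C, nb$N, nb$CA))
    # phi of residue j needs the preceding C, which is residue i's
    phi <- c(phi, dihedral(b$C, nb$N, nb$CA, nb$C))
  }

  msd <- function(x) c(mean = mean(x),
                       sd = if (length(x) > 1) stats::sd(x) else 0)
  out <- c(
    bond_N_CA = msd(b_nca), bond_CA_C = msd(b_cac), bond_C_O = msd(b_co),
    bond_C_N = msd(if (length(b_cn)) b_cn else 0),
    angle_N_CA_C = msd(a_ncac),
    angle_CA_C_N = msd(if (length(a_cacn)) a_cacn else 0),
    angle_C_N_CA = msd(if (length(a_cnca)) a_cnca else 0),
    stats::setNames(circ_hist(phi), paste0("phi_bin", 1:12)),
    stats::setNames(circ_hist(psi), paste0("psi_bin", 1:12)),
    phi_R = resultant_length(phi), psi_R = resultant_length(psi),
    omega_R = resultant_length(omega)
  )
  stopifnot(length(out) == 41)
  class(out) <- "geometry_descriptor"
  out
}

#' @export
print.geometry_descriptor <- function(x, ...) {
  cat("Backbone geometry descriptor (41 features)\n")
  print(round(unclass(x), 4))
  invisible(x)
}
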