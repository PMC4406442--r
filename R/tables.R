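# Bundled per-amino-acid lookup tables. All tables are plain named vectors /
# data frames so users can pass modified copies anywhere a table is accepted.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Convert three-letter residue names to one-letter codes
#'
#' Nonstandard residue names map to `"X"`; matching is case-insensitive.
#'
#' @param resid character vector of three-letter residue names.
#' @return character vector of one-letter codes (`"X"` for nonstandard).
#' @export
aa_three_to_one <- function(resid) {
  out <- AA1[match(toupper(resid), AA3)]
  out[is.na(out)] <- "X"
  out
}

#' AAindex property scales used by the shell-model fingerprint
#'
#' Returns the three AAindex entries the physicochemical fingerprint is built
#' from, as a list of named numeric vectors over the 20 standard one-letter
#' codes:
#' * `ARGP820101` — hydrophobicity index (Argos et al., 1982),
#' * `FAUJ880109` — number of hydrogen bond donors (Fauchere et al., 1988),
#' * `FAUJ880108` — localized electrical effect (Fauchere et al., 1988).
#'
#' Values are used raw (no rescaling). A unit test cross-checks this table
#' against the AAindex copy distributed with the seqinr package.
#'
#' @return named list of three named numeric vectors of length 20.
#' @export
aaindex_default <- function() {
  list(
    ARGP820101 = c(
      A = 0.61, R = 0.60, N = 0.06, D = 0.46, C = 1.07, Q = 0.00, E = 0.47,
      G = 0.07, H = 0.61, I = 2.22, L = 1.53, K = 1.15, M = 1.18, F = 2.02,
      P = 1.95, S = 0.05, T = 0.05, W = 2.65, Y = 1.88, V = 1.32),
    FAUJ880109 = c(
      A = 0, R = 4, N = 2, D = 1, C = 0, Q = 2, E = 1, G = 0, H = 1, I = 0,
      L = 0, K = 2, M = 0, F = 0, P = 0, S = 1, T = 1, W = 1, Y = 1, V = 0),
    FAUJ880108 = c(
      A = -0.01, R = 0.04, N = 0.06, D = 0.15, C = 0.12, Q = 0.05, E = 0.07,
      G = 0.00, H = 0.08, I = -0.01, L = -0.01, K = 0.00, M = 0.04, F = 0.03,
      P = 0.00, S = 0.11, T = 0.04, W = 0.00, Y = 0.03, V = 0.01)
  )
}

#' Van der Waals radii used for solvent accessibility
#'
#' Element-keyed radii (Angstrom) after Bondi (1964), the common choice for
#' protein SASA when only heavy-atom elements are known. Elements absent from
#' the table fall back to 1.8 A with a warning.
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80, SE = 1.90)
}

#' Residue class table for interaction typing
#'
#' Boolean membership of each standard amino acid in the classes the
#' per-residue interaction bits key on. Histidine is treated as aromatic and
#' polar but not charged (its side chain is mostly neutral at physiological
#' pH). The table is an ordinary data frame: users may pass an edited copy to
#' [residue_interaction_bits()] or [epif()].
#'
#' @return data.frame with row names = one-letter codes and logical columns
#'   `polar`, `hydrophobic`, `aromatic`, `charged`, `hbond_donor`,
#'   `hbond_acceptor` (the H-bond columns describe side-chain capability).
#' @export
residue_classes <- function() {
  hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "P")
  polar       <- c("S", "T", "N", "Q", "C", "Y", "H")
  aromatic    <- c("F", "W", "Y", "H")
  charged     <- c("D", "E", "K", "R")
  donor       <- c("R", "K", "W", "N", "Q", "H", "S", "T", "Y")
  acceptor    <- c("D", "E", "N", "Q", "H", "S", "T", "Y")
  data.frame(
    row.names      = AA1,
    polar          = AA1 %in% polar,
    hydrophobic    = AA1 %in% hydrophobic,
    aromatic       = AA1 %in% aromatic,
    charged        = AA1 %in% charged,
    hbond_donor    = AA1 %in% donor,
    hbond_acceptor = AA1 %in% acceptor
  )
}

# Backbone atom names; everything else on a residue counts as side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
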