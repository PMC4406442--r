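# Synthetic antigen-antibody complexes with planted, ground-truth
# interfaces, and synthetic PCM datasets with planted response structure.
#
# Geometry of a generated complex (interface plane at z = 0):
#   * planted contact pairs sit in clusters of three around grid positions
#     inside `interface_width`; the epitope residue's side-chain tip is at
#     z = -separation/2 and its paratope partner's at +separation/2, so the
#     minimum atom distance of a planted pair is `separation` (< 4 by
#     default) while backbone atoms stay out of contact range;
#   * clustering puts epitope residue points within 3.4 Angstrom of each
#     other, so every full cluster contributes unit patches;
#   * non-contact residues sit in slabs 10 Angstrom further out, at least
#     8 Angstrom from every partner atom, so they gain surface area but no
#     burial.
# Residues are compact pseudo-residues: backbone N, CA, C, O within
# ~1 Angstrom of CA plus a CB and a side-chain tip along z. All randomness
# (a small coordinate jitter and amino-acid shuffling) flows through the
# recipe seed, and the PDB output is byte-identical for equal recipes.

#' Recipe for a synthetic antigen-antibody complex
#'
#' @param seed integer seed; equal recipes give byte-identical PDB files.
#' @param contacts named integer vector of planted contact pairs per
#'   paratope class: names from `charged`, `hydrophobic`, `polar`,
#'   `aromatic`, `any`. Default plants 9 pairs (three full clusters).
#' @param n_antigen,n_antibody total residues per side (must be >= the
#'   number of contacts).
#' @param interface_width lateral extent of the contact area, Angstrom.
#' @param separation minimum atom-atom distance of planted pairs,
#'   Angstrom; values > 4 (with the default detection thresholds) yield an
#'   empty interface.
#' @param jitter sd of the Gaussian coordinate jitter, Angstrom (small so
#'   planted margins hold).
#' @return a `complex_recipe` list.
#' @export
complex_recipe <- function(seed = 1,
                           contacts = c(charged = 2, hydrophobic = 4,
                                        polar = 2, aromatic = 1),
                           n_antigen = 24, n_antibody = 24,
                           interface_width = 18, separation = 3.6,
                           jitter = 0.15) {
  nc <- sum(contacts)
  stopifnot(separation >= 2, jitter >= 0, interface_width > 0)
  if (n_antigen < nc || n_antibody < nc)
    stop("fewer residues than planted contacts")
  n_clusters <- ceiling(nc / 3)
  per_row <- max(1, floor(interface_width / 9) + 1)
  if (n_clusters > per_row^2)
    stop("infeasible geometry: too many contacts for the interface width")
  structure(list(seed = as.integer(seed), contacts = contacts,
                 n_antigen = n_antigen, n_antibody = n_antibody,
                 interface_width = interface_width, separation = separation,
                 jitter = jitter),
            class = "complex_recipe")
}

# paratope amino acid carrying each planted class
CONTACT_AA <- c(charged = "R", hydrophobic = "L", polar = "S",
                aromatic = "F", any = "A")

pseudo_residue <- function(chain, resno, aa, ca, up = 1) {
  # `up` = +1 when the side chain points toward positive z
  off <- rbind(N = c(-0.8, 0, 0), CA = c(0, 0, 0), C = c(0.8, 0, 0),
               O = c(0.9, 0.7, 0), CB = c(0, 0, up * 1.5),
               CG = c(0, 0, up * 2.8))
  if (aa == "G") off <- off[1:4, , drop = FALSE]  # glycine: no side chain
  data.frame(chain = chain, resno = resno, aa = aa,
             elety = rownames(off),
             x = ca[1] + off[, 1], y = ca[2] + off[, 2],
             z = ca[3] + off[, 3], stringsAsFactors = FALSE)
}

grid_xy <- function(n, spacing) {
  m <- ceiling(sqrt(n))
  i <- seq_len(n) - 1
  cbind((i %% m) * spacing, (i %/% m) * spacing) -
    (m - 1) * spacing / 2
}

format_pdb_atom <- function(serial, elety, resid3, chain, resno, xyz, ele) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, elety, resid3, chain, resno, xyz[1], xyz[2], xyz[3],
          1.0, 0.0, ele)
}

#' Generate a synthetic complex with a known interface
#'
#' Builds the pseudo-atomic complex described by the recipe, writes it as a
#' PDB file, reads it back through [load_complex()] and returns the loaded
#' structure together with the planted ground truth.
#'
#' @param recipe a [complex_recipe()].
#' @param path output PDB path (default: a tempfile).
#' @return list with `path`, `structure` (a `complex_structure`),
#'   `antigen_chains` (`"A"`), `antibody_chains` (`"H"`, `"L"`), and
#'   `truth`: a list with `epitope` / `paratope` key vectors and a
#'   `contacts` data.frame (`epitope_key`, `paratope_key`, `class`).
#' @export
make_complex <- function(recipe, path = tempfile(fileext = ".pdb")) {
  nc <- sum(recipe$contacts)
  sep2 <- recipe$separation / 2
  classes <- rep(names(recipe$contacts), recipe$contacts)

  with_seed(recipe$seed, {
    rows <- list()
    truth <- data.frame(epitope_key = character(0),
                        paratope_key = character(0), class = character(0))
    ag_no <- 0; ab_no <- 0
    # no glycine here: the planted contact runs through the side chain,
    # which the glycine template does not have
    epi_aa_pool <- c("A", "S", "T", "N", "D", "K", "Y", "E", "Q", "V")

    if (nc > 0) {
      n_clusters <- ceiling(nc / 3)
      centers <- grid_xy(n_clusters, 9)
      rho <- 3.4 / sqrt(3)
      ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
      for (i in seq_len(nc)) {
        cl <- (i - 1) %/% 3 + 1
        v <- (i - 1) %% 3 + 1
        xy <- centers[cl, ] + rho * c(cos(ang[v]), sin(ang[v]))
        ag_no <- ag_no + 1; ab_no <- ab_no + 1
        epi_aa <- epi_aa_pool[(i - 1) %% length(epi_aa_pool) + 1]
        par_aa <- CONTACT_AA[[classes[i]]]
        rows[[length(rows) + 1]] <-
          pseudo_residue("A", ag_no, epi_aa,
                         c(xy, -(sep2 + 2.8)), up = +1)
        rows[[length(rows) + 1]] <-
          pseudo_residue("H", ab_no, par_aa,
                         c(xy, sep2 + 2.8), up = -1)
        truth <- rbind(truth, data.frame(
          epitope_key = paste0("A:", ag_no, ":"),
          paratope_key = paste0("H:", ab_no, ":"),
          class = classes[i]))
      }
    }

    body_aa <- rep(AA1[AA1 != "X"], length.out = 2 *
                     max(recipe$n_antigen, recipe$n_antibody))
    n_ag_body <- recipe$n_antigen - nc
    if (n_ag_body > 0) {
      xy <- grid_xy(n_ag_body, 5)
      for (i in seq_len(n_ag_body)) {
        ag_no <- ag_no + 1
        rows[[length(rows) + 1]] <-
          pseudo_residue("A", ag_no, body_aa[i],
                         c(xy[i, ], -(sep2 + 10)), up = -1)
      }
    }
    n_ab_body <- recipe$n_antibody - nc
    if (n_ab_body > 0) {
      xy <- grid_xy(n_ab_body, 5)
      n_l <- max(1, n_ab_body %/% 2)  # put the tail of the slab on chain L
      l_no <- 0
      for (i in seq_len(n_ab_body)) {
        on_l <- i > n_ab_body - n_l
        if (on_l) l_no <- l_no + 1 else ab_no <- ab_no + 1
        rows[[length(rows) + 1]] <-
          pseudo_residue(if (on_l) "L" else "H",
                         if (on_l) l_no else ab_no,
                         body_aa[n_ag_body + i],
                         c(xy[i, ], sep2 + 10), up = +1)
      }
    } else {
      # chain L must exist: park one far-away residue on it
      rows[[length(rows) + 1]] <-
        pseudo_residue("L", 1, "A", c(30, 30, sep2 + 10), up = +1)
    }

    atoms <- do.call(rbind, rows)
    if (recipe$jitter > 0) {
      j <- matrix(stats::rnorm(3 * nrow(atoms), sd = recipe$jitter),
                  ncol = 3)
      atoms$x <- atoms$x + j[, 1]
      atoms$y <- atoms$y + j[, 2]
      atoms$z <- atoms$z + j[, 3]
    }

    resid3 <- AA3[match(atoms$aa, AA1)]
    ele <- substr(atoms$elety, 1, 1)
    lines <- vapply(seq_len(nrow(atoms)), function(i)
      format_pdb_atom(i, atoms$elety[i], resid3[i], atoms$chain[i],
                      atoms$resno[i],
                      c(atoms$x[i], atoms$y[i], atoms$z[i]), ele[i]),
      character(1))
    writeLines(c(lines, "END"), path)

    st <- load_complex(path, antigen_chains = "A",
                       antibody_chains = c("H", "L"))
    list(path = path, structure = st, antigen_chains = "A",
         antibody_chains = c("H", "L"),
         truth = list(epitope = truth$epitope_key,
                      paratope = truth$paratope_key, contacts = truth))
  })
}

#' Recipe for a synthetic PCM dataset
#'
#' @param seed integer seed.
#' @param n_samples number of complexes (>= 10).
#' @param response `"linear"` (y linear in a sparse set of features) or
#'   `"quadratic"` (adds antibody x antigen product terms).
#' @param noise_sd Gaussian noise sd, in units of the noiseless response's
#'   sd (0 = noiseless).
#' @param n_informative number of features carrying signal.
#' @return a `pcm_recipe` list.
#' @export
pcm_recipe <- function(seed = 1, n_samples = 200,
                       response = c("linear", "quadratic"), noise_sd = 0,
                       n_informative = 20) {
  if (n_samples < 10) stop("n_samples must be at least 10")
  stopifnot(noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 response = match.arg(response), noise_sd = noise_sd,
                 n_informative = n_informative),
            class = "pcm_recipe")
}

#' Generate a synthetic PCM dataset with planted response structure
#'
#' Feature tables use the real descriptor layouts: `Fab` and `Fag` are
#' 110 long (80 binary cylinder bits + 30 continuous shell values), `EPIF`
#' is 150 binary bits, and `MLPD` is their 12100-length outer product.
#' Complexes are drawn as perturbed copies of a panel of prototype
#' fingerprints (25 per descriptor; bits flip with probability 0.02,
#' continuous values get 10% perturbation), mimicking the clonal
#' relatedness of real antigen-antibody panels, where many complexes share
#' antibody frameworks and epitopes and differ by a few mutations. The
#' response is a sparse linear (optionally with antibody x antigen
#' interaction products) function of the `Fab`/`Fag` features plus
#' Gaussian noise, and rows are split 80/20 train/test by a seeded
#' shuffle.
#'
#' @param recipe a [pcm_recipe()].
#' @param combination descriptor recipe passed to [assemble_features()]
#'   (default `"Fab-Fag"`).
#' @return a `pcm_dataset` with extra fields `tables` (all four descriptor
#'   matrices) and `truth` (informative columns and coefficients).
#' @export
make_pcm_dataset <- function(recipe, combination = "Fab-Fag") {
  n <- recipe$n_samples
  with_seed(recipe$seed, {
    ids <- sprintf("cx%03d", seq_len(n))
    n_proto <- 25; flip <- 0.02; wobble <- 0.08
    family <- sample.int(n_proto, n, replace = TRUE)
    proto_table <- function(prefix, n_bits, n_cont, p_bit, cont_mu,
                            cont_sd) {
      proto_b <- matrix(stats::rbinom(n_proto * n_bits, 1, p_bit),
                        n_proto, n_bits)
      proto_c <- matrix(stats::rnorm(n_proto * n_cont, cont_mu, cont_sd),
                        n_proto, n_cont)
      bits <- abs(proto_b[family, , drop = FALSE] -
                    matrix(stats::rbinom(n * n_bits, 1, flip), n, n_bits))
      cont <- proto_c[family, , drop = FALSE] +
        matrix(stats::rnorm(n * n_cont, sd = wobble * cont_sd), n, n_cont)
      m <- cbind(bits, cont)
      dimnames(m) <- list(ids, paste0(prefix, "_",
                                      seq_len(n_bits + n_cont)))
      m
    }
    Fab <- proto_table("fab", 80, 30, 0.3, 1, 0.8)
    Fag <- proto_table("fag", 80, 30, 0.3, 1, 0.8)
    EPIF <- proto_table("epif", 150, 0, 0.2, 0, 1)
    MLPD <- t(vapply(seq_len(n), function(i)
      as.vector(t(outer(Fab[i, ], Fag[i, ]))), numeric(110 * 110)))
    dimnames(MLPD) <- list(ids, paste0("mlpd_", seq_len(110 * 110)))

    XX <- cbind(Fab, Fag)
    info <- sort(sample.int(ncol(XX), recipe$n_informative))
    beta <- stats::rnorm(recipe$n_informative)
    y0 <- as.vector(XX[, info, drop = FALSE] %*% beta)
    if (recipe$response == "quadratic") {
      pair_i <- sample.int(110, 5)
      pair_j <- sample.int(110, 5)
      for (q in 1:5)
        y0 <- y0 + stats::rnorm(1) * Fab[, pair_i[q]] * Fag[, pair_j[q]]
    }
    s <- stats::sd(y0)
    y <- y0 + stats::rnorm(n, sd = recipe$noise_sd * s)

    n_test <- round(n / 5)
    test_rows <- sample.int(n, n_test)
    split <- !(seq_len(n) %in% test_rows)

    ds <- assemble_features(list(Fab = Fab, Fag = Fag, EPIF = EPIF,
                                 MLPD = MLPD),
                            combination, y, split)
    ds$tables <- list(Fab = Fab, Fag = Fag, EPIF = EPIF, MLPD = MLPD)
    ds$truth <- list(informative = info, beta = beta,
                     noise_sd = recipe$noise_sd * s)
    ds
  })
}
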