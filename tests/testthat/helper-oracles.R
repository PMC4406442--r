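# Shared fixtures and independent oracles. Oracles deliberately use
# different code paths (plain loops, direct formulas) from the package.

# --- rigid motions -----------------------------------------------------

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_points <- function(pts, R, t) {
  sweep(pts %*% t(R), 2, t, "+")
}

transform_structure <- function(st, R, t) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  xyz <- transform_points(xyz, R, t)
  st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
  st
}

# --- structure builders ------------------------------------------------

# Build a complex_structure straight from an atom table
# (chain, resno, aa, elety, x, y, z), bypassing file I/O.
make_structure <- function(atoms, antigen_chains, antibody_chains) {
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
           X = "UNK")
  df <- data.frame(
    key = paste(atoms$chain, atoms$resno, "", sep = ":"),
    chain = atoms$chain, resno = atoms$resno, insert = "",
    resid = aa3[atoms$aa], aa = atoms$aa,
    role = ifelse(atoms$chain %in% antigen_chains, "antigen", "antibody"),
    elety = atoms$elety,
    element = toupper(substr(gsub("[0-9]", "", atoms$elety), 1, 1)),
    x = atoms$x, y = atoms$y, z = atoms$z, stringsAsFactors = FALSE)
  suppressWarnings(
    epifp:::new_complex_structure(df, antigen_chains, antibody_chains))
}

# A minimal interface annotation for frame/fingerprint unit tests.
fake_annotation <- function(epitope, paratope, surface_antigen = epitope,
                            surface_antibody = paratope) {
  structure(list(surface_antigen = surface_antigen,
                 surface_antibody = surface_antibody,
                 epitope = epitope, paratope = paratope,
                 delta_sasa = setNames(
                   rep(5, length(c(surface_antigen, surface_antibody))),
                   c(surface_antigen, surface_antibody)),
                 empty = length(epitope) == 0 || length(paratope) == 0),
            class = "interface_annotation")
}

# One shared planted-interface fixture per test run (SASA is the slow bit).
the_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cx <- make_complex(complex_recipe(seed = 101))
      sasa <- compute_sasa(cx$structure)
      ann <- detect_epitope_paratope(cx$structure, sasa)
      cache <<- list(cx = cx, sasa = sasa, ann = ann)
    }
    cache
  }
})

# --- independent oracles ----------------------------------------------

# SASA by uniform random direction sampling (independent of the package's
# Fibonacci lattice).
oracle_sasa <- function(xyz, radii, probe = 1.4, n_points = 20000) {
  dirs <- matrix(rnorm(3 * n_points), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rp <- radii + probe
  sapply(seq_len(nrow(xyz)), function(i) {
    pts <- sweep(dirs * rp[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 > rp[j]^2
    }
    4 * pi * rp[i]^2 * mean(free)
  })
}

# Exhaustive triangle enumeration.
oracle_triangles <- function(pts, cutoff) {
  n <- nrow(pts); out <- list()
  if (n >= 3) {
    d <- as.matrix(dist(pts))
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      if (d[i, j] <= cutoff && d[i, k] <= cutoff && d[j, k] <= cutoff)
        out[[length(out) + 1]] <- sort(rownames(pts)[c(i, j, k)])
  }
  out
}

# Per-point cylinder binning.
oracle_cylinder <- function(pts, frame, params) {
  vec <- numeric(params$nr * params$nz)
  for (i in seq_len(nrow(pts))) {
    rel <- pts[i, ] - frame$C
    z <- sum(rel * frame$z_axis)
    r <- sqrt(sum((rel - z * frame$z_axis)^2))
    if (r < params$radius && z >= params$z_min && z < params$z_max) {
      idx <- floor((z - params$z_min) / params$z_pixel) * params$nr +
        floor(r / params$r_pixel) + 1
      vec[idx] <- vec[idx] + 1
    }
  }
  if (params$mode == "binary") as.numeric(vec > 0) else vec
}

# Direct per-distance shell layer.
oracle_shell <- function(d, pixel, max_radius) {
  ifelse(d >= max_radius, NA_integer_, as.integer(d %/% pixel))
}

# Exhaustive atom-pair / class-count interaction bits.
oracle_bits <- function(epi_xyz, para_atoms, params = epif_params(),
                        classes = residue_classes()) {
  bits <- setNames(integer(15), interaction_bit_names())
  keys <- unique(para_atoms$key)
  tallies <- list(backbone = 0, sidechain = 0, polar = 0, hydrophobic = 0,
                  aromatic = 0, charged = 0, donor = 0, acceptor = 0)
  any_contact <- FALSE
  for (k in keys) {
    pa <- para_atoms[para_atoms$key == k, ]
    touch_bb <- FALSE; touch_sc <- FALSE; touch <- FALSE
    for (r in seq_len(nrow(pa))) for (e in seq_len(nrow(epi_xyz))) {
      d <- sqrt(sum((c(pa$x[r], pa$y[r], pa$z[r]) - epi_xyz[e, ])^2))
      if (d <= params$distance_cutoff) {
        touch <- TRUE
        if (pa$elety[r] %in% c("N", "CA", "C", "O", "OXT"))
          touch_bb <- TRUE else touch_sc <- TRUE
      }
    }
    if (!touch) next
    any_contact <- TRUE
    aa <- pa$aa[1]
    if (touch_bb) tallies$backbone <- tallies$backbone + 1
    if (touch_sc) tallies$sidechain <- tallies$sidechain + 1
    for (cl in c("polar", "hydrophobic", "aromatic", "charged"))
      if (aa %in% rownames(classes) && classes[aa, cl])
        tallies[[cl]] <- tallies[[cl]] + 1
    if (aa %in% rownames(classes) && classes[aa, "hbond_donor"])
      tallies$donor <- tallies$donor + 1
    if (aa %in% rownames(classes) && classes[aa, "hbond_acceptor"])
      tallies$acceptor <- tallies$acceptor + 1
  }
  if (!any_contact) return(bits)
  bits["any"] <- 1L
  for (ty in c("backbone", "sidechain", "polar", "hydrophobic",
               "aromatic", "charged")) {
    cut <- if (ty == "charged") params$count_cutoff_charged
           else params$count_cutoff_other
    if (tallies[[ty]] >= 1) bits[paste0(ty, "_e")] <- 1L
    if (tallies[[ty]] >= cut) bits[paste0(ty, "_s")] <- 1L
  }
  if (tallies$donor >= 1) bits["hbond_donor"] <- 1L
  if (tallies$acceptor >= 1) bits["hbond_acceptor"] <- 1L
  bits
}

# Random paratope neighbourhood for interaction-bit tests.
random_para_atoms <- function(n_res, radius = 5, atom_pool =
                                c("N", "CA", "C", "O", "CB", "CG")) {
  aa_pool <- rownames(residue_classes())
  rows <- lapply(seq_len(n_res), function(i) {
    na <- sample(2:5, 1)
    elety <- sample(atom_pool, na)
    ctr <- runif(3, -radius, radius)
    data.frame(key = paste0("H:", i, ":"), aa = sample(aa_pool, 1),
               elety = elety,
               x = ctr[1] + rnorm(na, sd = 0.8),
               y = ctr[2] + rnorm(na, sd = 0.8),
               z = ctr[3] + rnorm(na, sd = 0.8),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Gotoh affine-gap global alignment, Biostrings cost convention
# (a gap of length L costs open + L * extend).
oracle_nw_identity <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  s1 <- strsplit(a, "")[[1]]; s2 <- strsplit(b, "")[[1]]
  n <- length(s1); m <- length(s2)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sub <- BLOSUM62[s1[i - 1], s2[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                   Iy[i - 1, j - 1]) + sub
    Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
    Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
  }
  # traceback for the identity count and alignment length
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  ident <- 0; len <- 0
  while (i > 1 || j > 1) {
    len <- len + 1
    if (state == 1) {
      ident <- ident + (s1[i - 1] == s2[j - 1])
      sub <- BLOSUM62[s1[i - 1], s2[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- isTRUE(all.equal(Ix[i, j], M[i - 1, j] - open - extend))
      state <- if (from_m) 1 else 2
      i <- i - 1
    } else {
      from_m <- isTRUE(all.equal(Iy[i, j], M[i, j - 1] - open - extend))
      state <- if (from_m) 1 else 3
      j <- j - 1
    }
  }
  list(identity = 100 * ident / len,
       score = max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
}

# Internal-coordinate atom placement (NeRF) for ideal-geometry backbones.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle), bond * cos(dihedral) * sin(angle),
          -bond * sin(dihedral) * sin(angle))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone with fixed phi/psi/omega and exact bond geometry.
# Default torsions sit inside histogram bins, not on a boundary.
ideal_backbone <- function(n_res, phi = -57 * pi / 180,
                           psi = -47 * pi / 180, omega = pi,
                           b_nca = 1.46, b_cac = 1.52, b_co = 1.23,
                           b_cn = 1.33, chain = "A") {
  ang_ncac <- 111 * pi / 180; ang_cacn <- 116.5 * pi / 180
  ang_cnca <- 121.5 * pi / 180; ang_caco <- 120.5 * pi / 180
  rows <- list()
  N <- c(0, 0, 0); CA <- c(b_nca, 0, 0)
  C <- CA + b_cac * c(-cos(ang_ncac), sin(ang_ncac), 0)
  for (i in seq_len(n_res)) {
    O <- place_atom(N, CA, C, b_co, ang_caco, psi + pi)
    rows[[i]] <- data.frame(
      chain = chain, resno = i, aa = "A",
      elety = c("N", "CA", "C", "O"),
      x = c(N[1], CA[1], C[1], O[1]), y = c(N[2], CA[2], C[2], O[2]),
      z = c(N[3], CA[3], C[3], O[3]), stringsAsFactors = FALSE)
    if (i == n_res) break
    N2 <- place_atom(N, CA, C, b_cn, ang_cacn, psi)
    CA2 <- place_atom(CA, C, N2, b_nca, ang_cnca, omega)
    C2 <- place_atom(C, N2, CA2, b_cac, ang_ncac, phi)
    N <- N2; CA <- CA2; C <- C2
  }
  do.call(rbind, rows)
}
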