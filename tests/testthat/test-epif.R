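# Per-residue interaction bits and the 150-bit EPIF.

# a one-residue paratope neighbourhood at a given distance
para_residue <- function(key, aa, at, elety = "CB") {
  data.frame(key = key, aa = aa, elety = elety,
             x = at[1], y = at[2], z = at[3], stringsAsFactors = FALSE)
}

test_that("interaction bits encode contact, type, and strength cutoffs", {
  epi <- rbind(c(0, 0, 0))

  # nothing within 4 A -> all 15 bits are 0
  far <- para_residue("H:1:", "R", c(10, 0, 0))
  expect_true(all(residue_interaction_bits(epi, far) == 0))

  # one charged (Arg) side-chain contact: type and strength both set
  # (charged count cutoff is 1)
  arg <- para_residue("H:1:", "R", c(3, 0, 0))
  b <- residue_interaction_bits(epi, arg)
  expect_equal(unname(b[c("any", "sidechain_e", "charged_e",
                          "charged_s")]), rep(1L, 4))
  expect_equal(unname(b[c("backbone_e", "hydrophobic_e", "sidechain_s")]),
               rep(0L, 3))
  expect_equal(unname(b["hbond_donor"]), 1L)  # Arg side chain donates

  # 3 hydrophobic contacts: type set, strength not (3 < 4)
  leu3 <- do.call(rbind, lapply(1:3, function(i)
    para_residue(paste0("H:", i, ":"), "L", c(3, i - 2, 0))))
  b3 <- residue_interaction_bits(epi, leu3)
  expect_equal(unname(b3["hydrophobic_e"]), 1L)
  expect_equal(unname(b3["hydrophobic_s"]), 0L)
  # a 4th hydrophobic residue reaches the cutoff
  leu4 <- rbind(leu3, para_residue("H:4:", "V", c(-3, 0, 0)))
  expect_equal(unname(residue_interaction_bits(epi, leu4)["hydrophobic_s"]),
               1L)

  # backbone vs sidechain keys on the paratope atom name
  bbc <- para_residue("H:1:", "A", c(3, 0, 0), elety = "CA")
  bb <- residue_interaction_bits(epi, bbc)
  expect_equal(unname(bb[c("backbone_e", "sidechain_e")]), c(1L, 0L))
})

test_that("interaction bits match the exhaustive contact oracle", {
  set.seed(83)
  for (rep in 1:30) {
    epi <- matrix(rnorm(9, sd = 1.2), 3, 3)
    para <- random_para_atoms(sample(2:6, 1))
    got <- residue_interaction_bits(epi, para)
    want <- oracle_bits(epi, para)
    expect_equal(got, want)
  }
})

test_that("bit hierarchy: strength implies type implies any", {
  set.seed(89)
  pairs <- rbind(c(3, 2), c(5, 4), c(7, 6), c(9, 8), c(11, 10), c(13, 12))
  for (rep in 1:1000) {
    epi <- matrix(rnorm(6, sd = 1.5), 2, 3)
    para <- random_para_atoms(sample(1:5, 1), radius = sample(3:7, 1))
    b <- residue_interaction_bits(epi, para)
    for (r in seq_len(nrow(pairs)))
      expect_lte(b[pairs[r, 1]], b[pairs[r, 2]])
    expect_true(all(b[2:15] <= b[1]))
  }
})

test_that("bits are monotone in the distance and count cutoffs", {
  set.seed(97)
  for (rep in 1:10) {
    epi <- matrix(rnorm(6, sd = 1.5), 2, 3)
    para <- random_para_atoms(4)
    b1 <- residue_interaction_bits(epi, para, epif_params())
    b2 <- residue_interaction_bits(epi, para,
                                   epif_params(distance_cutoff = 6))
    expect_true(all(b2 >= b1))  # wider cutoff never clears a set bit
    b3 <- residue_interaction_bits(epi, para,
                                   epif_params(count_cutoff_other = 2))
    expect_true(all(b3 >= b1))  # lower count cutoff never clears strength
  }
})

test_that("EPIF aggregates per-residue bits by OR within shell layers", {
  fx <- the_fixture()
  e <- epif(fx$cx$structure, fx$ann)
  expect_length(e, 150)
  expect_true(all(e %in% c(0, 1)))

  # OR-composition: recompute each layer from the per-residue table
  pr <- attr(e, "per_residue")
  ctr <- build_frame(fx$ann, residue_points(fx$cx$structure),
                     "paratope")$C
  lay <- shell_index(residue_points(fx$cx$structure)[rownames(pr), ,
                                                     drop = FALSE], ctr)
  for (l in 0:9) {
    rows <- which(!is.na(lay) & lay == l)
    want <- if (length(rows) == 0) rep(0, 15) else
      as.numeric(colSums(pr[rows, , drop = FALSE]) > 0)
    expect_equal(as.numeric(e)[l * 15 + 1:15], want)
  }

  # input-order invariance: shuffling epitope residues changes nothing
  ann2 <- fx$ann
  set.seed(101)
  ann2$epitope <- sample(ann2$epitope)
  e2 <- epif(fx$cx$structure, ann2)
  expect_equal(as.numeric(e2), as.numeric(e))

  # sum mode counts residues instead of OR-ing them
  es <- epif(fx$cx$structure, fx$ann, params = epif_params(aggregate = "sum"))
  expect_true(all(es >= as.numeric(e)))
  expect_equal(sum(es[seq(1, 150, by = 15)]), nrow(pr))
})

test_that("planted contact classes surface in the right EPIF layer", {
  fx <- the_fixture()
  e <- epif(fx$cx$structure, fx$ann)
  pr <- attr(e, "per_residue")
  truth <- fx$cx$truth$contacts
  aa_class <- c(charged = "charged_e", hydrophobic = "hydrophobic_e",
                polar = "polar_e", aromatic = "aromatic_e")
  for (i in seq_len(nrow(truth))) {
    bitname <- aa_class[[truth$class[i]]]
    expect_equal(unname(pr[truth$epitope_key[i], bitname]), 1L,
                 label = paste("class bit for", truth$class[i]))
    # charged pairs also get the strength bit at count cutoff 1
    if (truth$class[i] == "charged")
      expect_equal(unname(pr[truth$epitope_key[i], "charged_s"]), 1L)
    if (truth$class[i] == "hydrophobic")
      expect_equal(unname(pr[truth$epitope_key[i], "hydrophobic_s"]), 0L)
  }
  # separated complex: no contacts anywhere -> zero vector (length 150)
  far <- make_complex(complex_recipe(seed = 23, contacts = c(any = 0),
                                     separation = 25))
  ann <- detect_epitope_paratope(far$structure, compute_sasa(far$structure))
  expect_error(epif(far$structure, ann), "empty")
  # bypass detection: force the far residues in as epitope/paratope
  keys_a <- far$structure$residues$key[far$structure$residues$role ==
                                         "antigen"][1:3]
  keys_h <- far$structure$residues$key[far$structure$residues$role ==
                                         "antibody"][1:3]
  e0 <- epif(far$structure, fake_annotation(keys_a, keys_h))
  expect_length(e0, 150)
  expect_true(all(e0 == 0))
})
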