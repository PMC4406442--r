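# Cylinder / shell fingerprints, the combined per-side vector, and MLPD.

simple_frame <- function() {
  pts <- rbind("A:1:" = c(0, 0, 0), "H:1:" = c(0, 0, 10))
  build_frame(fake_annotation("A:1:", "H:1:"), pts, "paratope")
}

test_that("cylinder binning: empty input, single point, oracle equality", {
  fr <- simple_frame()  # C = (0,0,5), z up
  fp0 <- structure_fingerprint(matrix(0, 0, 3), fr)
  expect_length(fp0, 80)
  expect_true(all(fp0 == 0))

  # r = 0.5, z = 0.5 above the plane -> first cell
  p1 <- rbind(fr$C + 0.5 * fr$z_axis + c(0.5, 0, 0))
  fp1 <- structure_fingerprint(p1, fr)
  expect_equal(sum(fp1 != 0), 1)
  expect_equal(unname(fp1[1]), 1)

  set.seed(61)
  for (rep in 1:4) {
    pts <- matrix(rnorm(150, sd = 15), 50, 3)
    for (mode in c("binary", "count")) {
      pars <- cylinder_params(mode = mode)
      got <- structure_fingerprint(pts, fr, pars)
      expect_length(got, 80)
      expect_equal(as.numeric(got), oracle_cylinder(pts, fr, pars))
    }
  }
})

test_that("cylinder coverage reports the in-grid fraction", {
  fr <- simple_frame()
  inpts <- rbind(fr$C + 1 * fr$z_axis, fr$C + 2 * fr$z_axis)
  outpts <- rbind(fr$C - 5 * fr$z_axis,            # below z_min
                  fr$C + 3 * fr$z_axis + c(25, 0, 0))  # beyond radius
  fp <- structure_fingerprint(rbind(inpts, outpts), fr)
  expect_equal(attr(fp, "coverage"), 0.5)
})

test_that("shell fingerprint: empty, single item, group-mean oracle,
           order invariance", {
  ctr <- c(0, 0, 0)
  fp0 <- physchem_fingerprint(matrix(0, 0, 3), list(), ctr)
  expect_length(fp0, 30)
  expect_true(all(fp0 == 0))

  # one residue at 5 A -> layer 2 of each property block
  aa <- "W"
  fp1 <- physchem_fingerprint(rbind(c(5, 0, 0)), list(aa), ctr)
  idx <- aaindex_default()
  for (p in 1:3) {
    block <- as.numeric(fp1)[(p - 1) * 10 + 1:10]
    expect_equal(block[3], unname(idx[[p]][aa]))
    expect_equal(block[-3], rep(0, 9))
  }

  set.seed(67)
  pts <- matrix(runif(120, -15, 15), 40, 3)
  aas <- replicate(40, sample(rownames(residue_classes()),
                              sample(1:3, 1)), simplify = FALSE)
  got <- physchem_fingerprint(pts, aas, ctr)
  # independent group-by-and-average oracle
  d <- sqrt(rowSums(pts^2))
  for (p in 1:3) {
    scale <- idx[[p]]
    vals <- sapply(aas, function(a) mean(scale[a]))
    for (l in 0:9) {
      sel <- d >= 2 * l & d < 2 * (l + 1) & d < 20
      want <- if (any(sel)) mean(vals[sel]) else 0
      expect_equal(as.numeric(got)[(p - 1) * 10 + l + 1], want)
    }
  }
  # permutation invariance in item order
  perm <- sample(40)
  got2 <- physchem_fingerprint(pts[perm, , drop = FALSE], aas[perm], ctr)
  expect_equal(as.numeric(got2), as.numeric(got))
  expect_error(physchem_fingerprint(pts, aas, ctr,
                                    shell_params(properties = "NOPE")),
               "unknown")
})

test_that("the per-side fingerprint is the 80+30 block concatenation", {
  fx <- the_fixture()
  st <- fx$cx$structure; ann <- fx$ann
  pts <- residue_points(st)
  aa_of <- setNames(st$residues$aa, st$residues$key)

  for (side in c("antibody", "antigen")) {
    fp <- protein_fingerprint(side, st, ann)
    expect_length(fp, 110)
    expect_equal(attr(fp, "side"), side)
    lay <- attr(fp, "layout")
    expect_equal(lay$structure, 1:80)
    expect_equal(lay$physchem, 81:110)
  }

  # block equality against independently invoked sub-operations
  fr_ab <- build_frame(ann, pts, "paratope")
  fab <- protein_fingerprint("antibody", st, ann)
  fs <- structure_fingerprint(pts[ann$surface_antibody, , drop = FALSE],
                              fr_ab)
  fpch <- physchem_fingerprint(pts[ann$surface_antibody, , drop = FALSE],
                               as.list(aa_of[ann$surface_antibody]),
                               fr_ab$Cp)
  expect_equal(as.numeric(fab)[1:80], as.numeric(fs))
  expect_equal(as.numeric(fab)[81:110], as.numeric(fpch))

  fr_ag <- build_frame(ann, pts, "epitope")
  up <- unit_patches(pts[ann$epitope, , drop = FALSE])
  fag <- protein_fingerprint("antigen", st, ann)
  fs_ag <- structure_fingerprint(up$centroids, fr_ag)
  expect_equal(as.numeric(fag)[1:80], as.numeric(fs_ag))
  expect_gt(sum(fag != 0), 0)

  # fixtures are built to fit inside the default cylinder
  expect_equal(attr(fab, "coverage"), 1.0)
  expect_equal(attr(fag, "coverage"), 1.0)

  # empty interface is an error
  far <- make_complex(complex_recipe(seed = 22, contacts = c(any = 0),
                                     separation = 25))
  ann0 <- detect_epitope_paratope(far$structure,
                                  compute_sasa(far$structure))
  expect_error(protein_fingerprint("antibody", far$structure, ann0),
               "empty")
})

test_that("fingerprints are invariant under rigid motion of the complex", {
  fx <- the_fixture()
  st <- fx$cx$structure
  fab <- protein_fingerprint("antibody", st, fx$ann)
  fag <- protein_fingerprint("antigen", st, fx$ann)
  ep <- epif(st, fx$ann)
  set.seed(71)
  for (rep in 1:3) {
    R <- random_rotation(); t <- runif(3, -30, 30)
    st2 <- transform_structure(st, R, t)
    sasa2 <- compute_sasa(st2)
    ann2 <- detect_epitope_paratope(st2, sasa2)
    expect_setequal(ann2$epitope, fx$ann$epitope)
    fab2 <- protein_fingerprint("antibody", st2, ann2)
    fag2 <- protein_fingerprint("antigen", st2, ann2)
    ep2 <- epif(st2, ann2)
    expect_equal(as.numeric(fab2), as.numeric(fab), tolerance = 1e-6)
    expect_equal(as.numeric(fag2), as.numeric(fag), tolerance = 1e-6)
    expect_equal(as.numeric(ep2), as.numeric(ep), tolerance = 1e-6)
    # binary blocks are exactly equal
    expect_identical(as.numeric(fab2)[1:80], as.numeric(fab)[1:80])
  }
})

test_that("MLPD is the flattened outer product", {
  e <- function(i) { v <- numeric(110); v[i] <- 1; v }
  m <- mlpd_cross_term(e(3), e(7))
  expect_length(m, 12100)
  expect_equal(sum(m != 0), 1)
  # 0-based position i*110 + j for (i, j) = (2, 6)
  expect_equal(unname(which(m != 0)), 2 * 110 + 6 + 1)

  expect_true(all(mlpd_cross_term(numeric(110), e(1)) == 0))
  set.seed(73)
  a <- rnorm(110); b <- rnorm(110)
  m2 <- mlpd_cross_term(a, b)
  expect_equal(sum(m2), sum(a) * sum(b))  # distributivity oracle
  expect_error(mlpd_cross_term(a, rnorm(109)), "differ")
})
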