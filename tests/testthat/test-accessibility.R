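# standard_complex built directly from an atom table (for micro-geometries)
fake_sc <- function(mhc_xyz, pep_xyz, pep_resno = 308) {
  mk <- function(xyz, chain, resno0) {
    data.frame(chain = chain, resno = resno0 + seq_len(nrow(xyz)) - 1,
               insert = "", resname = "ALA", elety = "CB",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(mhc_xyz, "A", 10), mk(pep_xyz, "C", pep_resno))
  structure(list(atoms = atoms,
                 transform = list(rotation = diag(3),
                                  translation = c(0, 0, 0), rmsd = 0),
                 source = list(entry_id = "fake", chains = c("A", "B", "C"))),
            class = "standard_complex")
}

test_that("sphere points are unit, centered, deterministic, and guarded", {
  sp <- sphere_points(960)
  expect_equal(dim(sp), c(960, 3))
  expect_lt(max(abs(sqrt(rowSums(sp^2)) - 1)), 1e-12)
  expect_lt(max(abs(colMeans(sp))), 0.01)
  expect_identical(sp, sphere_points(960))
  expect_error(sphere_points(15), "at least 16")
})

test_that("SASA matches analytic values for isolated, paired and caged atoms", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.88)
  a1 <- compute_sasa(one)
  expect_equal(as.numeric(a1), 4 * pi * 3.28^2, tolerance = 0.005)
  # two identical intersecting spheres: spherical-cap closed form
  d <- 3.0; R <- 1.88 + 1.4
  two <- data.frame(x = c(0, d), y = 0, z = 0, radius = 1.88)
  a2 <- compute_sasa(two)
  cap <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_equal(as.numeric(a2), c(cap, cap), tolerance = 0.01 * cap)
  # an atom caged by 26 tight neighbours has zero accessible area
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 1.5
  cage <- data.frame(x = g[, 1], y = g[, 2], z = g[, 3], radius = 1.88)
  ctr <- which(rowSums(g^2) == 0)
  expect_equal(as.numeric(compute_sasa(cage)[ctr]), 0)
  expect_error(compute_sasa(data.frame(x = 0, y = 0, z = 0)),
               "typing error")
})

test_that("per-atom areas satisfy the additivity bound and occlusion monotonicity", {
  p <- make_pocket(12, seed = 9)
  at <- p$atoms
  a <- compute_sasa(at)
  expect_true(all(a >= 0))
  expect_true(all(a <= 4 * pi * (at$radius + 1.4)^2 + 1e-9))
  # removing an atom never decreases any other atom's area
  a_less <- compute_sasa(at[-1, ])
  expect_true(all(a_less >= a[-1] - 1e-9))
})

test_that("SASA agrees with a naive per-point reimplementation", {
  p <- make_pocket(8, seed = 5)
  expect_equal(as.numeric(compute_sasa(p$atoms, n_points = 240)),
               oracle_sasa(p$atoms, n_points = 240), tolerance = 1e-9)
})

test_that("groove extraction returns exactly the occluded cup atoms", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cup <- cbind(3 * cos(th), 3 * sin(th), 0)
  far <- rbind(c(25, 0, 0), c(0, 25, 0), c(0, 25, 5))
  occ <- matrix(c(0, 0, 1), 1)
  sc <- fake_sc(rbind(cup, far), occ)
  pocket <- groove_atoms(sc)
  expect_s3_class(pocket, "pm13_pocket")
  # oracle: SASA drop per MHC atom, recomputed naively
  mhc <- data.frame(x = c(cup[, 1], far[, 1]), y = c(cup[, 2], far[, 2]),
                    z = c(cup[, 3], far[, 3]),
                    radius = group_radius("C4H2"))
  both <- rbind(mhc, data.frame(x = 0, y = 0, z = 1,
                                radius = group_radius("C4H2")))
  drop <- oracle_sasa(mhc) - oracle_sasa(both)[seq_len(nrow(mhc))]
  expect_equal(sort(pocket$atoms$resno), sort((10:18)[drop > 0.1]))
  # no peptide atom is ever part of the pocket
  expect_true(all(pocket$atoms$chain %in% c("A", "B")))
})

test_that("a peptide far from the MHC yields an extraction error", {
  sc <- fake_sc(matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0), 3, byrow = TRUE),
                matrix(c(50, 50, 50), 1))
  expect_error(groove_atoms(sc), "extraction error")
})

test_that("sub-pockets are subsets of the whole groove and named by position", {
  pk <- fixture_pockets()
  key <- function(p) paste(p$atoms$chain, p$atoms$resno, p$atoms$elety)
  gk <- key(pk$whole)
  for (k in c("P1", "P4", "P6", "P7", "P9")) {
    expect_false(is.null(pk[[k]]), info = k)
    expect_true(all(key(pk[[k]]) %in% gk), info = k)
    expect_true(all(pk[[k]]$atoms$chain %in% c("A", "B")), info = k)
  }
  # single-call extraction agrees with the one-pass variant
  p4 <- subpocket_atoms(fixture_complex(), "P4")
  expect_equal(key(p4), key(pk$P4))
  # absent anchor residue is a named error
  sc <- fixture_complex()
  drop311 <- sc
  drop311$atoms <- sc$atoms[!(sc$atoms$chain == "C" &
                                sc$atoms$resno == 311), ]
  expect_error(subpocket_atoms(drop311, "P4"), "311")
})

test_that("P7 membership responds to the P7 side-chain orientation", {
  path <- file.path(tempdir(), "fx_p7.pdb")
  make_complex_pdb(path, p7_orientation = "across")
  raw <- parse_structure(path)
  sc_across <- standardize_complex(raw, identify_complexes(raw)[[1]])
  p7_away <- fixture_pockets()$P7
  p7_across <- subpocket_atoms(sc_across, "P7")
  key <- function(p) paste(p$atoms$chain, p$atoms$resno, p$atoms$elety)
  expect_false(setequal(key(p7_away), key(p7_across)))
})

test_that("membership decisions are stable under quadrature refinement", {
  sc <- fixture_complex()
  key <- function(p) paste(p$atoms$chain, p$atoms$resno, p$atoms$elety)
  g1 <- key(groove_atoms(sc, n_points = 960))
  g2 <- key(groove_atoms(sc, n_points = 1920))
  n_mhc <- sum(sc$atoms$chain %in% c("A", "B"))
  flipped <- length(setdiff(g1, g2)) + length(setdiff(g2, g1))
  expect_lte(flipped, ceiling(0.01 * n_mhc))
})

test_that("pocket TSV files round-trip", {
  p <- fixture_pockets()$P4
  path <- file.path(tempdir(), "p4.tsv")
  write_pocket(p, path)
  q <- read_pocket(path)
  expect_equal(q$kind, p$kind)
  expect_equal(q$atoms$type, p$atoms$type)
  expect_equal(q$atoms$x, p$atoms$x)
  expect_equal(compare_pockets(p, q)$pms_min, 1.0)
})
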