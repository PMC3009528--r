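# PDB line writer for hand-made micro-fixtures
pdb_line <- function(serial, name, alt, res, chain, resno, x, y, z,
                     occ = 1.0, rec = "ATOM  ", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(trimws(name), 1, 1)
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("%s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name4, alt, res, chain, resno, x, y, z, occ, 0,
          elesy)
}

test_that("parsing a generated fixture round-trips chains and atom counts", {
  path <- file.path(tempdir(), "fx_parse.pdb")
  make_complex_pdb(path)
  raw <- parse_structure(path)
  expect_s3_class(raw, "raw_structure")
  expect_setequal(unique(raw$atoms$chain), c("A", "B", "C"))
  n_res <- c(74, 87, 13)
  n_gly <- c(sum(reference_frame()$alpha$resname == "GLY"),
             sum(reference_frame()$beta$resname == "GLY"), 0)
  expect_equal(as.vector(table(raw$atoms$chain)[c("A", "B", "C")]),
               5 * n_res - n_gly)  # N,CA,C,O,CB minus missing GLY CB
})

test_that("altloc keeps the highest-occupancy conformer, hydrogens and waters drop", {
  path <- file.path(tempdir(), "fx_altloc.pdb")
  writeLines(c(
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "A", "ALA", "A", 1, 1.5, 0, 0, occ = 0.6),
    pdb_line(3, "CA", "B", "ALA", "A", 1, 9.9, 0, 0, occ = 0.4),
    pdb_line(4, "HA", " ", "ALA", "A", 1, 2, 1, 0, elesy = " H"),
    pdb_line(5, "O", " ", "HOH", "W", 1, 8, 8, 8, rec = "HETATM"),
    "END"), path)
  raw <- parse_structure(path)
  expect_equal(nrow(raw$atoms), 2)  # N + one CA; no H, no water
  ca <- raw$atoms[raw$atoms$elety == "CA", ]
  expect_equal(ca$x, 1.5)
  # occupancy tie falls back to altloc label order
  writeLines(c(pdb_line(1, "CA", "B", "ALA", "A", 1, 9.9, 0, 0, occ = 0.5),
               pdb_line(2, "CA", "A", "ALA", "A", 1, 1.5, 0, 0, occ = 0.5),
               "END"), path)
  expect_equal(parse_structure(path)$atoms$x, 1.5)
})

test_that("degenerate files raise input/format errors", {
  path <- file.path(tempdir(), "fx_bad.pdb")
  writeLines(c(pdb_line(1, "O", " ", "HOH", "W", 1, 0, 0, 0, rec = "HETATM"),
               "END"), path)
  expect_error(parse_structure(path), "no protein heavy atoms")
  writeLines("REMARK nothing here", path)
  expect_error(parse_structure(path), "no ATOM records")
  bad <- pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0)
  substr(bad, 31, 38) <- "  xx.yyy"
  writeLines(c(bad, "END"), path)
  expect_error(parse_structure(path), "line 1")
  expect_error(parse_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("complex identification finds one triple per copy and validates overrides", {
  path <- file.path(tempdir(), "fx_id.pdb")
  make_complex_pdb(path)
  raw <- parse_structure(path)
  specs <- identify_complexes(raw)
  expect_length(specs, 1)
  expect_equal(unlist(specs[[1]][c("alpha", "beta", "peptide")]),
               c(alpha = "A", beta = "B", peptide = "C"))
  make_complex_pdb(path, n_copies = 2)
  specs2 <- identify_complexes(parse_structure(path))
  expect_length(specs2, 2)
  expect_equal(specs2[[2]]$alpha, "D")
  # explicit spec is validated and returned as-is
  sp <- complex_spec("D", "E", "F")
  expect_identical(identify_complexes(parse_structure(path), spec = sp),
                   list(sp))
  expect_error(identify_complexes(raw, spec = complex_spec("A", "B", "Z")),
               "not in structure")
})

test_that("single-chain structures trigger a detection error", {
  path <- file.path(tempdir(), "fx_single.pdb")
  writeLines(c(pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", " ", "ALA", "A", 2, 3.8, 0, 0),
               "END"), path)
  expect_error(identify_complexes(parse_structure(path)),
               "detection error")
})

test_that("domain alignment maps identity, deletions, and matches the DP oracle", {
  ref <- reference_frame()$alpha_seq
  m <- align_domain_sequence(ref, ref)
  expect_equal(m, seq_len(nchar(ref)), ignore_attr = TRUE)
  expect_equal(attr(m, "identity"), 1)
  # delete one internal residue from the query: exactly that reference
  # position is skipped, all others map
  del <- 30
  q <- paste0(substr(ref, 1, del - 1), substr(ref, del + 1, nchar(ref)))
  md <- align_domain_sequence(q, ref)
  expect_equal(stats::na.omit(as.vector(md)),
               setdiff(seq_len(nchar(ref)), del), ignore_attr = TRUE)
  expect_true(all(diff(stats::na.omit(md)) > 0))  # strictly increasing
  expect_error(align_domain_sequence("ACDEFGHIKL", ref), "precondition")
})

test_that("alignment score is optimal against an exhaustive DP oracle", {
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:20) {
    r <- paste(sample(aa, 34, replace = TRUE), collapse = "")
    # mutate + indel the query
    q <- strsplit(r, "")[[1]]
    q[sample(34, 4)] <- sample(aa, 4, replace = TRUE)
    ndel <- sample(0:2, 1)
    if (ndel > 0) q <- q[-sample(34, ndel)]
    q <- paste(q, collapse = "")
    m <- suppressWarnings(align_domain_sequence(q, r))
    expect_equal(mapping_alignment_score(m, q, r),
                 oracle_global_alignment_score(q, r), info = k)
  }
})

test_that("Kabsch superposition recovers exact and noisy transforms", {
  set.seed(21)
  X <- matrix(rnorm(30), ncol = 3)
  tf <- kabsch_superpose(X, X)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
  # 90 degree rotation about z plus a shift
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  Y <- sweep(X %*% Rz, 2, c(1, 2, 3), "+")
  tf2 <- kabsch_superpose(X, Y)
  expect_equal(tf2$rotation, Rz, tolerance = 1e-8)
  expect_equal(apply_transform(X, tf2), Y, tolerance = 1e-8)
  expect_equal(det(tf2$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(X, Y[1:5, ]), "differ in length")
})

test_that("Kabsch RMSD equals a brute-force rotational minimization", {
  set.seed(22)
  X <- matrix(rnorm(15), ncol = 3)
  Y <- X %*% rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)) +
    matrix(rnorm(15, sd = 0.3), ncol = 3)
  expect_equal(kabsch_superpose(X, Y)$rmsd, oracle_superpose_rmsd(X, Y),
               tolerance = 1e-4)
})

test_that("standardization renumbers to the reference ranges and trims peptides", {
  sc <- fixture_complex()
  a_pos <- unique(sc$atoms$resno[sc$atoms$chain == "A"])
  b_pos <- unique(sc$atoms$resno[sc$atoms$chain == "B"])
  c_pos <- unique(sc$atoms$resno[sc$atoms$chain == "C"])
  expect_length(a_pos, 74); expect_true(all(a_pos %in% 5:78))
  expect_length(b_pos, 87); expect_true(all(b_pos %in% 5:91))
  expect_length(c_pos, 13); expect_true(all(c_pos %in% 308:320))
  expect_setequal(unique(sc$atoms$chain), c("A", "B", "C"))
  expect_equal(det(sc$transform$rotation), 1, tolerance = 1e-9)
  # a 20-residue peptide is trimmed to the 13 reference positions
  path <- file.path(tempdir(), "fx_pep20.pdb")
  make_complex_pdb(path, peptide_length = 20)
  raw <- parse_structure(path)
  sc20 <- standardize_complex(raw, identify_complexes(raw)[[1]])
  expect_length(unique(sc20$atoms$resno[sc20$atoms$chain == "C"]), 13)
})

test_that("a peptide far from the groove fails standardization", {
  path <- file.path(tempdir(), "fx_far.pdb")
  make_complex_pdb(path, peptide_offset = c(0, 0, 50))
  raw <- parse_structure(path)
  expect_error(standardize_complex(raw, identify_complexes(raw)[[1]]),
               "no peptide residue")
})

test_that("standardization is idempotent and invariant to input frame", {
  sc <- fixture_complex()
  again <- structure(list(entry_id = "again", atoms = sc$atoms),
                     class = "raw_structure")
  sc2 <- standardize_complex(again, complex_spec("A", "B", "C"))
  expect_equal(max(abs(sc2$transform$rotation - diag(3))), 0,
               tolerance = 1e-6)
  expect_equal(sc2$atoms$resno, sc$atoms$resno)
  expect_equal(sc2$atoms$chain, sc$atoms$chain)
  # arbitrary rigid motion of the input does not move the output
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  rot <- sc$atoms
  rot[, c("x", "y", "z")] <- as.matrix(rot[, c("x", "y", "z")]) %*% R +
    matrix(c(10, -4, 7), nrow(rot), 3, byrow = TRUE)
  sc3 <- standardize_complex(
    structure(list(entry_id = "rot", atoms = rot), class = "raw_structure"),
    complex_spec("A", "B", "C"))
  expect_equal(as.matrix(sc3$atoms[, c("x", "y", "z")]),
               as.matrix(sc$atoms[, c("x", "y", "z")]), tolerance = 1e-6)
})

test_that("peptide assignment is injective and order-preserving", {
  sc <- fixture_complex()
  pep <- sc$atoms[sc$atoms$chain == "C" & sc$atoms$elety == "CA", ]
  expect_false(any(duplicated(pep$resno)))
  expect_true(all(diff(pep$resno) > 0))
})

test_that("standard PDB output round-trips and stays within reference ranges", {
  sc <- fixture_complex()
  out <- file.path(tempdir(), "fx_out.pdb")
  write_standard_pdb(sc, out)
  back <- parse_structure(out)
  expect_equal(back$atoms$resno, sc$atoms$resno)
  expect_equal(back$atoms$chain, sc$atoms$chain)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(sc$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
  a <- back$atoms
  expect_true(all(a$resno[a$chain == "A"] %in% 5:78))
  expect_true(all(a$resno[a$chain == "B"] %in% 5:91))
  expect_true(all(a$resno[a$chain == "C"] %in% 308:320))
  # refuse to write a complex with no peptide
  nop <- sc
  nop$atoms <- nop$atoms[nop$atoms$chain != "C", ]
  expect_error(write_standard_pdb(nop, out), "empty peptide")
})
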