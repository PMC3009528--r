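# Synthetic fixtures: bare typed point-cloud pockets, and small valid PDB
# files with an MHC-like two-helix groove plus a short peptide, so the whole
# pipeline (parse -> identify -> standardize -> pockets -> compare) runs
# without any downloaded structure. Geometry is deliberately schematic
# (backbone + CB only); physical realism is a non-goal.

# the two flanking helical "rails" and the central extended peptide define
# both the fixture complexes and the packaged reference frame
.rail_ca <- function(n, y_axis) {
  i <- seq_len(n)
  x <- -((n - 1) * 1.5) / 2 + (i - 1) * 1.5
  th <- i * 100 * pi / 180
  cbind(x = x, y = y_axis + 2.3 * cos(th), z = 2.3 * sin(th))
}

.peptide_ca <- function(n) {
  i <- seq_len(n)
  cbind(x = (i - (n + 1) / 2) * 3.5, y = rep(0, n), z = rep(0, n))
}

.seq_to_resnames <- function(seq) {
  bio3d::aa123(strsplit(seq, "")[[1]])
}

# backbone (+CB) atoms for one chain given its Calpha trace.
# side: "alpha" (CB points to -y), "beta" (CB to +y), "peptide" (CB along z,
# alternating sign; cb_override replaces the unit CB direction per residue).
.chain_atoms <- function(ca, resnames, chain, side, cb_override = NULL) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- ca[i, ]
    if (side == "peptide") {
      nn <- p + c(-1.25, 0.35, 0); cc <- p + c(1.25, 0.35, 0)
      cb_dir <- c(0, 0, 1.53 * (-1)^(i + 1))
    } else {
      nn <- p + c(-1.25, 0, 0.35); cc <- p + c(1.25, 0, 0.35)
      cb_dir <- c(0, if (side == "alpha") -1.0 else 1.0, -0.3)
    }
    if (!is.null(cb_override) && !is.null(cb_override[[i]])) {
      cb_dir <- cb_override[[i]]
    }
    oo <- cc + c(0, 0, 1.2)
    at <- rbind(N = nn, CA = p, C = cc, O = oo)
    if (resnames[i] != "GLY") at <- rbind(at, CB = p + cb_dir)
    rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                            resname = resnames[i], elety = rownames(at),
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            o = 1, b = 0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# full synthetic complex in the reference frame
.groove_backbone <- function(ref = reference_frame(), peptide_length = 13,
                             p7_orientation = "away",
                             peptide_offset = c(0, 0, 0)) {
  a_ca <- .rail_ca(nrow(ref$alpha), 5.8)
  b_ca <- .rail_ca(nrow(ref$beta), -5.8)
  p_ca <- sweep(.peptide_ca(peptide_length), 2, peptide_offset, "+")
  pep_names <- if (peptide_length == 13) {
    ref$peptide$resname
  } else if (peptide_length < 13) {
    ref$peptide$resname[seq_len(peptide_length)]
  } else {
    extra <- peptide_length - 13
    pre <- floor(extra / 2)
    c(rep("GLY", pre), ref$peptide$resname, rep("GLY", extra - pre))
  }
  cb_override <- NULL
  if (p7_orientation == "across" && peptide_length == 13) {
    cb_override <- vector("list", 13)
    cb_override[[7]] <- c(0, -2.1, 0.4)  # P7 side chain across the groove
  }
  rbind(.chain_atoms(a_ca, ref$alpha$resname, "A", "alpha"),
        .chain_atoms(b_ca, ref$beta$resname, "B", "beta"),
        .chain_atoms(p_ca, pep_names, "C", "peptide", cb_override))
}

#' Generate a random typed point-cloud pocket
#'
#' Uniform rejection sampling in a cube with a minimum inter-atom separation
#' of 1.5 Angstrom; group types drawn from a palette. Deterministic for a
#' given seed.
#'
#' @param n_atoms Number of atoms (>= 3).
#' @param seed Integer seed.
#' @param types Palette of group types to sample from.
#' @param min_dist Minimum pairwise distance (Angstrom).
#' @return A `pm13_pocket` of kind `"synthetic"`.
#' @export
make_pocket <- function(n_atoms, seed = 1L, types = group_types(),
                        min_dist = 1.5) {
  if (n_atoms < 3) stop("fixture error: need at least 3 atoms", call. = FALSE)
  set.seed(seed)
  side <- max(8, ceiling(n_atoms^(1 / 3)) * 3.2)
  xyz <- matrix(NA_real_, n_atoms, 3)
  placed <- 0L
  for (attempt in seq_len(500L * n_atoms)) {
    cand <- stats::runif(3, 0, side)
    if (placed == 0L ||
        min(sqrt(colSums((t(xyz[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= min_dist) {
      placed <- placed + 1L
      xyz[placed, ] <- cand
      if (placed == n_atoms) break
    }
  }
  if (placed < n_atoms) {
    stop("fixture error: could not pack ", n_atoms, " atoms at min distance ",
         min_dist, call. = FALSE)
  }
  type <- sample(types, n_atoms, replace = TRUE)
  atoms <- data.frame(chain = "A", resno = seq_len(n_atoms), resname = "UNK",
                      elety = "X", type = type, radius = group_radius(type),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  .new_pocket("synthetic", atoms, sprintf("make_pocket(seed=%d)", seed))
}

#' Write a synthetic MHC-like complex as a PDB file
#'
#' Builds a schematic complex in the reference frame — a 74-residue
#' alpha-like helical rail, an 87-residue beta-like rail (both carrying the
#' reference domain sequences, backbone + CB atoms) and a peptide threaded
#' between them — and writes it in PDB format. The default complex passes the
#' full parse/identify/standardize/groove pipeline with a non-empty groove.
#'
#' @param path Output PDB path.
#' @param peptide_length Peptide residues (13 matches the reference; longer
#'   peptides gain glycine flanks which standardization trims away).
#' @param n_copies 1 or 2; a second copy (chains D/E/F) is shifted 60
#'   Angstrom along z, emulating two molecules per asymmetric unit.
#' @param peptide_offset Rigid offset applied to the peptide only (e.g.
#'   `c(0, 0, 50)` to detach it from the groove).
#' @param p7_orientation `"away"` (side chain points out of the groove) or
#'   `"across"` (toward the beta rail); only the P7 residue is affected.
#' @param jitter SD (Angstrom) of Gaussian coordinate noise, seeded.
#' @param seed Seed for `jitter`.
#' @return `path`, invisibly.
#' @export
make_complex_pdb <- function(path, peptide_length = 13, n_copies = 1,
                             peptide_offset = c(0, 0, 0),
                             p7_orientation = c("away", "across"),
                             jitter = 0, seed = 1L) {
  p7_orientation <- match.arg(p7_orientation)
  stopifnot(peptide_length >= 9, n_copies %in% 1:2)
  at <- .groove_backbone(peptide_length = peptide_length,
                         p7_orientation = p7_orientation,
                         peptide_offset = peptide_offset)
  if (n_copies == 2) {
    at2 <- at
    at2$chain <- c(A = "D", B = "E", C = "F")[at2$chain]
    at2$z <- at2$z + 60
    at <- rbind(at, at2)
  }
  if (jitter > 0) {
    set.seed(seed)
    at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(at), sd = jitter), ncol = 3)
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain, resid = at$resname,
                   elety = at$elety, o = at$o, b = at$b)
  invisible(path)
}
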