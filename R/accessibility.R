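# Solvent-accessible surface area (Shrake-Rupley quadrature with a
# deterministic spherical point set) and occlusion-based pocket definition:
# the binding groove is the set of MHC atoms whose accessibility to a 1.4 A
# probe drops when the peptide is present; sub-pockets use a single peptide
# residue as the occluder.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-angle (Fibonacci) spiral construction; no randomness, so SASA
#' values are exactly reproducible.
#'
#' @param n Number of points (>= 16).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 16) stop("input error: need at least 16 sphere points",
                   call. = FALSE)
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * k * (1 - 1 / ((1 + sqrt(5)) / 2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley scheme: each atom's sphere is expanded by the probe radius
#' and sampled with a deterministic point set; the accessible area is the
#' fraction of sample points not inside any other expanded sphere, times the
#' expanded sphere's area.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` and `radius` (Angstrom);
#'   typically pocket or complex atoms typed via [assign_group_type()] with
#'   [group_radius()].
#' @param probe Probe sphere radius in Angstrom (water: 1.4).
#' @param n_points Sample points per atom.
#' @param subset Optional integer indices: compute areas only for these atoms
#'   (still occluded by all atoms); others are returned as NA.
#' @return Numeric vector of areas (Angstrom^2) with attributes `probe` and
#'   `n_points`.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960, subset = NULL) {
  n <- nrow(atoms)
  if (is.null(n) || n < 1) stop("input error: no atoms", call. = FALSE)
  if (!"radius" %in% names(atoms) || anyNA(atoms$radius)) {
    stop("typing error: missing radius for one or more atoms", call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$radius + probe
  sp <- sphere_points(n_points)
  if (is.null(subset)) subset <- seq_len(n)
  area <- rep(NA_real_, n)
  for (i in subset) {
    Ri <- R[i]
    if (n > 1) {
      d2 <- colSums((t(xyz) - xyz[i, ])^2)
      nb <- which(d2 < (Ri + R)^2 & seq_len(n) != i)
    } else nb <- integer(0)
    if (!length(nb)) {
      area[i] <- 4 * pi * Ri^2
      next
    }
    pts <- sweep(sp * Ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dx <- pts[free, 1] - xyz[j, 1]
      dy <- pts[free, 2] - xyz[j, 2]
      dz <- pts[free, 3] - xyz[j, 3]
      free[free] <- dx * dx + dy * dy + dz * dz >= R[j]^2
    }
    area[i] <- 4 * pi * Ri^2 * sum(free) / n_points
  }
  attr(area, "probe") <- probe
  attr(area, "n_points") <- n_points
  area
}

# typed atom table (adds group type + radius) for selected chains of a
# standard complex; lenient mode drops untypable atoms with a warning
.typed_atoms <- function(sc, chains, lenient = FALSE) {
  a <- sc$atoms[sc$atoms$chain %in% chains, , drop = FALSE]
  a$type <- assign_group_type(a$resname, a$elety, lenient = lenient)
  if (lenient && anyNA(a$type)) a <- a[!is.na(a$type), , drop = FALSE]
  a$radius <- group_radius(a$type)
  rownames(a) <- NULL
  a
}

.new_pocket <- function(kind, atoms, source) {
  structure(list(kind = kind, atoms = atoms, source = source),
            class = "pm13_pocket")
}

#' @export
print.pm13_pocket <- function(x, ...) {
  cat("pm13_pocket [", x$kind, "] -", nrow(x$atoms), "typed atoms from",
      x$source, "\n")
  invisible(x)
}

# occlusion rule shared by groove and sub-pocket extraction: an MHC atom is in
# the pocket iff its SASA drops by more than epsilon when the occluder atoms
# are added. Only atoms near an occluder can change, so only those are
# recomputed in the bound state.
.occlusion_pocket <- function(mhc, occ, kind, source, epsilon, probe,
                              n_points, free_area = NULL) {
  if (is.null(free_area)) {
    free_area <- compute_sasa(mhc, probe = probe, n_points = n_points)
  }
  xyz_m <- as.matrix(mhc[, c("x", "y", "z")])
  xyz_o <- as.matrix(occ[, c("x", "y", "z")])
  reach <- outer(mhc$radius, occ$radius, "+") + 2 * probe
  near <- which(vapply(seq_len(nrow(mhc)), function(i) {
    d2 <- colSums((t(xyz_o) - xyz_m[i, ])^2)
    any(d2 < reach[i, ]^2)
  }, TRUE))
  drop <- rep(0, nrow(mhc))
  if (length(near)) {
    both <- rbind(mhc, occ)
    bound_area <- compute_sasa(both, probe = probe, n_points = n_points,
                               subset = near)
    drop[near] <- free_area[near] - bound_area[near]
  }
  keep <- drop > epsilon
  if (sum(keep) < 3) {
    stop("extraction error: ", kind, " pocket has fewer than 3 atoms ",
         "(peptide does not occlude the MHC surface)", call. = FALSE)
  }
  .new_pocket(kind, mhc[keep, , drop = FALSE], source)
}

#' Extract the whole binding groove of a standardized complex
#'
#' MHC atoms (chains A/B) whose solvent accessibility is reduced by more than
#' `epsilon` by the presence of the peptide (chain C).
#'
#' @param sc A `standard_complex`.
#' @param epsilon Inclusion threshold on the SASA drop (Angstrom^2). The
#'   occlusion criterion is a reduction in accessibility; a small positive
#'   threshold keeps the decision stable against quadrature noise.
#' @param probe Probe radius (Angstrom).
#' @param n_points SASA sample points per atom.
#' @param lenient Drop untypable atoms instead of failing.
#' @return A `pm13_pocket` of kind `"whole"`.
#' @export
groove_atoms <- function(sc, epsilon = 0.1, probe = 1.4, n_points = 960,
                         lenient = FALSE) {
  stopifnot(inherits(sc, "standard_complex"))
  mhc <- .typed_atoms(sc, c("A", "B"), lenient = lenient)
  pep <- .typed_atoms(sc, "C", lenient = lenient)
  if (nrow(pep) == 0) stop("extraction error: empty peptide", call. = FALSE)
  .occlusion_pocket(mhc, pep, "whole", sc$source$entry_id, epsilon, probe,
                    n_points)
}

#' Extract one sub-pocket of the binding groove
#'
#' MHC atoms whose accessibility is reduced by the presence of the single
#' peptide residue anchoring the sub-pocket (P1 at position 308, P4 at 311,
#' P6 at 313, P7 at 314, P9 at 316). The other peptide residues take no part
#' in the calculation.
#'
#' @param sc A `standard_complex`.
#' @param which One of `"P1"`, `"P4"`, `"P6"`, `"P7"`, `"P9"`.
#' @inheritParams groove_atoms
#' @return A `pm13_pocket` of the requested kind.
#' @export
subpocket_atoms <- function(sc, which, epsilon = 0.1, probe = 1.4,
                            n_points = 960, lenient = FALSE) {
  stopifnot(inherits(sc, "standard_complex"))
  pos_map <- subpocket_positions()
  which <- match.arg(which, names(pos_map))
  pos <- pos_map[[which]]
  mhc <- .typed_atoms(sc, c("A", "B"), lenient = lenient)
  pep <- .typed_atoms(sc, "C", lenient = lenient)
  occ <- pep[pep$resno == pos, , drop = FALSE]
  if (nrow(occ) == 0) {
    stop("missing-residue error: peptide position ", pos, " (", which,
         ") absent from this complex", call. = FALSE)
  }
  .occlusion_pocket(mhc, occ, which, sc$source$entry_id, epsilon, probe,
                    n_points)
}

#' Extract the whole groove and all sub-pockets in one pass
#'
#' Computes the unbound MHC surface once and reuses it for the whole-groove
#' and the five sub-pocket extractions. Sub-pockets whose anchoring peptide
#' residue is missing, or whose occlusion set is too small to score, are
#' reported as `NULL`.
#'
#' @inheritParams groove_atoms
#' @param which Pocket kinds to extract.
#' @return Named list of `pm13_pocket` (or `NULL`) per requested kind.
#' @export
extract_pockets <- function(sc, which = c("whole", "P1", "P4", "P6", "P7",
                                          "P9"),
                            epsilon = 0.1, probe = 1.4, n_points = 960,
                            lenient = FALSE) {
  stopifnot(inherits(sc, "standard_complex"))
  which <- match.arg(which, several.ok = TRUE)
  mhc <- .typed_atoms(sc, c("A", "B"), lenient = lenient)
  pep <- .typed_atoms(sc, "C", lenient = lenient)
  if (nrow(pep) == 0) stop("extraction error: empty peptide", call. = FALSE)
  free_area <- compute_sasa(mhc, probe = probe, n_points = n_points)
  pos_map <- subpocket_positions()
  out <- stats::setNames(vector("list", length(which)), which)
  for (w in which) {
    occ <- if (w == "whole") pep else pep[pep$resno == pos_map[[w]], ,
                                          drop = FALSE]
    if (nrow(occ) == 0) next
    out[[w]] <- tryCatch(
      .occlusion_pocket(mhc, occ, w, sc$source$entry_id, epsilon, probe,
                        n_points, free_area = free_area),
      error = function(e) NULL)
  }
  out
}

#' Write a pocket as a TSV table
#'
#' Plain-text sidecar format: one typed atom per row with provenance,
#' group type, radius and coordinates.
#'
#' @param pocket A `pm13_pocket`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pocket <- function(pocket, path) {
  stopifnot(inherits(pocket, "pm13_pocket"))
  hdr <- sprintf("# pm13 pocket kind=%s source=%s", pocket$kind,
                 pocket$source)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  cols <- c("chain", "resno", "resname", "elety", "type", "radius",
            "x", "y", "z")
  utils::write.table(pocket$atoms[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pocket written by [write_pocket()]
#'
#' @param path Path to a pocket TSV.
#' @return A `pm13_pocket`.
#' @export
read_pocket <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub(".*kind=(\\S+).*", "\\1", first)
  source <- sub(".*source=(\\S+).*", "\\1", first)
  atoms <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                             stringsAsFactors = FALSE)
  .new_pocket(kind, atoms, source)
}
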