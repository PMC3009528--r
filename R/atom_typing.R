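# ProtOr atomic group typing: each heavy atom plus its bonded hydrogens is one
# group, typed by element, total covalent connectivity and hydrogen count.

.pm13 <- new.env(parent = emptyenv())

#' The 13 ProtOr atomic group type labels
#'
#' Heavy atoms of the 20 standard amino acids are classified into 13 united-atom
#' group types. Each label encodes the heavy-atom element, its total covalent
#' connectivity and the number of attached hydrogens (e.g. `C4H3` is a
#' tetravalent carbon carrying three hydrogens — a methyl group).
#'
#' @return Character vector of the 13 group labels, in canonical order.
#' @export
#' @examples
#' group_types()
group_types <- function() {
  c("C3H0", "C3H1", "C4H1", "C4H2", "C4H3",
    "N3H0", "N3H1", "N3H2", "N4H3",
    "O1H0", "O2H1", "S2H0", "S2H1")
}

#' The ProtOr typing table
#'
#' Reads the plain-text asset mapping every heavy atom of the 20 standard
#' residues (including backbone and the C-terminal OXT) to its group type and
#' united-atom radius. The asset ships with the package so users can audit or
#' extend the assignments.
#'
#' @return A data.frame with columns `residue`, `atom`, `group`, `radius`.
#' @export
typing_table <- function() {
  if (is.null(.pm13$typing)) {
    path <- system.file("extdata", "protor_typing.tsv", package = "pm13",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(setequal(unique(tab$group), group_types()))
    .pm13$typing <- tab
    .pm13$typing_key <- paste(tab$residue, tab$atom)
    radii <- tab$radius[!duplicated(tab$group)]
    names(radii) <- tab$group[!duplicated(tab$group)]
    .pm13$radii <- radii[group_types()]
  }
  .pm13$typing
}

# residue-name aliases for common modified residues (lenient mode)
.residue_aliases <- c(MSE = "MET")

#' Assign a ProtOr group type to a heavy atom
#'
#' Deterministic lookup of the group type for a (residue name, atom name) pair
#' under PDB v3 nomenclature. Protonation-dependent atoms (HIS ring nitrogens,
#' chain termini) use the table's single fixed assignment.
#'
#' @param residue_name Three-letter residue code, upper case (e.g. `"ALA"`).
#' @param atom_name PDB atom name, upper case (e.g. `"CB"`). Vectorized over
#'   both arguments.
#' @param lenient If `TRUE`, unknown pairs yield `NA` with a warning instead of
#'   an error, and the alias map (e.g. MSE to MET) is applied.
#' @return Character vector of group labels (see [group_types()]).
#' @export
#' @examples
#' assign_group_type("ALA", "CB")   # "C4H3"
#' assign_group_type("LYS", "NZ")   # "N4H3"
assign_group_type <- function(residue_name, atom_name, lenient = FALSE) {
  typing_table()
  res <- toupper(residue_name)
  if (lenient) {
    hit <- res %in% names(.residue_aliases)
    res[hit] <- .residue_aliases[res[hit]]
  }
  key <- paste(res, toupper(atom_name))
  idx <- match(key, .pm13$typing_key)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    if (!lenient) {
      stop("no ProtOr group type for atom(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping untypable atom(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
  }
  .pm13$typing$group[idx]
}

#' ProtOr united-atom radius of a group type
#'
#' @param gt Group type label(s), see [group_types()].
#' @return Radius in Angstrom.
#' @export
#' @examples
#' group_radius("C4H3")
group_radius <- function(gt) {
  typing_table()
  r <- .pm13$radii[gt]
  if (anyNA(r)) {
    stop("unknown group type: ", paste(unique(gt[is.na(r)]), collapse = ", "),
         call. = FALSE)
  }
  unname(r)
}
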