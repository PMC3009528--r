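# Common reference frame for standardization.
#
# All complexes are renumbered and superposed onto a single reference binding
# domain: alpha-1 positions 5-78 (chain A), beta-1 positions 5-91 (chain B) and
# a 13-residue peptide at harmonized positions 308-320 (chain C), so that
# P1 = 308, P4 = 311, P6 = 313, P7 = 314 and P9 = 316. The shipped asset
# carries the HLA-DR1 binding-domain sequences together with SYNTHETIC
# Calpha coordinates (a constructed two-helix groove; see the methods
# vignette) — filename marks it as synthetic.

#' The packaged reference frame
#'
#' Loads the reference binding domain used for renumbering and superposition:
#' per-position chain, reference residue number, residue name and Calpha
#' coordinates for the alpha-1 domain (chain A, positions 5-78), the beta-1
#' domain (chain B, positions 5-91) and the 13-residue reference peptide
#' (chain C, positions 308-320). Coordinates in the shipped asset are
#' synthetic (a constructed groove in a fixed frame); sequences are those of
#' the HLA-DR1 binding domain.
#'
#' @return An object of class `pm13_reference`: a list with data.frames
#'   `alpha`, `beta`, `peptide` (columns `pos`, `resname`, `x`, `y`, `z`) and
#'   one-letter sequence strings `alpha_seq`, `beta_seq`, `peptide_seq`.
#' @export
reference_frame <- function() {
  if (is.null(.pm13$reference)) {
    path <- system.file("extdata", "reference_frame_synthetic.tsv",
                        package = "pm13", mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    split_chain <- function(ch) {
      d <- tab[tab$chain == ch, c("pos", "resname", "x", "y", "z")]
      rownames(d) <- NULL
      d
    }
    ref <- list(alpha = split_chain("A"), beta = split_chain("B"),
                peptide = split_chain("C"))
    ref$alpha_seq <- paste(bio3d::aa321(ref$alpha$resname), collapse = "")
    ref$beta_seq <- paste(bio3d::aa321(ref$beta$resname), collapse = "")
    ref$peptide_seq <- paste(bio3d::aa321(ref$peptide$resname), collapse = "")
    class(ref) <- "pm13_reference"
    .pm13$reference <- ref
  }
  .pm13$reference
}

#' Peptide positions anchoring the five sub-pockets
#'
#' The groove's P1/P4/P6/P7/P9 sub-pockets are defined by occlusion from the
#' peptide residue at a fixed harmonized position: P1 at 308, P4 at 311,
#' P6 at 313, P7 at 314 and P9 at 316.
#'
#' @return Named integer vector mapping sub-pocket name to peptide residue
#'   number in the reference frame.
#' @export
#' @examples
#' subpocket_positions()[["P4"]]  # 311
subpocket_positions <- function() {
  c(P1 = 308L, P4 = 311L, P6 = 313L, P7 = 314L, P9 = 316L)
}
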