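Package: pm13
Title: Alignment-Free Comparison of MHC Class II Peptide-Binding Grooves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the peptide-binding grooves of MHC class II
    molecules directly from their three-dimensional structures. Complexes are
    standardized into a common reference frame (chain relabelling, residue
    renumbering, rigid-body superposition), binding grooves and the P1, P4,
    P6, P7 and P9 sub-pockets are extracted as the MHC atoms whose solvent
    accessibility (1.4 Angstrom probe, ProtOr group radii) is reduced by the
    bound peptide, and pockets are compared with an alignment-free descriptor:
    all intra-site distances partitioned into 91 sorted lists keyed by
    unordered pairs of 13 atomic group types, scored by threshold alignment
    (PMSMin and PMSMax). Includes neighbour-joining cladograms of score
    matrices, score histograms, perturbation sensitivity analysis, and a
    synthetic fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
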