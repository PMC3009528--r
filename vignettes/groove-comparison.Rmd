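---
title: "Comparing MHC class II binding grooves with pm13"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing MHC class II binding grooves with pm13}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm13)
```

## The problem

MHC class II molecules present exogenous peptides to T cells. Their
peptide-binding domain is an open groove formed jointly by the alpha-1 and
beta-1 domains, with depressions — the P1, P4, P6, P7 and P9 sub-pockets —
that accommodate the peptide's anchor side chains. Which peptides an allele
binds is largely decided by the shape and chemistry of these pockets, so a
quantitative, automatic way to compare grooves and sub-pockets across many
crystal structures (and comparative models) is the basis for classifying
alleles structurally, spotting unexpected similarities between different
alleles, and rationalizing disease associations.

`pm13` implements such a comparison pipeline: structures are standardized
into a common reference frame, pockets are defined by solvent-accessibility
occlusion, and pockets are compared with an alignment-free sorted-distance
descriptor scored by threshold matching. Score matrices feed
neighbour-joining cladograms and score histograms.

## Standardization

Crystal structures of MHC-peptide complexes use arbitrary chain identifiers
and numbering. `standardize_complex()` maps every complex onto one frame:

* chains are relabelled A (alpha-1), B (beta-1), C (peptide);
* each domain is renumbered by global sequence alignment
  (Needleman–Wunsch; match +1, mismatch 0, gap −1) against the packaged
  reference profiles, and trimmed to reference positions 5–78 (alpha-1) and
  5–91 (beta-1);
* the complex is superposed onto the reference by a Kabsch fit over the
  mapped Cα pairs of both domains jointly;
* peptide residues are assigned to the 13 harmonized peptide positions
  308–320 by nearest reference Cα, under an order-consistent injective
  assignment (a small dynamic program maximizing assignments, then
  minimizing total distance, with a 6 Å cutoff per assignment); unassigned
  residues are removed. Position 308 is P1, 311 P4, 313 P6, 314 P7, 316 P9.

Renumbering by *sequence* alignment is a design choice: the alpha-1/beta-1
domains are gap-free and highly conserved across the family, so sequence and
structure alignment give the same correspondence while the former is
deterministic and dependency-free. The nearest-Cα peptide register handles
engineered or covalently linked peptides and non-standard numbering.

The reference asset shipped with the package carries the HLA-DR1
binding-domain sequences with *synthetic* Cα coordinates (a constructed
two-helix groove in a fixed frame; the filename says so). Because every
complex is aligned to the same reference, only internal consistency of this
asset matters for comparisons, not crystallographic accuracy; users wanting
the published frame can regenerate the asset from a reference structure.

Standardization is idempotent and the output is invariant to any rigid
motion of the input — both properties are asserted in the test suite.

## Atom typing and pocket definition

Each heavy atom (hydrogens are dropped; the typing encodes them) of the 20
standard residues is assigned one of 13 ProtOr united-atom group types,
labelled by element, total covalent connectivity and attached-hydrogen count:
C3H0, C3H1, C4H1, C4H2, C4H3, N3H0, N3H1, N3H2, N4H3, O1H0, O2H1, S2H0,
S2H1. Group radii are the ProtOr united-atom radii (1.42–1.88 Å). The
per-atom table ships as a plain-text asset (`inst/extdata/protor_typing.tsv`)
so assignments can be audited. Protonation-ambiguous atoms get one fixed
assignment for determinism: HIS ND1 = N3H1 and NE2 = N3H0 (one neutral
tautomer), OXT = O2H1, side-chain carboxylates OD1/OE1 = O1H0 and
OD2/OE2 = O2H1.

Solvent-accessible surface area is computed with the Shrake–Rupley scheme:
each atom's sphere is expanded by the probe radius (1.4 Å, a water molecule)
and sampled with a deterministic golden-angle spiral point set (default 960
points per atom); the accessible fraction of points gives the area. The
point set contains no randomness, so areas — and therefore pocket
memberships — are exactly reproducible.

The *whole groove* is the set of MHC atoms whose accessibility drops by more
than `epsilon` when the peptide is added; a *sub-pocket* uses only the single
peptide residue at its anchor position as the occluder, with the other twelve
peptide residues taking no part (a literal reading of occlusion "by the
peptide residue at Pk"; whether the original analysis kept the rest of the
peptide in the context is not documented, and the choice is exposed by the
API design rather than buried). `epsilon` defaults to 0.1 Å²: the occlusion
criterion is "accessibility is reduced", and a strictly-positive float
comparison would be at the mercy of quadrature noise, so a small positive
threshold is used and exposed as an argument. With 960 points one sample
point on a typical expanded sphere represents roughly 0.14 Å², so 0.1 Å² is
just below the single-point resolution. Doubling the point count flips
membership for at most about 1% of atoms on the test fixtures.

Alanine-remodelling of peptide side chains, seen in some published figures
of this kind of analysis, is treated as a visualization device: extraction
always uses the residue as crystallized.

## The descriptor and score

For a pocket of *n* typed atoms, all *n(n−1)/2* pairwise distances are
partitioned into 91 lists — one per unordered pair of the 13 group types
(13·12/2 + 13 = 91) — and each list is sorted non-decreasing. This is the
shape descriptor: frame-invariant by construction, and sensitive to both
geometry (the distances) and chemistry (the binning).

Two descriptors are compared list-by-list. Corresponding sorted lists are
aligned by a greedy two-pointer sweep: heads within the threshold (default
0.5 Å, inclusive) are matched and both advance, otherwise the smaller head
advances; every element matches at most once. On sorted inputs with this
interval compatibility rule the greedy count equals the maximum bipartite
matching size; the test suite verifies this against an exhaustive matching
oracle on a thousand random list pairs rather than assuming it. Matches are
summed over the 91 lists ("cumulative" matching, not per-bin averaging) and
normalized two ways:

* **PMSMin** = matches / (distance count of the *larger* site) — the default
  PM13Score;
* **PMSMax** = matches / (distance count of the *smaller* site).

PMSMin ≤ PMSMax always, with equality exactly for equal-size sites; a pocket
against itself scores (1, 1); scores are non-decreasing in the threshold.
Distances are kept at full precision — no rounding before matching. An empty
or undersized (< 3 atoms) pocket is an error, never a silent 0 or 1, since it
indicates an upstream extraction failure.

## Clustering and histograms

The distance between two sites is 1 − PM13Score. `neighbor_join()` applies
Saitou–Nei neighbour joining (via ape's implementation — no external
phylogeny program is involved) and clamps the occasional negative branch
length of non-additive data to zero, reporting the clamped deficit. Input
label order serves as the deterministic tie-break; exact reproduction of
published tree shapes in tie cases is therefore not promised. Trees are
serialized to Newick with verbatim (quoted where necessary) labels, readable
by `ape::read.tree` and by standard viewers. `score_histogram()` bins scores
into `[0,0.1), ..., [0.9,1.0]`; the top bin is closed so a score of exactly 1
is counted in bin 9.

## Sensitivity analysis

`sensitivity_curve()` probes how the score decays as a pocket's geometry is
corrupted: ensemble members receive i.i.d. Gaussian displacements rescaled so
the in-frame RMSD to the original hits a target drawn uniformly up to
`max_rmsd` (5 Å by default), and each member is scored against the original
at thresholds 0.125, 0.25, 0.5, 0.75 and 1 Å. No re-superposition is done —
the perturbation is meant as conformational noise in a fixed frame. The
distribution of the perturbation is a design choice (the procedure being
emulated says only "perturbed randomly"); Gaussian-then-rescale gives exact
RMSD control. `relabel_types()` is the complementary chemistry-only
perturbation: a chosen fraction of atoms gets a uniformly random *different*
group type while coordinates stay put. Geometry-only perturbation preserves
each bin's occupancy; relabelling preserves the pooled distance multiset —
two invariants the tests assert.

Everything is seeded and reproducible end-to-end. The tests and the
acceptance script run a 200-member ensemble on a 40-atom pocket — a
deliberately scaled-down ensemble size chosen to keep the default check
suite quick while leaving the monotone decay and threshold-dominance
patterns unambiguous; users reproducing full-scale curves should use
`n_members = 1000`.

## The fixture generator

`make_complex_pdb()` writes a small, valid PDB: a 74-residue alpha-like
helical rail and an 87-residue beta-like rail flanking an extended peptide
threaded between them, with backbone plus CB atoms only. The chains carry
the reference domain sequences — a deliberate departure from an all-alanine
fixture, because `identify_complexes()` assigns the alpha/beta roles by
sequence similarity to the reference profiles and poly-ALA chains would be
indistinguishable; the *geometry* stays alanine-like, keeping typing nearly
trivial. Options produce a second copy (two molecules per asymmetric unit),
longer peptides (to exercise trimming), a detached peptide (to exercise
failure paths), coordinate jitter, and a P7 side chain pointing out of vs
across the groove (to exercise occlusion-set sensitivity).

What the fixtures emulate: chain layout, domain lengths, a peptide that
occludes groove atoms, per-residue anchoring of sub-pockets, multi-copy
entries. What they do not: real side-chain geometry and packing, crystal
contacts, alternate conformations, missing residues, non-standard residues
beyond the alias map. Green tests on fixtures therefore validate the
machinery and its contracts, not crystallographic edge cases.

## Numerical choices, degenerate inputs, limitations

* Alternate locations: highest occupancy wins, ties by altloc label order.
* Alignment identity below 30% flags a warning but proceeds; fewer than 50%
  of reference positions mapped, or zero assignable peptide residues, abort
  standardization.
* Collinear point sets for superposition are not specially handled (the SVD
  fit still returns a proper rotation); fewer than 3 points is an error.
* `all_vs_all()` refuses mixed pocket kinds; comparisons of empty pockets
  are errors.
* mmCIF input, MHC class I, non-protein cofactors, analytic SASA and
  database-scale pocket search are out of scope. Comparative models are
  accepted as ordinary PDB input but never built.
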