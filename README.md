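# pm13 — alignment-free comparison of MHC class II binding grooves

MHC class II molecules present peptides to T cells from an open groove formed
by their alpha-1 and beta-1 domains; depressions in the groove (the P1, P4,
P6, P7 and P9 sub-pockets) hold the peptide's anchor side chains and largely
determine which peptides an allele binds. `pm13` compares these grooves and
sub-pockets directly from three-dimensional structures, for structural
immunologists who want to classify alleles by binding-site similarity, find
unexpected cross-allele matches, or track down which sub-pocket makes two
alleles behave differently.

## The method

1. **Standardize.** Each MHC–peptide complex is relabelled to chains A/B/C,
   renumbered by global sequence alignment to a packaged reference (alpha-1
   positions 5–78, beta-1 positions 5–91), superposed onto the reference by a
   Kabsch fit over the mapped Cα pairs, and its peptide registered onto the
   13 harmonized positions 308–320 (P1 = 308, P4 = 311, P6 = 313, P7 = 314,
   P9 = 316).
2. **Extract pockets.** Per-atom solvent accessibility is computed by the
   Shrake–Rupley scheme with a 1.4 Å probe and ProtOr united-atom radii. The
   whole groove is the set of MHC atoms whose accessibility drops when the
   peptide is present; each sub-pocket uses only its single anchoring peptide
   residue as the occluder.
3. **Describe and score.** Pocket atoms are typed into 13 ProtOr groups
   (element + connectivity + attached hydrogens). All intra-site distances
   are split into 91 sorted lists, one per unordered type pair
   (13·12/2 + 13). Corresponding lists of two pockets are aligned greedily
   with a match threshold *t* (default 0.5 Å); with *M* total matches and
   *N_a*, *N_b* intra-site distance counts,

       PMSMin = M / max(N_a, N_b)        PMSMax = M / min(N_a, N_b)

   and the PM13Score reported by default is PMSMin.
4. **Cluster.** Score matrices become `1 − score` distances, neighbour-joining
   cladograms (Newick) and ten-bin score histograms. A seeded perturbation
   module measures how scores decay with coordinate noise (controlled RMSD)
   or random re-typing.

## Worked example

No downloads are needed: the package generates valid synthetic complexes.

```r
library(pm13)

pdb <- file.path(tempdir(), "demo.pdb")
make_complex_pdb(pdb)                       # synthetic groove + peptide
raw <- parse_structure(pdb)
raw
#> raw_structure demo - 861 heavy atoms, 3 chains ( A, B, C )

sc <- standardize_complex(raw, identify_complexes(raw)[[1]])
sc
#> standard_complex from demo (chains ABC )- 861 atoms, 13 peptide residues

pockets <- extract_pockets(sc)
pockets$whole
#> pm13_pocket [ whole ] - 103 typed atoms from demo
pockets$P4
#> pm13_pocket [ P4 ] - 16 typed atoms from demo

# a second, jittered copy of the same complex
pdb2 <- file.path(tempdir(), "demo2.pdb")
make_complex_pdb(pdb2, jitter = 0.3, seed = 2)
raw2 <- parse_structure(pdb2)
sc2 <- standardize_complex(raw2, identify_complexes(raw2)[[1]])
pockets2 <- extract_pockets(sc2)

compare_pockets(pockets$whole, pockets2$whole)
#> PM13Score (threshold 0.5 A): PMSMin 0.777  PMSMax 0.824  (4081 matches / 5253 | 4950)
compare_pockets(pockets$P4, pockets2$P4)
#> PM13Score (threshold 0.5 A): PMSMin 0.566  PMSMax 0.642  (77 matches / 136 | 120)
```

The whole groove of the original complex contains 103 MHC atoms whose
accessibility the peptide reduces; its 5253 intra-site distances match the
jittered copy's at 78% (PMSMin), while the small P4 sub-pocket — 16 atoms,
136 distances — is more sensitive to the same 0.3 Å jitter (PMSMin 0.57).
Identical pockets score exactly (1, 1).

`run_pipeline()` (or the `exec/pm13` command-line wrapper) chains all steps
for a directory of structures, writing standardized PDBs, pocket tables,
PMSMin/PMSMax matrices, Newick trees, histograms and an echoed JSON
configuration.

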