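---
title: "Methods: structure-guided agonist screening and receptor-pocket analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-guided agonist screening and receptor-pocket analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agscreen)
```

## Scope and model

`agscreen` implements the post-docking computational layer of a
structure-guided screen for abscisic acid (ABA) receptor agonists, and the
pocket-comparison analysis used to engineer a receptor variant with altered
ligand sensitivity.  Docking itself (pose generation and scoring) is out of
scope: poses arrive as SDF input, optionally carrying an external docking
score such as a CHEMPLP value in a data tag.  The package covers:

1. physicochemical pre-filtering of a ligand library,
2. pharmacophore sphere-occupancy descriptors evaluated on docked poses,
3. aggregation of descriptor occupancies with the docking ranking,
4. binding-pocket definition, rigid superposition and residue diffing
   between homologous receptor structures,
5. geometric interaction analysis (hydrogen bonds, water bridges, the
   water-mediated "Trp lock", hydrophobic tunnel contacts),
6. ligand torsion-strain reporting against reference torsion statistics,
7. seeded synthetic-structure generators that make all of the above
   testable without any structure downloads.

## Library filter

The screening constants the pipeline is configured with are: molecular
weight in [200, 350] Da, at most 2 hydrogen-bond donor heavy atoms, and 1
to 5 acceptor heavy atoms.  All bounds are read as closed intervals;
`filter_criteria()` exposes each of them.  Donors are counted per donor
heavy atom, not per hydrogen.

Atom typing is a deliberate, documented convention
(`typing_rules()`) rather than a reconstruction of any docking program's
internal definitions, which are not public:

* donor: N or O bearing at least one hydrogen (explicit or implicit);
* acceptor: any O with non-positive formal charge; N with non-positive
  formal charge and at most two heavy neighbors, excluding amide-type N
  (neighbor carbon double-bonded to O or S) and pyrrole/aniline-type N
  (H-bearing N whose heavy neighbors are all sp2 carbons);
* hydrophobic: C or S whose heavy neighbors are all C or S.

The convention is enforced twice: once by the graph-based implementation
in `type_atoms()`, and once, independently, by a SMARTS-pattern encoding
of the same rules evaluated with a separate cheminformatics engine; the
frozen panel labels for a 200-molecule synthetic library ship with the
test suite and the two implementations agree exactly on it.  Molecular
weights use embedded IUPAC standard atomic weights with implicit hydrogens
derived from a smallest-consistent-valence model; they agree with the
independent engine to better than 0.02 Da on the panel, and no library
molecule sits within 0.2 Da of a filter boundary, so pass/fail labels are
insensitive to that residual difference.

## Sphere-occupancy descriptors

Four spheres anchor on the reference agonist bound in the receptor (the
natural hormone in the shipped defaults) and on the pocket:

| name | anchor | radius (Å) | property |
|---|---|---|---|
| `keto_O` | ligand ketone oxygen | 1.5 | acceptor |
| `carboxylate` | carboxylate oxygens' centroid | 2.8 | acceptor |
| `methyl` | a ligand methyl carbon | 1.4 | hydrophobic |
| `pocket_centroid` | side-chain centroid of residues 90/139 | 3.5 | hydrophobic |

"Carboxylate position" is geometrically ambiguous (the carbon, either
oxygen, or the O–O centroid); the default is the O–O centroid and the
alternatives are selectable in the anchor spec.  Which of the ligand's
methyls anchors the 1.4 Å sphere is likewise configurable and not asserted
as canonical.

A pose's score per sphere is the percentage of sphere volume covered by
the union of van der Waals spheres (Bondi radii, overridable) of the
pose's atoms that carry the required property.  Hydrogens never
contribute: the crystal structures this analysis targets have none, and
all geometric criteria in the package are heavy-atom-first by design.

The default sampler is a deterministic cell-centered cubic grid (spacing
0.2 Å) aligned to the sphere center, with one refinement: every cell
straddling either the sphere surface or an atom surface (within half a
cell diagonal of it) is re-sampled on a 3×3×3 sub-grid, and numerator and
denominator are accumulated from the same sub-samples.  Plain point
counting at 0.2 Å carries up to ~1 percentage point of surface bias on the
small spheres; the refinement brings the maximum absolute error against
the closed-form two-sphere lens volume below 0.15 points at 0.2 Å spacing
(0.23/0.13/0.02 points at 0.4/0.2/0.1 Å over 25 single-atom placements
spanning the full overlap range), at roughly twice the cost.  A seeded
Monte Carlo sampler (default 10^5 points; seed required) provides an
independent cross-check and agrees with the grid within 0.15 points at
10^6 points on the pose panel.  The estimator counts the union once, so
overlapping atoms are never double counted, occupancy is monotone in
added qualifying atoms, and rigid co-transformation of pose and spheres
leaves scores unchanged up to discretization.

## Rank aggregation

Docking scores and occupancies live on incommensurate scales.  There is no
single canonical combination rule, and the exact weighting used in the
historical screen to select its 93-ligand shortlist is not public, so no
default here claims to reproduce that list.  The default is a weighted
rank sum: per criterion, competition ranks (ties share the minimum rank);
aggregate = weighted mean of ranks; ascending order; remaining ties broken
lexicographically by pose id so output is reproducible.  `weighted_z`
(scale-sensitive) and `pareto_then_rank_sum` (dominance-first) are
config-selectable alternatives.  `select_top(n)` keeps every row tied at
the cutoff boundary and flags the expansion rather than truncating
arbitrarily.

## Pocket definition, superposition, diffing

The binding site is the set of protein residues with at least one heavy
atom within 6 Å (inclusive) of any reference-ligand heavy atom; waters
and hetero groups are excluded.  Superposition is the Kabsch SVD
construction with the determinant correction, so reflections are never
returned; it is checked in the tests against an independent quaternion
(Horn) implementation.  The caller supplies the residue pairing —
typically identical residue keys for same-numbering structures, or an
explicit correspondence table for homologs; automatic remote-homolog
alignment is a non-goal.

`diff_pocket()` matches each pocket residue of structure A to the nearest
Cα of structure B after superposition (greedy nearest-first, each B
residue used once, default 2 Å match cutoff) and reports identity
mismatches as substitutions.  Cross-numbering comparisons are thus handled
spatially, not by sequence alignment — the use case is comparing solved
structures, where spatial correspondence is the ground truth.
`second_shell()` reports residues just outside the pocket (default
4.5 Å from any pocket heavy atom): the package reports these candidates
(e.g. chains of interacting residues along the β-sheet, which motivated a
five-substitution receptor design shipped as `cspyl1_5m.yaml`) but makes
no claim that a ranking of them reproduces expert choices.

## Interaction geometry

Hydrogen bonds use a heavy-atom donor–acceptor distance criterion,
default 3.5 Å; if an explicit hydrogen is present on the donor, a
D–H···A angle of at least 120° is additionally required.  Water bridges
use the same distance criterion on both legs; hydrophobic contacts pair
C/S atoms within 4.5 Å.  These are conventional geometric values, exposed
in the configuration and not claimed to be the values used for any
published figure; without the deposited structures and the original
criteria, bit-exact reproduction of published interaction networks is not
attempted.  Protein atoms are typed by residue template (backbone N
donor, backbone O acceptor, standard side-chain tables) to avoid needing
bond orders for the protein; ligands are typed from their bond graph.

The "Trp lock" ships as a `motif_pattern()`: a water oxygen
simultaneously within hydrogen-bond distance of the ligand carbonyl
oxygen, the latch residue's backbone N, the gate residue's backbone O and
the tryptophan side-chain NE1 of the partner phosphatase.
`match_motif()` enumerates all satisfying slot assignments, so the tests
can compare it against exhaustive enumeration.

## Torsion strain

`dihedral()` follows the standard signed convention (cis = 0°, range
(−180°, 180°]), verified in the tests against two independent
implementations.  Reference means for named torsions (the α/β angles of
a sulfonamide linker in the shipped example) are user-supplied
configuration: the canonical source of such statistics is a licensed
small-molecule structure database, so the package never queries one, and
the shipped α/β atom quadruples are labeled illustrative.  The report
gives per-pose circular absolute deviations (in [0°, 180°]) and, in
comparative mode, flags which of two pose sets is more relaxed per
torsion — the pattern used to compare agonist conformations across
receptor variants.

## Synthetic data: what it does and does not emulate

All fixtures are generated by seeded code and written through the real
I/O layer (PDB/SDF), so parsing is exercised on every test:

* `make_toy_complex()` builds an idealized pocket — a multi-atom ligand
  with ketone, carboxylate-like and methyl groups, residues on an inner
  (< 6 Å) and an outer (> 6 Å) shell, bulk waters, and optionally an
  exactly lock-satisfying water network with gate/latch/Trp anchors.
  Residue geometry is a toy template (backbone plus a zig-zag side
  chain), deliberately not stereochemically accurate.
* `make_pose_with_occupancy()` inverts the closed-form lens volume by
  bisection (to 1e-9 Å) to place one atom at an exact target occupancy —
  the oracle for the samplers.
* `make_library()` assembles molecules from a fragment grammar (ring,
  alkyl/ether linkers, ketone, sulfonamide, polar caps) with adjacency
  constraints chosen so every fragment's donor/acceptor contribution is
  context-free; labels come from fragment-mass bookkeeping, not from the
  typing module under test.
* `make_mutant_pair()` swaps side-chain templates at listed positions and
  optionally jitters coordinates — the ground truth for pocket diffing.
* `make_conformer()` sets named torsions by rotating downstream atoms
  about acyclic bonds; round-trip recovery is exact to 1e-6°.

Because geometry is idealized, green tests demonstrate correctness of the
computations (distances, volumes, matching, angles) on well-posed inputs;
they do not demonstrate robustness to real crystallographic pathologies
(alternate conformations beyond simple altlocs, occupancy disorder,
missing atoms, non-standard residues), force-field-quality geometry, or
realistic water networks.

## Numerical and degenerate-input choices

* Distance thresholds are inclusive (≤) throughout.
* Altloc resolution defaults to highest occupancy, ties to the first
  record encountered; "first" is selectable.
* Superposition requires ≥ 3 non-collinear pairs and errors otherwise;
  collinearity is detected via the second singular value (< 1e-12).
* Zero-radius pockets/shells and empty motif-candidate sets are valid or
  raise named errors as documented per function.
* Aromatic SDF bond order 4 contributes 1.5 to the valence sum with
  round-up; molecules using aromatic orders should carry explicit H where
  that is ambiguous (e.g. pyrrole N-H).  The shipped generators emit
  Kekulé forms only.
* The problem sizes used by the test-suite and acceptance script — a
  200-molecule library, 25 occupancy placements, 10^6 Monte Carlo points,
  20 random pocket fixtures, 50-conformer torsion round trips — were
  chosen as the smallest sizes at which each property is measured well
  away from its tolerance, and run in well under a minute each on one
  core.

## Command-line use

A thin CLI over the same functions ships in
`inst/cli/agscreen.R` (subcommands `filter`, `score`, `rank`, `screen`,
`pocket-diff`, `torsions`, `simulate`); every subcommand writes only
files named by the caller plus a JSON run manifest with input paths,
resolved configuration and output checksums, and identical inputs and
seeds reproduce byte-identical tables.
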