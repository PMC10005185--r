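# agscreen

Post-docking analysis toolkit for structure-guided discovery of abscisic
acid (ABA) receptor agonists and for engineering receptor variants with
altered agonist sensitivity.

ABA receptors (the PYR/PYL/RCAR family) close their gate and latch loops
over a bound agonist and then inhibit clade-A PP2C phosphatases; small
molecules that reproduce this closure (sulfonamide agonists such as
sulfobactin and quinabactin analogues) are candidate drought-protection
agrochemicals.  `agscreen` implements the computations that sit on either
side of the docking step in such a campaign, working from standard PDB and
SDF (V2000) files:

* **Library filtering** — molecular weight in [200, 350] Da, ≤ 2
  hydrogen-bond donors, 1–5 acceptors (inclusive bounds, all
  configurable), with a documented and independently cross-checked atom
  typing convention.
* **Pharmacophore sphere-occupancy descriptors** — four spheres anchored
  on the receptor-bound reference hormone (ketone oxygen, r = 1.5 Å,
  acceptor; carboxylate centroid, 2.8 Å, acceptor; methyl carbon, 1.4 Å,
  hydrophobic; pocket side-chain centroid of residues 90/139, 3.5 Å,
  hydrophobic).  Each docked pose is scored by the percent of sphere
  volume occupied by the van der Waals spheres of its qualifying atoms,
  computed on a deterministic refined grid (or a seeded Monte Carlo
  sampler) and validated against the closed-form two-sphere lens volume.
* **Rank aggregation** — weighted rank-sum (default), weighted-z or
  Pareto aggregation of the external docking score (e.g. CHEMPLP, read
  from an SDF tag) with the sphere occupancies; deterministic tie
  handling; boundary-tie-aware top-N selection.
* **Pocket comparison** — binding-site definition (heavy atoms within
  6 Å of the reference ligand), Kabsch superposition, spatial
  nearest-Cα residue diffing between homologous structures, and
  second-shell reporting; a shipped preset (`cspyl1_5m.yaml`) records the
  five-substitution receptor design this analysis supports
  (Val112Leu, Phe137Ile, Thr135Leu, Thr153Ile, Val168Ala).
* **Interaction analysis** — heavy-atom hydrogen bonds, water bridges,
  hydrophobic tunnel contacts, and a constraint-based motif matcher
  shipping the water-mediated "Trp lock" (water H-bonded simultaneously
  to the ligand carbonyl, the latch backbone amine, the gate backbone
  carbonyl and the phosphatase tryptophan side chain).
* **Torsion strain** — signed dihedrals, circular deviations from
  user-supplied reference torsion statistics, and a comparative mode that
  flags which of two pose sets is more relaxed.
* **Synthetic data** — seeded generators for toy complexes, occupancy-
  calibrated single-atom poses, labeled molecule libraries, mutant
  structure pairs and set-torsion conformers, so the full pipeline runs
  and is tested entirely offline.

See the methods vignette (`vignettes/agscreen-methods.Rmd`) for the
conventions, estimators and their error bounds.

## Worked example

```r
library(agscreen)

# synthetic study: a 200-molecule library, a reference complex, 8 docked poses
make_library(n = 200, seed = 1, sdf_out = "library.sdf")
ref <- make_toy_complex(seed = 1, path = "reference.pdb")
res <- run_screen("library.sdf", "reference.pdb", "poses.sdf",
                  out_dir = "out", top_n = 3)

res$filter_counts[c("read", "passed", "failed")]
#> $read
#> [1] 200
#> $passed
#> [1] 62
#> $failed
#> [1] 138

head(res$ranked[, c("pose_id", "docking_score", "occ_keto_O", "occ_methyl",
                    "aggregate", "rank")], 4)
#>     pose_id docking_score occ_keto_O occ_methyl aggregate rank
#> 1 pose_0001            53   89.28526  100.00000       2.8    1
#> 2 pose_0004            62   89.58744   99.62345       3.6    2
#> 3 pose_0008            74   75.85512   99.62603       4.2    3
#> 4 pose_0002            56   98.40937  100.00000       4.4    4
```

62 of 200 library molecules satisfy the physicochemical filter; each
docked pose then gets one occupancy column per descriptor sphere (percent
of sphere volume covered by acceptor/hydrophobic atoms), and poses are
ordered by the weighted mean of their per-criterion competition ranks
(`aggregate`, lower is better).  The pocket and interaction layer on the
same complex:

```r
define_pocket(ref, "ABA")
#> <pocket: 11 residues within 6.0 A of ABA>

match_motif(ref, trp_lock_pattern("ABA"))[, c("water_res_seq",
                                              "latch_n_res_seq",
                                              "gate_o_res_seq",
                                              "trp_ne1_res_seq")]
#>   water_res_seq latch_n_res_seq gate_o_res_seq trp_ne1_res_seq
#> 1           601             145            117             385
```

The single lock-satisfying water (601) bridges the ligand carbonyl, the
latch (145), the gate (117) and the phosphatase tryptophan (385) — the
geometry that couples agonist binding to phosphatase inhibition.

A thin command-line front end over the same functions is in
`inst/cli/agscreen.R`
(`filter | score | rank | screen | pocket-diff | torsions | simulate`).

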