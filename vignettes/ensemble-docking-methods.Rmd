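---
title: "Ensemble docking against a disordered peptide: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble docking against a disordered peptide: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdock)
```

# The problem

Intrinsically disordered peptides such as the 42-residue amyloid-beta peptide
have no single native structure, so a docking study against one conformation
is close to meaningless. The established workaround is *ensemble docking*:
sample a large, diverse library of receptor conformations, dock the ligand
against each of them, and draw conclusions only from statistics aggregated
over the whole ensemble — per-residue contact frequencies, interaction-type
tallies, and so on. `ensdock` implements that pipeline end to end for
rigid-receptor Vina-style docking output, with a synthetic-fixture layer so
every stage can be exercised and validated without any external program or
downloaded structure.

This vignette explains the methods, the tunable parameters and their
defaults, the numerical choices, and what the synthetic fixtures do and do
not establish about real data.

# Conformer library by blockwise excursion sampling

The library generator (`build_library()`) runs many independent *excursion
chains*. One chain alternates two kinds of blocks:

* a **simulated-annealing (SA) block** (`run_sa_block()`): the system is
  heated to a block-specific maximum temperature and cooled down a
  monotone schedule (linear by default, exponential optional) to the base
  temperature, letting the chain cross barriers into a new basin;
* a **relaxation block** (`run_relaxation_block()`): constant-temperature
  dynamics at the base temperature, recording frames.

From each relaxation block exactly one representative structure is extracted
(`select_representative()`): over a tail window of the trajectory, every
frame is superposed onto the first window frame (Kabsch), the coordinate
mean is formed, the frame with the smallest RMSD to that mean is chosen
(earliest frame on exact ties), and that frame is energy-minimised with a
conjugate-gradient minimiser (`stats::optim(method = "CG")`, analytic
gradients). The library is the collection of all block representatives, so
its size is exactly `n_chains * blocks_per_chain` — an accounting identity
the tests assert at full scale (2000 chains of 5 blocks giving 10,000
representatives).

Default configuration (`excursion_config()`): 2000 chains of 5 blocks with
SA maximum temperatures 700, 600, 500, 400 and 350 K and a base temperature
of 310 K, every chain starting from the same fully extended structure. Time
is measured in integrator steps, not picoseconds: the conventional
120-ps-block / 100-ps-analysis-tail design maps onto the default 120-step
relaxation block with a 100-frame representative window (the same 5/6
ratio). The test suite and the acceptance script run reduced blocks (12 SA
and 12 relaxation steps, window 10, 5-bead chains); the accounting
identities they check are invariant to these sizes, and the reduction keeps
the full 2000-chain driver to a couple of minutes on one core.

## Dynamics and the energy-model contract

The sampler is defined over a minimal energy-model contract — `energy(xyz)`,
`gradient(xyz)` — rather than over a specific force field. Dynamics are
overdamped Langevin,

$$x_{t+1} = x_t - \frac{\Delta t}{\gamma}\nabla E(x_t)
  + \sqrt{2 k_B T \Delta t/\gamma}\,\xi_t,$$

with a Metropolis random-walk fallback (`dynamics = "metropolis"`). Two
models ship with the package:

* `harmonic_well_model()` — a quadratic well with a unique analytic
  minimum, used to validate the annealer and minimiser;
* `bead_chain_model()` — the default toy peptide potential: one bead per
  residue, harmonic virtual bonds (equilibrium 3.8 Å, the CA–CA distance),
  a harmonic excluded-volume repulsion switching on below 4.5 Å for beads
  at least two apart, and a cosine dihedral term $k(1+\cos\phi)$ over
  consecutive quadruples that gives the chain competing extended and
  compact states. All gradients are analytic and are checked against
  central finite differences (relative error below $10^{-4}$) in the
  tests.

The toy potential is a sampling testbed, not a physical model of any real
peptide: it reproduces the *shape* of the problem (a chain with many
accessible conformations and barriers between them), which is what the
library-accounting and determinism properties need. No claim about real
conformational ensembles — and in particular no chemical-shift-level
validation — follows from it.

## Numerical and design choices

* **Superposition reference.** Frames are superposed onto the *first window
  frame* before averaging. The mean structure depends slightly on this
  choice and no convention is universal; it is fixed, documented, and
  configurable in code.
* **RMSD flavour.** All-atom, mass-unweighted throughout — the simplest
  fully reproducible choice.
* **Tie-breaks.** Exact RMSD ties select the earliest frame
  (`which.min`).
* **Seeds.** Every stochastic stage derives its seed from the master seed
  by a fixed integer mix (`derive_seed()`, always below $2^{31}$); chain
  seeds are recorded in the library manifest, and repeated runs give
  byte-identical manifests and fixture files.
* **Degenerate inputs.** Non-finite energies or gradients abort with a
  diagnostic naming the step and temperature; empty representative windows
  and window/block inconsistencies are rejected at configuration time.

# Docking interface

Search boxes (`build_search_box()`) are axis-aligned, centred on the
receptor's heavy-atom centroid, and sized so that every heavy atom keeps a
margin (default 12 Å) from every face. "Centre of mass" is implemented as
the *unweighted* heavy-atom centroid — whether extents should use all atoms
or a mass weighting is not standardised, so both are toggles
(`heavy_only`, `mass_weighted`) with the simplest variant as default.

Running a docking engine is out of scope. `external_dock_hook()` substitutes
receptor, ligand, box and output placeholders into a user-supplied shell
template and only checks that the output file appears; parsing stays in
`read_vina_pdbqt()`, which reads the Vina *output* dialect (MODEL blocks
with `REMARK VINA RESULT:` affinities and torsion-tree records) and rejects
AutoDock grid-map and flexible-residue files. Pose rank is file order;
affinity ordering is validated (`validate_runs()`) but never silently
repaired.

# Pose selection by binding-energy difference

Within one run, the difference between the top pose's affinity and a
lower-ranked pose's affinity flags near-optimal alternative placements that
a top-1 analysis would discard. `select_poses()` keeps the top pose always,
plus every lower-ranked pose whose difference is within the cutoff.
Choices made here:

* the difference is stored as a magnitude (the raw top-minus-lower value is
  $\le 0$, while cutoffs are quoted positive);
* the comparison is **inclusive** (`<= cutoff`), so a pose exactly at the
  cutoff is kept;
* duplicate best affinities: the first file pose is "top", its twin is a
  selected lower-ranked pose;
* no pose deduplication is attempted.

`summarize_selection()` tabulates selected-set sizes over ascending cutoffs
("set-1", "set-2", ...); the total is provably non-decreasing in the
cutoff, a property the tests exercise on random fixtures at the
conventional 0.1/0.2/0.3 kcal/mol ladder.

# Per-residue contact statistics

A residue is a *binding residue* of a complex when at least one of its
heavy atoms lies within the distance cutoff of any ligand heavy atom
(inclusive; hydrogens ignored on both sides). `build_contact_table()`
counts, for every residue and every cutoff in the nested ladder 3.0, 3.5,
4.0, 4.5, 5.0 Å, the number of selected complexes in which the residue
binds. Counting one hit per complex (binary per complex) follows from
building a binding-residue list per complex and then counting; since
table semantics could also be read as atom-pair counts, that alternative
ships as a flagged mode (`mode = "atom_pairs"`) and is not the default.

The fast path is a uniform-grid cell list (fixed-radius neighbour search,
the same complexity class as a KD-tree query); the tests pin it to an
$O(N^2)$ double-loop oracle on dozens of random fixtures. Row-wise
monotonicity across the nested cutoffs and permutation invariance over
complexes are asserted as properties. `rank_hotspots()` sorts residues by
count (ties broken by residue number) and reports the share of contacts in
a residue window, with 0/0 defined as 0.

# Interaction geometry

The classifier covers hydrogen bonds and the aromatic interaction types
relevant to polyphenol binders: parallel and T-shaped ring stacking, XH–pi
(X = C, N, O) and lone-pair–pi. The literature names these types far more
often than it fixes their thresholds, so **every threshold lives in one
criteria block** (`interaction_criteria()`) with defaults drawn from common
practice, and every emitted record stores the geometry it was accepted on
so the whole output can be re-audited against any criteria
(`audit_interactions()`). Defaults:

| interaction | acceptance geometry |
|---|---|
| hydrogen bond | donor–acceptor $\le$ 3.5 Å **and** donor–H–acceptor $\ge 130^\circ$ |
| pi–pi parallel | centroid distance $\le$ 5.5 Å, interplanar angle $\le 30^\circ$ |
| pi–pi T-shaped | centroid distance $\le$ 6.0 Å, interplanar angle $\ge 60^\circ$ |
| XH–pi | H–centroid $\le$ 3.0 Å, in-plane offset $\le$ ring radius + 0.5 Å, X–H toward ring within $60^\circ$ |
| lone-pair–pi | atom–centroid $\le$ 3.5 Å, within $25^\circ$ of the ring normal |

Interplanar angles are folded to $[0^\circ, 90^\circ]$ so the sign
ambiguity of ring normals cannot flip a class. Protein rings come from
residue-name templates (PHE/TYR six-membered, HIS five-membered, TRP both);
ligand rings come from an explicit annotation or from fundamental-cycle
perception on a bond table, and every ring must pass a 0.3 Å planarity
tolerance, which is what rejects puckered pyran-like rings. Donor/acceptor
typing for ligands is annotation-driven — no automatic protonation is
attempted.

# Trajectory metrics

`rmsd_series()` (Kabsch-fitted, first frame or a supplied reference),
`rg_series()`, Shrake–Rupley `sasa()` with a deterministic golden-spiral
point set and a Bondi-style element radius table shipped in code,
`min_distance_series()` (with a centroid-distance alternative, since
"average distance" conventions differ between reports),
`hbond_series()` and `end_to_end_series()`. Internals are in Å; length
series are reported in nm, matching MD-report conventions. Validated
analytic limits: an isolated sphere's SASA within 1% of
$4\pi(r+r_p)^2$ at 960 points, exact two-point radius of gyration, RMSD
below $10^{-9}$ Å for rotated copies, and rigid-motion invariance of every
metric. No solvent is ever simulated: solvent-involving hydrogen-bond
modes require explicit solvent coordinates in the trajectory and error
otherwise, so solvent metrics are reproducible in form, not in value.

# Synthetic fixtures: what they show and what they cannot

The fixture layer generates every input format the pipeline consumes: toy
bead peptides (extended / collapsed / random), a rigid catechin-like toy
ligand (two planar aromatic rings bridged by a puckered ether ring, an
optional gallate-like third ring, annotated donors/acceptors), Vina-dialect
pose files with controlled affinity gaps, planted distance-band contacts
placed by direct rigid placement (never optimisation; unsatisfiable
combinations are rejected), minimal interaction geometries with one-
threshold-violated negative twins, and noisy trajectories with scripted
events. Everything is deterministic given its seed, down to byte-identical
files.

Passing on these fixtures establishes *correctness of the machinery*:
parsing, accounting identities, geometric classification, statistical
aggregation, determinism. It does **not** establish anything about real
docking accuracy, real peptide ensembles, or real interaction prevalence —
those depend on the docking engine and force field that are explicitly out
of scope here.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the library driver at the
full 2000-chain, 5-block configuration on a 5-bead chain with 12-step
blocks and a 10-frame window, and the pose-accounting check at the full
10,000-run, 9-pose scale with the standard toy ligand. These sizes are the
package's own validation choices: they preserve every count the
accounting identities predict while keeping a complete run on a single
core to a few minutes.

# Known limitations

* The sampler's toy potential has no sequence specificity, sidechains or
  solvent; it validates the protocol, not the thermodynamics.
* Receptor coordinates are the docked rigid conformer's; no induced fit or
  re-minimisation of complexes.
* Geometric interaction thresholds are conventions, not fitted values;
  results at other criteria are one `interaction_criteria()` call away, and
  the audit property guarantees internal consistency whatever the values.
* PDB support is the fixed-column v3.3 dialect (plus the Vina PDBQT output
  dialect); mmCIF, MOL2 and SDF are out of scope.
* Vina affinities are treated as selection scores only, never as free
  energies; no Boltzmann reweighting of poses is attempted.
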