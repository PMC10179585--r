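Package: ensdock
Title: Ensemble Docking Analysis for Intrinsically Disordered Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ensemble-docking studies of small molecules binding to
    intrinsically disordered peptides. Provides conformer-library generation by
    blockwise excursion sampling (alternating simulated-annealing and
    constant-temperature relaxation blocks over a pluggable energy model),
    reading of Vina-dialect PDBQT multi-pose docking results, per-run docking
    search-box construction, selection of near-optimal poses by a binding
    free-energy difference cutoff, per-residue ensemble contact statistics at
    multiple heavy-atom distance cutoffs, geometric classification of hydrogen
    bonds and aromatic interactions (pi-pi stacking, T-shaped, XH-pi,
    lone-pair-pi), and trajectory validation metrics (RMSD, radius of gyration,
    solvent accessible surface area, minimum-distance and hydrogen-bond time
    series). A synthetic-fixture generator produces toy peptide conformers,
    controlled pose sets and trajectories so the whole pipeline can be
    exercised without external structure files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
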