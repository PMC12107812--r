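Package: moldesirer
Title: Crossover-Free Genetic Algorithm for Multi-Property Molecular
    Optimization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An evolutionary engine for small-molecule design that evolves
    candidate ligands by fragment-based mutation (no crossover) under a
    multi-property fitness built from Derringer-Suich desirability
    transforms of a docking-score axis, drug-likeness (QED) and synthetic
    accessibility. Provides Boltzmann roulette selection, elitist
    merge-and-truncate population updates, resumable checkpointed
    campaigns, a single-shot local grow operator, constrained conformer
    generation with protein clash filtering, campaign analytics
    (Tanimoto similarity distributions, population evolution summaries,
    chemical-space projection) and relative-to-absolute binding free
    energy conversion with error propagation. Molecule handling is backed
    by Open Babel via ChemmineR/ChemmineOB; drug-likeness and synthetic
    accessibility are computed through a bundled RDKit helper script.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    parallel,
    ChemmineR,
    ChemmineOB,
    igraph,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (via ChemmineOB); Python (>= 3.9) with
    RDKit for the QED and synthetic-accessibility descriptors
Config/testthat/edition: 3
biocViews: Cheminformatics, Software
RoxygenNote: 7.3.3
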