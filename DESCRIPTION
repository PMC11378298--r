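Package: pocketedda
Title: In-Pocket Analysis and Energy Decomposition for Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue analysis of protein-ligand binding pockets. Extracts
    and hydrogen-caps the residues surrounding a bound ligand, computes
    ligand-residue interaction energies with a transparent classical backend
    (Coulomb, Lennard-Jones, geometric hydrogen-bond reattribution,
    generalized-Born solvation) or through a file-exchange adapter to an
    external semiempirical engine, refines hydrogen positions with heavy atoms
    fixed, and assembles energy-decomposition reports that compare alternative
    ligand binding modes. Includes Boltzmann multiconformer averaging,
    binding-energy bookkeeping with explicit term ledgers, conversion between
    relative affinities and free-energy differences, and deterministic
    synthetic pocket fixtures with closed-form reference energetics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
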