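Package: hmgfunc
Title: Amino-Acid Function Analysis of the HMG Box from Variants,
    Conservation, Structure and Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for assigning putative function to
    amino-acid positions of the HMG-box DNA-binding domain. Loads and
    summarizes catalogs of disease-associated missense variants, maps
    domain positions onto multiple sequence alignments and classifies
    their conservation at the HMG-family and Sox-subfamily levels,
    superposes structure ensembles onto a reference by alignment-guided
    Kabsch fitting, computes per-residue alpha-carbon RMSD profiles from
    molecular-dynamics trajectories, and compares peptide-binding
    stability across docked, alanine-substituted and free simulation
    regimes. A synthetic-data module generates alignments, variant
    tables, helical structures and Gaussian-fluctuation trajectories
    with known ground truth so that every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
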