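Package: pepscreen
Title: Coarse-Grained Screening of Cholesterol-Peptide Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico screening pipeline that ranks cholesterol-modified
    cationic peptides by self-assembly propensity. A peptide library is mapped
    to a coarse-grained bead model (one bead per residue plus one hydrophobic
    cholesterol terminal domain bead), packed into a periodic box, and evolved
    with implicit-solvent BAOAB Langevin dynamics. Per-frame observables --
    Shrake-Rupley solvent-accessible surface area, radius of gyration,
    intermolecular Lennard-Jones and Coulomb energies, and the saturation
    number of hydrophobic terminal domains -- feed an aggregation-timeline
    classifier and a rank-sum composite score with a cationic-charge exclusion
    rule, reproducing the structure of a computer-modelling screen for
    siRNA-delivery peptide candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
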