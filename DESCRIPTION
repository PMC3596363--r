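Package: cannmotif
Title: Backbone Model Building and Anion-Interaction Analysis for the
    CaNN Peptide Motif
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing anion recognition by the CaNN peptide
    backbone motif: construction of peptide backbone models from
    per-residue phi/psi torsions (including Aib-containing designed
    helices and acetyl/amide caps), geometric hydrogen-bond detection
    and point-charge Coulomb scoring of sulfate/phosphate contacts,
    verification of the canonical two-oxygen contact pattern,
    Ramachandran-window state classification and NH-NH(i,i+1) helicity
    tracking over conformer ensembles and trajectories, Gaussian-fit
    ensemble statistics, NOE/Karplus NMR-restraint translation, and
    peptide-anion adduct m/z computation.  Seeded synthetic generators
    emulate docking-pose ensembles and binding/unbinding trajectories
    so every analysis stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
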