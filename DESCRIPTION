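Package: actinovar
Title: Residue-Level Variability Analysis of Actinoporin Pore-Forming Toxins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis toolkit for actinoporin (sea-anemone
    pore-forming toxin) variability. Classifies alignment columns into the
    four Clustal conservation categories, computes side-chain accessible
    surface area by the Shrake-Rupley method with random-coil reference
    ratios and burial classes, and cross-tabulates conservation, solvent
    accessibility and interaction role (lipid-binding, protein-protein
    interface, non-interacting) per residue of a reference structure.
    Includes hemolysis-kinetics analytics (lag time, maximum lysis velocity,
    power-law time constants, Hill dose-response HC50), thermal-melting Tm
    extraction by the first-derivative-maximum method, sequence utilities
    (cDNA translation, Edman-prefix splicing, theoretical average mass,
    pairwise identity, Kabsch superposition RMSD), and seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'actinovar-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sequence-core.R'
    'conservation.R'
    'synthetic.R'
    'structure-asa.R'
    'crosstab.R'
    'kinetics.R'
    'melting.R'
    'pipeline.R'
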