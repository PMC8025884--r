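Package: bondflex
Title: Bond-Based Ensemble Parametrization and Torsion-Space Refinement for Protein Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds deterministic conformer ensembles of protein crystal
    structures from a bond-based (torsion-space) parametrization: a single
    anchored atom carries a Fibonacci-lattice point cloud from which every
    other atom is generated recursively through bond lengths, bond angles and
    torsion angles.  Flexibility enters through whole-molecule translation
    tensors and screw motions and through per-bond torsion kicks, rather than
    per-atom B factors.  The package computes real-space density segments,
    multi-conformer bulk-solvent masks, space-group expanded structure
    factors, phase-spread weighted 2Fo-Fc maps, and drives a four-mode
    Nelder-Mead refinement protocol against observed amplitudes.  Synthetic
    fixture generators (ideal peptides, simulated reflection data) support
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
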