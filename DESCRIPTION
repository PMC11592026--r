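Package: replate
Title: Protein Backbone Reconstruction from C-Alpha Traces by Peptide-Plate Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rebuilds all heavy backbone atoms (N, C, O) of a protein from its
    C-alpha trace alone. Each peptide unit is modelled as a rigid planar plate
    of ideal geometry whose orientation about the Ca-Ca virtual bond is a
    single dihedral angle (lambda); a small one-dimensional convolutional
    network predicts lambda per residue from trace-derived geometric features,
    and the backbone is then recovered deterministically by placing ideal
    plates rotated by the predicted angles. Includes PDB/mmCIF input, training
    data filters, a synthetic-structure generator for testing, and evaluation
    of reconstruction error by atom type and secondary structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
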