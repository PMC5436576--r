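Package: peptwist
Title: Helical Parameters and Twist Handedness of Regular Peptide Backbones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a regular peptide backbone as a helix and computes its
    axial displacement per residue (d), angular displacement per residue
    (theta) and per-atom-type helix radii directly from the backbone dihedral
    angles (phi, psi, omega) and six stereochemical constants, using both the
    exact closed forms and their simplified trans/cis two-coefficient
    reductions. Provides the backbone handedness metric h = sgn(d)*sin(theta),
    coordinate-based chirality indices for cross-validation, an
    internal-coordinate backbone builder with PDB input/output, an independent
    screw-decomposition oracle that recovers the helical parameters from 3-D
    coordinates, and survey tools that map handedness over Ramachandran space
    for arbitrary amide dihedral angles, extract the d = 0 and theta = 180
    degree boundary curves, and generate the universal Cartesian (theta, d)
    map with its cis/trans envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    grDevices,
    graphics,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
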