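Package: molforge
Title: Headless Building, Editing and Rendering of Small-Molecule 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A headless molecular building and editing engine for small
    molecules. Reads and writes XYZ coordinate files and reads a subset of
    MDL MOL V2000, perceives bonds from interatomic distances and covalent
    radii, measures bond lengths, angles and dihedrals, edits structures
    (atom and bond addition and deletion, element changes with octet-rule
    hydrogen autocompletion, ring-aware rotation of fragments about bonds,
    bounded undo/redo), runs a crude VSEPR-style geometry relaxation, and
    renders depth-sorted ball-and-stick scenes to SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
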