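Package: svgphylo
Title: Scalable Interactive SVG Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Draws phylogenetic trees as compact, interactive Scalable Vector
    Graphics for direct embedding in web pages. Reads Newick strings and NEXUS
    TREES blocks (with TRANSLATE tables), extracts display subtrees from a
    cached parent topology without re-inference while preserving patristic
    distances, computes phylogram and cladogram layouts with rectangular or
    triangular branches and aligned labels, and emits deterministic SVG with
    stable CSS class hooks, per-leaf hyperlinks and tooltips, and per-clade
    subtree links. Includes a seeded Yule tree simulator so every feature is
    testable without external data, an XML tree export, a preference-file
    reader, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'assets.R'
    'utils-internal.R'
    'newick.R'
    'xmltree.R'
    'synthgen.R'
    'nexus.R'
    'subtree.R'
    'layout.R'
    'svgrender.R'
    'preferences.R'
    'cli.R'
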