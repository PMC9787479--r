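Package: feronet
Title: Iron Effects on Rule-Based Abiotic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generation-wise expansion of small-molecule chemical reaction
    networks from declarative graph-transformation reaction rules, with and
    without iron-ion (Fe2+/Fe3+) redox chemistry. Molecules are canonicalized
    molecular graphs in a restricted SMILES dialect; reaction mechanisms are
    L/K/R-style edit rules applied exhaustively to a growing species pool
    under a nominal-mass cap. Ships curated rule libraries and seed sets for
    the formose, pyruvic acid, glucose-degradation and Maillard networks,
    comparison analytics between iron-free and iron-containing networks
    (catalysis detection, rule frequencies, degree metrics, growth fitting,
    saturation), a brute-force expansion oracle, and CSV/GraphML/GEXF export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    yaml,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
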