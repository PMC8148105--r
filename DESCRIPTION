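Package: glyphnet
Title: Typed Metabolic Network Graphs, Pathway Subnetworks and Multi-Omics Node Glyphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn SBML metabolic models (COBRA notes, fbc gene
    associations, SBO terms) into typed multi-partite graphs of species,
    reactions, genes and proteins; to decompose bipartite networks into
    pathway subnetworks joined by navigable linker nodes; to replicate
    highly connected co-factor hubs and remerge them; and to render
    per-node multi-omics glyph images (heatmaps, bars, lines, time series,
    scatter) with automatically generated legends, exported as SVG or PNG
    together with GraphML, Cytoscape.js JSON and SIF network files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    xml2,
    jsonlite,
    readr,
    igraph,
    ggplot2,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
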