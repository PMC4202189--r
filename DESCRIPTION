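Package: pathbic
Title: Shared Components Across Biological Pathway Networks via Maximal
    Bicliques
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes collections of biological pathway networks
    (SIF-style edge files) into uniquely identified gene-gene edges,
    builds the edges-by-pathways bipartite incidence structure, and
    enumerates all maximal bicliques, i.e. groups of edges shared by
    groups of pathways. Bicliques are arranged into a hierarchical
    similarity graph (the Hasse diagram of pathway-set containment)
    whose top node is the subgraph shared by the most pathways.
    Per-biclique gene graphs, breadth-first-search connected components,
    largest-component selection, root augmentation with edges from two
    hierarchy levels below, and coloring of genes by their highest
    hierarchical membership support visualization and discovery of
    shared kernel subgraphs. A synthetic generator plants nested shared
    kernels so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
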