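Package: cxviz
Title: Data-Dependent Styling, Layout and Export of Biological Networks in CX Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, validate, style and export biological networks stored in the
    Cytoscape Exchange (CX) aspect format. Provides lossless CX parsing and
    serialization (including custom aspects), discrete, continuous and
    pass-through attribute-to-visual mappings with default-property fallback
    and per-element bypasses, attribute summaries and histograms, rule-based
    element highlighting, seven graph layout algorithms (random, grid,
    circular, concentric, breadth-first, force-directed spring embedder and
    preset restoration), deterministic SVG rendering with PNG/JPEG
    rasterization, an optional NDEx transfer client, a seeded generator of
    protein-interaction-style fixture networks, and a command-line interface
    over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    curl,
    igraph,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
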