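Package: netkin
Title: Network Module Detection, Overrepresentation Analysis and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates undirected networks by detecting communities,
    testing each community for overrepresentation of annotation terms
    (permutation, hypergeometric, chi-squared and binomial tests over a
    sparse node-by-term membership matrix), scoring clustering quality on
    2-D layouts (compactness, separation, silhouette), and rendering
    contour-overlay visualizations. Includes a synthetic scale-free
    benchmark generator with simulated annotation tables so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
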