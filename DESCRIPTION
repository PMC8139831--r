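Package: devconn
Title: Developmental Origin and Circuit Structure in Synapse-Resolution Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating neuronal developmental origin (neuroblast lineage,
    hemilineage, temporal cohort) to circuit structure in synapse-resolution
    connectomes. Provides readers for SWC skeletons and polyadic connector tables,
    skeleton morphometrics (Strahler pruning, cortex neurite length, temporal-cohort
    binning, dotprops morphology clustering), spatial synapse-similarity and
    pre/post overlap kernels, kernel density maps of synapse position, connectivity
    similarity and synaptic network distance statistics, degree-preserving
    Monte-Carlo null models of connectivity, and a ground-truth-labelled synthetic
    connectome generator that makes every stage testable without an electron
    microscopy dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
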