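Package: satconnect
Title: Satellite Repeat Discovery, Clustering and Evolution Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for mining shotgun sequencing data for satellite DNA
    repeats and comparing repeat repertoires across species. Merges
    paired-end reads, screens them for repeat content against a satellite
    clone library, clusters retained reads by sequence identity with
    per-library composition, normalized abundances and Shannon diversity,
    and connects the clusters in a minimum spanning tree of pairwise
    similarities. Companion analyses build consensus monomers,
    intra/interspecific identity matrices, scan for CENP-B box motifs and
    model in-silico restriction digestion of tandem arrays. A simulator
    evolves satellite monomer families along a species tree under
    concerted-evolution (molecular drive) or conserved regimes and
    generates paired-end reads, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
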