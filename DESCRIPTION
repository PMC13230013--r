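Package: micnetsim
Title: Simulation of Microbial Communities and 16S Count Tables from Known
    Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic 16S rDNA-seq count tables whose ground-truth
    microbial interaction network is known. A directed, signed interaction
    network (user-supplied or generated with Erdos-Renyi or directed
    Barabasi-Albert topologies) is translated into consumer-preference and
    metabolic matrices of a microbial consumer-resource model, community
    dynamics are integrated to steady state, biological samples are produced
    by perturbing the resource environment, and sequencing is emulated by
    multivariate hypergeometric subsampling at specified library sizes. A
    benchmarking harness scores network-inference methods against the known
    network with the Matthews correlation coefficient and topological metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
biocViews: Microbiome, Sequencing, Software, NetworkInference, Metagenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
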