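Package: connectoscope
Title: Statistical Analysis of Mesoscale Cortical Connectomes from Retrograde Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted, directed interareal connectomes from retrograde
    tracer labeled-cell tables and characterises their statistical structure.
    Computes fraction-of-extrinsic-labeled-neuron (FLN) connection weights and
    supragranular labeled-neuron (SLN) laminar fractions, aggregates replicate
    injections, and extracts the edge-complete subnetwork. Provides binary
    graph analyses (density, degree distributions, dyad and triad motif
    censuses against degree-preserving nulls, clique enumeration and the
    core-periphery partition, similarity-distance connection probability),
    a beta-regression estimator of the cortical hierarchy with a circular
    hierarchy-plus-weights embedding, exponential-distance-rule fits of axonal
    projection lengths, cross-species allometric scaling of the decay rate,
    and correlations of the hierarchy with microstructural gradients. A
    synthetic-connectome generator with known ground truth makes every stage
    testable without access to the source atlas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
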