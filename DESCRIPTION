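Package: lineagecx
Title: Lineage Annotation and Synaptic Architecture of the Insect Central Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating neuroblast lineages in synapse-resolution
    connectomes and summarising the synaptic architecture of the central
    complex (CX) large-field network. Reduces neuron skeletons (SWC, nm
    scale) to their lineage-tract backbones by an iterative twig-pruning and
    fragment-selection rule set, assigns neurons to lineages from tract
    geometry against annotated bundle seeds, applies the CX large-field
    catalog inclusion filter, and computes compartment-level synaptic
    summaries: group-by-group connection matrices, max-normalised heatmap
    tables, lineage input fractions, per-neuron T-bar counts, pairwise
    connection-strength ECDFs, toroidal (ellipsoid-body) circular
    projections and domain-occupancy tables. Ships a deterministic
    synthetic-connectome generator with planted ground truth (bundles,
    compartments, connectivity blocks) so the whole pipeline is testable
    without any remote data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
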