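Package: commarch
Title: Community Architecture of Complex Networks: Segregation, Overlap,
    and Their Functional Consequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes the community architecture of undirected
    networks along two axes: community segregation (Newman-Girvan
    modularity of the best Louvain partition) and community overlap (mean
    link-community memberships per node, optionally normalized by
    degree-preserving random nulls). Includes planted-partition and
    Erdos-Renyi generators with a segregation-vs-overlap parameter sweep,
    degree-preserving randomized and latticized null models, a topological
    reinforcement rewiring model with routing (global/local efficiency)
    and diffusion (linear threshold) communication readouts,
    sliding-window dynamic functional connectivity with per-node dynamic
    flexibility, and a synthetic cohort generator with planted
    structure-dynamics-behavior couplings for end-to-end pipeline
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
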