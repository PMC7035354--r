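Package: metanet
Title: Topological Analysis of Metabolic Brain Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level metabolic covariance networks from subject-by-ROI
    uptake tables, analysed with threshold-free topology: correlation-derived
    distance matrices d = sqrt(1 - r), graph filtration with beta0-curves,
    single-linkage matrices and dendrograms, minimum spanning trees with
    region-set modularization scores, volume entropy of weighted graphs via a
    generalized Markov system on directed edges (edge and node capacities),
    global efficiency, and a permutation + Benjamini-Hochberg statistical
    layer (sampled unpaired, exhaustive paired sign-flip, bootstrap). Includes
    a synthetic paired two-group two-timepoint cohort generator with
    block-modular correlation structure and behavioral phenotyping (marble
    burying, open field, delay discounting) so the full workflow is testable
    without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
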