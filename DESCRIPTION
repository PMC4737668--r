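Package: gmsv
Title: Discriminative Subgraph Mining from Brain Networks with Side-View Guidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects discriminative subgraph patterns from datasets of labeled
    graphs (such as fMRI or DTI brain connectivity networks) under the guidance
    of vector-valued side views (clinical, immunologic, serologic or cognitive
    measures recorded per subject). Implements the gSide evaluation criterion,
    a Laplacian quadratic form built from label constraints and side-view
    kernel similarity, together with its lower bound, and a gSpan-based
    branch-and-bound search (gMSV) for the top-k lowest-scoring patterns.
    Includes a side-information consistency test, utilities for thresholding
    weighted connectivity matrices into binary graphs, a seeded synthetic-data
    generator with planted subgraphs, and a cross-validated classification
    harness combining subgraph features with side views.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
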