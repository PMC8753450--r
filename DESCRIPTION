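Package: clonodyn
Title: Longitudinal T-Cell Clonal Dynamics from Bulk and Single-Cell Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for longitudinal T-cell receptor beta (TCRbeta)
    repertoire analysis. Identifies significantly expanded or contracted
    clonotypes between timepoints with a conditional exact test whose null has
    beta-binomial component marginals (degenerating to Fisher's exact test at
    zero overdispersion), applies Benjamini-Hochberg false-discovery control,
    and flags novel expansions from low or undetectable baseline frequency.
    Tracks clone trajectories across blood and marrow, links bulk-identified
    clonotypes into CITE-seq single-cell data via CDR3 matching, gates T-cell
    subsets on antibody-derived-tag counts, computes supervised differential
    expression signatures, per-cell gene-module scores, and subset-resolved
    repertoire clonality, and quantifies the sampling bias of single-cell-only
    clone discovery by subsample-overlap curves and an emergent-clone audit.
    A synthetic-data generator with known ground truth (power-law clone sizes,
    beta-binomial count noise, spiked expansions, subset-structured marker
    counts, gene-module activation) makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
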