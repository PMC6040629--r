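Package: stemtrace
Title: Ancestral Gene-Family Content Reconstruction from Homology Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the gene-family content of ancestral nodes on a
    rooted species tree from all-vs-all protein homology searches. Gene-family
    membership is scored probabilistically by rescaling each protein's average
    BLAST E-value to its family co-members through the empirical cumulative
    distribution of all search E-values, and family origins are assigned to
    named ancestors (e.g. the Urmetazoan and Urchoanozoan) with parsimony
    rules over major species groups and sub-groups. Includes Dollo parsimony
    reconstruction, retention and core-family summaries, heat-map ordering by
    presence pattern with uncentered-Pearson clustering, cross-contamination
    filtering of multiplexed transcriptome assemblies, error-correction and
    expression noise filters, a declarative protein domain-architecture
    evidence engine, and a synthetic-data generator that emulates gene-family
    gain and loss along a species tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
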