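Package: substratomics
Title: Kinase Consensus Motif Statistics and Secretory-Pathway Substratome Definition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining the putative substratome of a secretory-pathway
    kinase from curated phosphosite data. Implements probability-logo style
    exact binomial significance statistics on phosphosite sequence windows with
    Bonferroni-corrected thresholds, a compartment/membrane-topology filter
    cascade selecting luminal S-x-E phosphosites, glutamate-preference
    profiling of acidophilic kinases from peptide-library scoring matrices,
    novelty comparison against validated substrate lists, hypergeometric
    annotation enrichment with Benjamini-Hochberg correction, and screening of
    clinical missense variants hitting motif serines or the +2 glutamate. A
    synthetic phosphoproteome generator with planted motif signal makes every
    stage testable without database downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
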