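Package: dcsim
Title: Domain Combination Similarity for Protein Function Prediction in
    Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts Gene Ontology annotations for uncharacterized proteins
    by transferring functions from the most similar annotated proteins in a
    protein-protein interaction network.  Similarity between two proteins is
    the negative log hypergeometric probability of the observed overlap of
    their Pfam domain-type sets, combining a context term (domains of the
    closed interaction neighborhood, or of the protein complexes containing
    the protein) with a composition term (domains of the proteins
    themselves).  Includes leave-one-out and leave-percent-out
    cross-validation with precision, recall, F-measure and Matthews
    correlation summaries, precision-recall curves over a top-K sweep,
    neighbor-counting and chi-square baselines, GO annotation filtering with
    optional ontology ancestor propagation, and a seeded generator of
    synthetic benchmark bundles with planted functional modules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
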