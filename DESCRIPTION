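Package: mlnmatch
Title: Ontology Matching by MAP Inference in Markov Logic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns two anatomy ontologies by grounding weighted first-order
    matching formulas (a priori label similarity, one-to-one cardinality,
    coherence with disjointness, structural stability, and match propagation)
    over a threshold-pruned candidate set, and selecting the
    maximum-a-posteriori alignment by exact combinatorial optimization.
    Includes readers for OWL (RDF/XML) ontologies and OAEI-style alignment
    files, precision/recall/F-measure evaluation, and a synthetic
    ontology-pair generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, xml2
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
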