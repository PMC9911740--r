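Package: textzero
Title: Zero-Shot Annotation of Biological Data from Ontology Text Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Embeds textual descriptions of biological classes (ontology terms,
    cell types, pathways, phenotypes) and non-text biological instances
    (expression profiles, protein sequences, network features, molecular
    fingerprints) in one shared vector space. A bi-nonlinear classifier
    scoring an instance embedding against a class text embedding through a
    learned bilinear form enables zero-shot annotation of classes that have
    no annotated training examples, cross-modal association prediction
    without any paired data, and marker-gene discovery for unseen cell
    types. Includes an OBO ontology parser with true-path annotation
    propagation, a contrastive fine-tuning procedure for pluggable text
    encoders, a multi-kernel convolutional sequence encoder, text, graph and
    annotation similarity statistics, and seeded synthetic-data generators
    that emulate the statistical structure the method exploits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
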