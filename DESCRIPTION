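Package: aotk
Title: Stand-Off Annotation of Web Documents with the Annotation Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for stand-off annotation of web documents: a domain
    model for annotations, agents, source-document provenance, curation
    tokens and versioned annotation sets; robust fragment selectors
    (prefix/exact/postfix text quotes, offset ranges, XPointer
    pass-through, image bounding boxes) with the normalization and
    anchoring algorithms that keep them resolvable as documents mutate;
    lossless RDF serialization and parsing (Turtle, RDF/XML, N-Triples,
    JSON-LD) in the Annotation Ontology namespaces with Annotea and MOAT
    interoperability; SKOS-graded qualifier semantics with cross-ontology
    mapping inference; an append-only lifecycle store for curation chains,
    versioning, branching and supersession; and a synthetic document and
    mutation generator for benchmarking anchor robustness without external
    data.
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
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
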