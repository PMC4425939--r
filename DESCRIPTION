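Package: ciotools
Title: Confidence Information Ontology Tools for Annotation Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the Confidence Information Ontology (CIO) used by
    biocuration teams to attach confidence statements to annotations.
    Provides an OBO parser and writer restricted to is_a subsumption
    structure, a typed model of the CIO statement axes (evidence arity,
    evidence-type multiplicity, concordance, overall confidence level,
    rejection), evidence-type comparison over the Evidence and Conclusion
    Ontology (ECO), a configurable rule engine that aggregates
    single-evidence confidence annotations into summary statements
    (detecting congruent, weakly conflicting and strongly conflicting
    evidence groups), readers and writers for GAF 2.0-style gene
    association files and Bgee anatomical-similarity TSV files, legacy
    confidence imputation, a file-level summarisation and validation
    pipeline with a command-line interface, and a synthetic annotation
    generator plus an independent decision-table oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
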