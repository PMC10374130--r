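Package: crossmapr
Title: Cross-Classification Concept Mapping and Harmonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing typed concept mappings between
    two health classification hierarchies, modelled on the harmonization of
    ICF Body Structures with the ICD-11 Anatomic Detail extension codes.
    Reads classifications from ClaML XML and from offline snapshots of the
    ICD-11 Foundation entity model, flags residual ("other specified" /
    "unspecified") categories, auto-detects lexical equivalences including
    the "Structure of X" synonym rule, manages multi-rater typed mapping
    assertions, computes inter-observer agreement and hierarchy-aware
    redundancy, consolidates assertions by relation priority, and serializes
    the result as an SSSOM mapping-set TSV with SKOS match predicates.
    Ships a synthetic fixture generator and a simulated-rater model so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
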