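Package: exoanno
Title: Multi-Level Stand-Off Annotation Toolkit for Clinical Exome
    Sequencing Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A typed stand-off annotation data model for clinical exome
    sequencing reports (16 entity types, 7 directed relation types with a
    domain/range constraint table), validators for HGVS variant notation and
    OMIM/ClinVar/dbSNP identifiers, a seeded template-based generator that
    renders structured gene-variant-disease records into Russian-style report
    text with gold character-offset annotations, inter-annotator agreement
    metrics (exact span F1, per-category token-level Cohen's kappa), exact-match
    NER/RE scoring with micro/macro aggregates, stratified 70/15/15 corpus
    splitting and corpus statistics, and lossless converters for Label Studio
    JSON, JSONL stand-off, and BIO/CoNLL formats.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
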