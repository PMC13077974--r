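#' Bundled reference benchmark tables
#'
#' Published baseline results for transformer NER/RE models on a
#' multi-level annotated corpus of clinical exome reports, shipped as plain
#' TSV inputs so the package's metric arithmetic can be demonstrated and
#' checked against independently printed aggregates: `ner` (per-model
#' precision/recall), `re` (per-relation-type F1 per model, using the
#' relation names as printed, which for two types differ from the canonical
#' inventory — see [normalize_relation_alias()]), `iaa` (per-category
#' annotator percentages and Cohen's kappa), and `corpus_counts`
#' (per-source report and entity totals).
#'
#' @return a list of four tibbles: `ner`, `re`, `iaa`, `corpus_counts`.
#' @examples
#' b <- reference_benchmarks()
#' round_half_away(f1_from_pr(b$ner$precision, b$ner$recall), 2)
#' @export
reference_benchmarks <- function() {
  dir <- system.file("extdata", "benchmarks", package = "exoanno", mustWork = TRUE)
  rd <- function(f) {
    readr::read_tsv(file.path(dir, f), show_col_types = FALSE, progress = FALSE)
  }
  list(
    ner = rd("ner_results.tsv"),
    re = rd("re_results.tsv"),
    iaa = rd("iaa_kappa.tsv"),
    corpus_counts = rd("corpus_counts.tsv")
  )
}
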