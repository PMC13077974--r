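#' Closed annotation vocabularies
#'
#' The annotation scheme is built on four closed vocabularies: 16 entity
#' types covering the clinical-genetic workflow (gene, variant notation,
#' disease, ACMG/AMP significance, zygosity, inheritance, knowledge-base
#' identifiers, phenotype, and the recommendation-style categories), 8
#' clinical significance codes, 8 inheritance modes, and 7 directed relation
#' types. Membership is case-sensitive on the canonical upper-case tokens.
#'
#' @return a character vector of canonical codes.
#' @examples
#' entity_types()
#' significance_values()
#' @export
entity_types <- function() {
  c(
    "GENE", "CDNA_PROT", "VARIANT_LOC", "DISEASE", "SIGNIFICANCE",
    "ZYGOSITY", "INHERITANCE_MODE", "OMIM_ID", "CLINVAR_ID", "DBSNP_ID",
    "PHENOTYPE", "RECOMMENDATION", "EXON_NUMBER", "DIAGNOSTIC_METHOD",
    "RETEST_PLAN", "THERAPY_RECOMMENDATION"
  )
}

#' @rdname entity_types
#' @export
significance_values <- function() {
  c(
    "PATHOGENIC", "LIKELY_PATHOGENIC", "VUS", "LIKELY_BENIGN", "BENIGN",
    "PROTECTIVE", "RISK_FACTOR", "DRUG_RESPONSE"
  )
}

#' @rdname entity_types
#' @export
inheritance_modes <- function() {
  c(
    "AD", "AR", "XLD", "XLR", "Y_LINKED", "MITOCHONDRIAL", "DE_NOVO",
    "COMPOUND_HET"
  )
}

#' Relation inventory with domain/range constraints
#'
#' Each of the 7 directed relation types is constrained by the entity types
#' admissible as its head (source) and tail (target): a variant notation or
#' genomic location points to its gene, a gene to its associated disease, a
#' variant to its significance or zygosity, a disease to its inheritance
#' mode or OMIM identifier, and a phenotype to the disease it supports.
#'
#' @return a tibble with columns `type`, `head_types` (list), `tail_types`
#'   (list).
#' @examples
#' relation_types()
#' @export
relation_types <- function() {
  tibble(
    type = c(
      "VARIANT_IN_GENE", "GENE_ASSOCIATED_WITH", "VARIANT_SIGNIFICANCE",
      "DISEASE_INHERITANCE_MODE", "PHENOTYPE_SUPPORTS_DISEASE",
      "DISEASE_OMIM_ID", "VARIANT_ZYGOSITY"
    ),
    head_types = list(
      c("CDNA_PROT", "VARIANT_LOC"), "GENE", c("CDNA_PROT", "VARIANT_LOC"),
      "DISEASE", "PHENOTYPE", "DISEASE", c("CDNA_PROT", "VARIANT_LOC")
    ),
    tail_types = list(
      "GENE", "DISEASE", "SIGNIFICANCE", "INHERITANCE_MODE", "DISEASE",
      "OMIM_ID", "ZYGOSITY"
    )
  )
}

vocab_check <- function(token, vocabulary, what) {
  if (!is_string(token) || !token %in% vocabulary) {
    abort(
      sprintf("unknown %s: '%s'", what, paste(token, collapse = ",")),
      class = "exoanno_vocab_error"
    )
  }
  invisible(token)
}

#' Check a relation against the domain/range constraint table
#'
#' @param rel_type canonical relation type name.
#' @param head_type,tail_type entity type names of the head and tail span.
#' @return `TRUE` iff `head_type` is an admissible head and `tail_type` an
#'   admissible tail for `rel_type`.
#' @examples
#' check_relation_constraint("VARIANT_IN_GENE", "CDNA_PROT", "GENE") # TRUE
#' check_relation_constraint("VARIANT_IN_GENE", "GENE", "CDNA_PROT") # FALSE
#' @export
check_relation_constraint <- function(rel_type, head_type, tail_type) {
  rt <- relation_types()
  vocab_check(rel_type, rt$type, "relation type")
  vocab_check(head_type, entity_types(), "entity type")
  vocab_check(tail_type, entity_types(), "entity type")
  row <- match(rel_type, rt$type)
  head_type %in% rt$head_types[[row]] && tail_type %in% rt$tail_types[[row]]
}

#' Default relation-name alias table
#'
#' The published description of the scheme uses divergent lower-case names
#' for two relation types in its evaluation tables (`disease_inheritance`,
#' `disease_omim_link`); the canonical inventory of [relation_types()] is
#' authoritative and these synonyms are reconciled only through this table.
#' Names that are neither canonical nor aliased are a hard error, never
#' passed through.
#'
#' @return named character vector, lower-case alias -> canonical name.
#' @export
relation_aliases <- function() {
  c(
    disease_inheritance = "DISEASE_INHERITANCE_MODE",
    disease_inheritance_mode = "DISEASE_INHERITANCE_MODE",
    disease_omim_link = "DISEASE_OMIM_ID",
    disease_omim_id = "DISEASE_OMIM_ID"
  )
}

#' Normalize a relation name to its canonical form
#'
#' Comparison is case-insensitive; canonical names map to themselves.
#'
#' @param name relation name or alias.
#' @param alias_table named character vector mapping lower-case aliases to
#'   canonical names; defaults to [relation_aliases()].
#' @return the canonical relation type name.
#' @examples
#' normalize_relation_alias("disease_inheritance") # DISEASE_INHERITANCE_MODE
#' normalize_relation_alias("variant_in_gene")     # VARIANT_IN_GENE
#' @export
normalize_relation_alias <- function(name, alias_table = relation_aliases()) {
  stopifnot(is_string(name))
  lower <- tolower(name)
  canonical <- relation_types()$type
  hit <- match(toupper(name), canonical)
  if (!is.na(hit)) {
    return(canonical[hit])
  }
  if (lower %in% names(alias_table)) {
    out <- unname(alias_table[[lower]])
    vocab_check(out, canonical, "relation type")
    return(out)
  }
  abort(
    sprintf("unknown relation name: '%s' (not canonical, no alias configured)", name),
    class = "exoanno_unknown_relation_error"
  )
}

#' Construct entity and relation tables
#'
#' Entities are stand-off spans over the document text: 0-based, half-open
#' character offsets `[start, end)` (Label Studio's export convention), so
#' `surface` must equal the text slice. `norm` holds the optional normalized
#' payload (HGNC symbol, canonical HGVS, vocabulary code, identifier) and
#' `parent_id` an optional enclosing/governing entity for nested annotation.
#'
#' @param id,type,start,end,surface,norm,parent_id entity span fields.
#' @return a tibble with one row per span / relation.
#' @examples
#' entity_tbl(id = "e1", type = "GENE", start = 0L, end = 5L, surface = "BRCA1")
#' @export
entity_tbl <- function(id = character(), type = character(),
                       start = integer(), end = integer(),
                       surface = character(), norm = NA_character_,
                       parent_id = NA_character_) {
  n <- max(length(id), length(type), length(start), length(end), length(surface))
  if (n == 0) {
    return(tibble(
      id = character(), type = character(), start = integer(),
      end = integer(), surface = character(), norm = character(),
      parent_id = character()
    ))
  }
  tibble(
    id = as.character(id), type = as.character(type),
    start = as.integer(start), end = as.integer(end),
    surface = as.character(surface),
    norm = rep_len(as.character(norm), n),
    parent_id = rep_len(as.character(parent_id), n)
  )
}

#' @rdname entity_tbl
#' @param head_id,tail_id ids of the head and tail entity span.
#' @export
relation_tbl <- function(id = character(), type = character(),
                         head_id = character(), tail_id = character()) {
  tibble(
    id = as.character(id), type = as.character(type),
    head_id = as.character(head_id), tail_id = as.character(tail_id)
  )
}

#' Construct an annotated document / bind documents into a corpus
#'
#' A document is the triple (text, entities, relations) plus identity and
#' provenance metadata; a corpus is a tibble with one document per row,
#' entities and relations held in list-columns.
#'
#' @param doc_id unique document identifier.
#' @param text report text.
#' @param entities an [entity_tbl()].
#' @param relations a [relation_tbl()].
#' @param source `"authentic"` or `"synthetic"`.
#' @param language BCP-47 language tag.
#' @return a one-row corpus tibble (class `exoanno_corpus`).
#' @examples
#' d <- document("d1", "Pathogenic variant in BRCA1",
#'   entities = entity_tbl("e1", "GENE", 22L, 27L, "BRCA1", norm = "BRCA1")
#' )
#' @export
document <- function(doc_id, text, entities = entity_tbl(),
                     relations = relation_tbl(), source = "synthetic",
                     language = "ru") {
  stopifnot(is_string(doc_id), is_string(text))
  if (!source %in% c("authentic", "synthetic")) {
    abort(sprintf("unknown source: '%s'", source), class = "exoanno_vocab_error")
  }
  as_corpus(tibble(
    doc_id = doc_id, source = source, language = language, text = text,
    entities = list(entities), relations = list(relations)
  ))
}

#' @rdname document
#' @param x a tibble with corpus columns.
#' @export
as_corpus <- function(x) {
  needed <- c("doc_id", "source", "language", "text", "entities", "relations")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(
      paste("not a corpus, missing columns:", paste(missing, collapse = ", ")),
      class = "exoanno_corpus_error"
    )
  }
  if (anyDuplicated(x$doc_id)) {
    abort(
      paste(
        "duplicated doc_id:",
        paste(unique(x$doc_id[duplicated(x$doc_id)]), collapse = ", ")
      ),
      class = "exoanno_corpus_error"
    )
  }
  class(x) <- unique(c("exoanno_corpus", class(tibble())))
  x
}

#' @rdname document
#' @param ... one-row corpus tibbles (or multi-row corpora) to bind.
#' @export
corpus <- function(...) {
  as_corpus(bind_rows(...))
}

#' @rdname document
#' @export
empty_corpus <- function() {
  as_corpus(tibble(
    doc_id = character(), source = character(), language = character(),
    text = character(), entities = list(), relations = list()
  ))
}

#' @export
print.exoanno_corpus <- function(x, ...) {
  n_ent <- sum(map_int(x$entities, nrow))
  n_rel <- sum(map_int(x$relations, nrow))
  cat(sprintf(
    "<annotated corpus: %d document(s), %d entities, %d relations>\n",
    nrow(x), n_ent, n_rel
  ))
  NextMethod()
}
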