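# slot name -> knowledge-record field
SLOT_FIELDS <- c(
  gene = "gene", gene_b = "gene", gene_c = "gene", cdna = "hgvs_c",
  prot = "hgvs_p", gloc = "genomic", disease = "disease",
  disease_b = "disease", significance = "significance", zygosity = "zygosity",
  inheritance = "inheritance", omim = "omim_id", clinvar = "clinvar_rcv",
  dbsnp = "dbsnp", phenotype = "phenotypes", recommendation = "recommendation",
  retest = "retest_plan", therapy = "therapy", method = "diagnostic_method",
  exon = "exon"
)

SIG_SURFACE <- list(
  ru = c(
    PATHOGENIC = "патогенный",
    LIKELY_PATHOGENIC = "вероятно патогенный",
    VUS = "вариант неопределенного клинического значения (VUS)",
    LIKELY_BENIGN = "вероятно доброкачественный",
    BENIGN = "доброкачественный",
    PROTECTIVE = "протективный",
    RISK_FACTOR = "фактор риска",
    DRUG_RESPONSE = "фармакогенетический"
  ),
  en = c(
    PATHOGENIC = "pathogenic", LIKELY_PATHOGENIC = "likely pathogenic",
    VUS = "variant of uncertain clinical significance (VUS)",
    LIKELY_BENIGN = "likely benign", BENIGN = "benign",
    PROTECTIVE = "protective", RISK_FACTOR = "risk factor",
    DRUG_RESPONSE = "drug response"
  )
)

INH_SURFACE <- list(
  ru = c(
    AD = "аутосомно-доминантный",
    AR = "аутосомно-рецессивный",
    XLD = "X-сцепленный доминантный",
    XLR = "X-сцепленный рецессивный",
    Y_LINKED = "Y-сцепленный",
    MITOCHONDRIAL = "митохондриальный",
    DE_NOVO = "de novo",
    COMPOUND_HET = "компаунд-гетерозиготный"
  ),
  en = c(
    AD = "autosomal dominant", AR = "autosomal recessive",
    XLD = "X-linked dominant", XLR = "X-linked recessive",
    Y_LINKED = "Y-linked", MITOCHONDRIAL = "mitochondrial",
    DE_NOVO = "de novo", COMPOUND_HET = "compound heterozygous"
  )
)

EXON_WORD <- c(ru = "экзон", en = "exon")

#' Load a template bank
#'
#' A template bank is a JSON file describing report templates: each template
#' is a list of sentence patterns with named `{slot}` placeholders, a
#' slot-to-entity-type mapping, and relation/nesting recipes between slots.
#' Every relation recipe is checked against the domain/range constraint
#' table on load, so a loadable bank can only generate schema-valid
#' relations. Banks in Russian (the corpus language, with Latin-script HGVS
#' and gene tokens embedded) and English (used in documentation and tests)
#' are bundled.
#'
#' @param path JSON file; when `NULL` the bundled bank for `language` is
#'   used.
#' @param language `"ru"` or `"en"` (bundled banks).
#' @return a template bank (list, class `exoanno_bank`).
#' @export
load_template_bank <- function(path = NULL, language = "ru") {
  if (is.null(path)) {
    path <- system.file("extdata", paste0("templates_", language, ".json"),
      package = "exoanno", mustWork = TRUE
    )
  }
  bank <- read_json(path, simplifyVector = FALSE)
  stopifnot(is.character(bank$language), length(bank$templates) >= 1)
  for (tpl in bank$templates) {
    for (sent in tpl$sentences) {
      slots <- unlist(sent$slots)
      pat_slots <- pattern_slots(sent$pattern)
      if (!setequal(pat_slots, names(slots))) {
        abort(sprintf(
          "template '%s': pattern slots {%s} do not match declared slots {%s}",
          tpl$id, paste(pat_slots, collapse = ","), paste(names(slots), collapse = ",")
        ), class = "exoanno_bank_error")
      }
      for (ty in slots) vocab_check(ty, entity_types(), "entity type")
      for (sl in names(slots)) {
        if (!sl %in% names(SLOT_FIELDS)) {
          abort(sprintf("template '%s': unknown slot name '%s'", tpl$id, sl),
            class = "exoanno_bank_error"
          )
        }
      }
    }
    type_of <- slot_types(tpl)
    for (rec in tpl$relations) {
      rec <- unlist(rec)
      if (!isTRUE(check_relation_constraint(rec[1], type_of[[rec[2]]], type_of[[rec[3]]]))) {
        abort(sprintf(
          "template '%s': relation recipe %s(%s,%s) violates the constraint table",
          tpl$id, rec[1], rec[2], rec[3]
        ), class = "exoanno_bank_error")
      }
    }
  }
  structure(bank, class = "exoanno_bank")
}

pattern_slots <- function(pattern) {
  m <- gregexpr("\\{[a-z_0-9]+\\}", pattern)[[1]]
  if (m[1] == -1) {
    return(character())
  }
  gsub("[{}]", "", regmatches(pattern, list(m))[[1]])
}

slot_types <- function(tpl) {
  out <- list()
  for (sent in tpl$sentences) out <- c(out, sent$slots)
  map_chr(out, identity)
}

#' Generation profile
#'
#' Bundles the knobs of a generation run: batch size, seed, per-sentence
#' inclusion probability for optional report elements, coverage mode and
#' language. In `coverage_mode = "full"` the batch is guaranteed (or errors)
#' to contain every one of the 16 entity types and 7 relation types at
#' least once; `"minimal"` samples freely.
#'
#' @param n_documents number of documents to generate.
#' @param seed integer seed; generation is a pure function of
#'   (records, bank, profile) including this seed.
#' @param optional_entity_probability probability in `[0,1]` that an
#'   optional report sentence is included (when the record supports it);
#'   either a single number or a vector named by entity type.
#' @param coverage_mode `"full"` or `"minimal"`.
#' @param language language tag selecting templates.
#' @return a profile (list, class `exoanno_profile`).
#' @export
generation_profile <- function(n_documents, seed = 1L,
                               optional_entity_probability = 0.7,
                               coverage_mode = c("full", "minimal"),
                               language = "ru") {
  stopifnot(
    n_documents >= 0,
    all(optional_entity_probability >= 0), all(optional_entity_probability <= 1)
  )
  structure(
    list(
      n_documents = as.integer(n_documents), seed = as.integer(seed),
      optional_entity_probability = optional_entity_probability,
      coverage_mode = match.arg(coverage_mode), language = language
    ),
    class = "exoanno_profile"
  )
}

slot_available <- function(record, slot) {
  field <- SLOT_FIELDS[[slot]]
  val <- record[[field]]
  if (field == "phenotypes") {
    return(length(val[[1]]) > 0)
  }
  !is.na(val)
}

sentence_available <- function(record, sent) {
  all(map_lgl(names(sent$slots), function(sl) slot_available(record, sl)))
}

template_eligible <- function(record, tpl) {
  req <- keep(tpl$sentences, function(s) !isTRUE(s$optional))
  all(map_lgl(req, function(s) sentence_available(record, s)))
}

opt_prob <- function(profile, type) {
  p <- profile$optional_entity_probability
  if (!is.null(names(p)) && type %in% names(p)) {
    return(unname(p[[type]]))
  }
  unname(p[[1]])
}

# resolve a slot to (surface, norm); surfaces embed record strings verbatim
# so offsets and validators stay stable (no morphological inflection).
slot_value <- function(record, slot, type, language) {
  field <- SLOT_FIELDS[[slot]]
  val <- record[[field]]
  switch(slot,
    significance = list(
      surface = unname(SIG_SURFACE[[language]][[val]]), norm = val
    ),
    inheritance = list(
      surface = unname(INH_SURFACE[[language]][[val]]), norm = val
    ),
    omim = list(surface = paste0("OMIM #", val), norm = val),
    clinvar = list(surface = val, norm = val),
    dbsnp = list(surface = val, norm = val),
    phenotype = {
      ph <- val[[1]]
      pick <- if (length(ph) > 1) ph[[sample.int(length(ph), 1)]] else ph[[1]]
      list(surface = pick, norm = NA_character_)
    },
    exon = list(
      surface = paste(EXON_WORD[[language]], val), norm = NA_character_
    ),
    cdna = list(surface = val, norm = render_hgvs(parse_hgvs_cdna(val))),
    prot = list(surface = val, norm = render_hgvs(parse_hgvs_protein(val))),
    gloc = list(surface = val, norm = render_hgvs(parse_genomic_loc(val, allow_region = TRUE))),
    gene = ,
    gene_b = ,
    gene_c = list(surface = val, norm = val),
    list(surface = as.character(val), norm = NA_character_)
  )
}

# Render one document; offsets are computed during rendering, never by
# post-hoc search. `force_optionals` switches every supportable optional
# sentence on (used by full-coverage scheduling).
render_document <- function(record, tpl, profile, doc_id,
                            force_optionals = FALSE) {
  language <- profile$language
  chunks <- character()
  offset <- 0L
  e_type <- e_surface <- e_norm <- character()
  e_start <- e_end <- integer()
  slot_entity <- character() # slot name -> entity id
  for (sent in tpl$sentences) {
    if (isTRUE(sent$optional)) {
      if (!sentence_available(record, sent)) next
      primary <- unlist(sent$slots)[[1]]
      if (!force_optionals && runif(1) >= opt_prob(profile, primary)) next
    } else if (!sentence_available(record, sent)) {
      missing <- names(sent$slots)[!map_lgl(names(sent$slots), function(sl) slot_available(record, sl))]
      abort(
        sprintf(
          "record '%s' is missing field(s) required by template '%s': %s",
          record$gene, tpl$id, paste(SLOT_FIELDS[missing], collapse = ", ")
        ),
        class = "exoanno_generation_error"
      )
    }
    if (offset > 0L) {
      chunks <- c(chunks, " ")
      offset <- offset + 1L
    }
    pattern <- sent$pattern
    m <- gregexpr("\\{[a-z_0-9]+\\}", pattern)[[1]]
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    cursor <- 1L
    for (k in seq_along(starts)) {
      lead <- substr(pattern, cursor, starts[k] - 1L)
      chunks <- c(chunks, lead)
      offset <- offset + n_chars(lead)
      slot <- substr(pattern, starts[k] + 1L, starts[k] + lens[k] - 2L)
      sv <- slot_value(record, slot, sent$slots[[slot]], language)
      n <- length(e_type) + 1L
      e_type[n] <- sent$slots[[slot]]
      e_start[n] <- offset
      e_end[n] <- offset + n_chars(sv$surface)
      e_surface[n] <- sv$surface
      e_norm[n] <- sv$norm %||% NA_character_
      slot_entity[[slot]] <- paste0("e", n)
      chunks <- c(chunks, sv$surface)
      offset <- offset + n_chars(sv$surface)
      cursor <- starts[k] + lens[k]
    }
    tail_chunk <- substr(pattern, cursor, n_chars(pattern))
    chunks <- c(chunks, tail_chunk)
    offset <- offset + n_chars(tail_chunk)
  }
  ids <- paste0("e", seq_along(e_type))
  # nesting links declared by the template (child governed by parent)
  parent <- rep(NA_character_, length(ids))
  for (p in tpl$parents %||% list()) {
    p <- unlist(p)
    if (all(p %in% names(slot_entity))) {
      parent[match(slot_entity[[p[1]]], ids)] <- slot_entity[[p[2]]]
    }
  }
  entities <- tibble(
    id = ids, type = e_type, start = e_start, end = e_end,
    surface = e_surface, norm = e_norm, parent_id = parent
  )
  r_type <- r_head <- r_tail <- character()
  for (rec in tpl$relations %||% list()) {
    rec <- unlist(rec)
    if (all(rec[2:3] %in% names(slot_entity))) {
      n <- length(r_type) + 1L
      r_type[n] <- rec[1]
      r_head[n] <- slot_entity[[rec[2]]]
      r_tail[n] <- slot_entity[[rec[3]]]
    }
  }
  document(doc_id, paste(chunks, collapse = ""),
    entities = entities,
    relations = tibble(
      id = paste0("r", seq_along(r_type)), type = r_type,
      head_id = r_head, tail_id = r_tail
    ),
    source = "synthetic", language = language
  )
}

#' Generate a single synthetic report
#'
#' Renders one knowledge record through a uniformly chosen eligible
#' template. Deterministic in `seed`: the same record, bank, profile and
#' seed reproduce a byte-identical document.
#'
#' @param record a one-row knowledge tibble.
#' @param bank a template bank (defaults to the bundled bank for the
#'   profile's language).
#' @param profile a [generation_profile()].
#' @param doc_id document identifier.
#' @param seed seed for this call (defaults to the profile seed).
#' @return a one-row corpus tibble.
#' @export
generate_report <- function(record, bank = NULL,
                            profile = generation_profile(1),
                            doc_id = "doc-00001", seed = profile$seed) {
  bank <- bank %||% load_template_bank(language = profile$language)
  elig <- keep(bank$templates, function(t) template_eligible(record, t))
  if (!length(elig)) {
    missing <- unique(unlist(map(bank$templates, function(tpl) {
      req <- keep(tpl$sentences, function(s) !isTRUE(s$optional))
      slots <- unlist(map(req, function(s) names(s$slots)))
      SLOT_FIELDS[slots[!map_lgl(slots, function(sl) slot_available(record, sl))]]
    })))
    abort(
      sprintf(
        "no template is satisfiable for this record; missing field(s): %s",
        paste(missing, collapse = ", ")
      ),
      class = "exoanno_generation_error"
    )
  }
  with_seed(seed, {
    tpl <- elig[[sample.int(length(elig), 1)]]
    render_document(record, tpl, profile, doc_id)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Samples records with replacement and templates uniformly among those the
#' record can fill, rendering each into report text with gold stand-off
#' annotations. In full coverage mode, (record, template) pairs covering
#' still-missing entity or relation types are scheduled first with all
#' optional report elements switched on; the remaining documents are
#' sampled freely. Every generated document satisfies [validate_document()]
#' by construction.
#'
#' @param records knowledge tibble (non-empty unless `n_documents` is 0).
#' @param bank template bank; defaults to the bundled bank for the
#'   profile's language.
#' @param profile a [generation_profile()].
#' @return a corpus tibble with `profile$n_documents` rows.
#' @examples
#' k <- load_knowledge()
#' corp <- generate_corpus(k, profile = generation_profile(5, seed = 7))
#' @export
generate_corpus <- function(records, bank = NULL, profile) {
  bank <- bank %||% load_template_bank(language = profile$language)
  n <- profile$n_documents
  if (n == 0) {
    return(empty_corpus())
  }
  if (nrow(records) == 0) {
    abort("records must be non-empty", class = "exoanno_generation_error")
  }
  elig <- map(seq_len(nrow(records)), function(i) {
    which(map_lgl(bank$templates, function(t) template_eligible(records[i, ], t)))
  })
  usable <- which(lengths(elig) > 0)
  if (!length(usable)) {
    abort("no record can fill any template in the bank",
      class = "exoanno_generation_error"
    )
  }
  schedule <- list()
  if (profile$coverage_mode == "full") {
    uncovered <- c(
      paste0("ENT:", entity_types()),
      paste0("REL:", relation_types()$type)
    )
    pair_cover <- function(ri, ti) {
      tpl <- bank$templates[[ti]]
      rec <- records[ri, ]
      realized <- character()
      types <- character()
      for (sent in tpl$sentences) {
        if (!sentence_available(rec, sent)) next
        realized <- c(realized, names(sent$slots))
        types <- c(types, paste0("ENT:", unlist(sent$slots)))
      }
      for (r in tpl$relations %||% list()) {
        r <- unlist(r)
        if (all(r[2:3] %in% realized)) types <- c(types, paste0("REL:", r[1]))
      }
      unique(types)
    }
    pairs <- list()
    for (ri in usable) for (ti in elig[[ri]]) pairs[[length(pairs) + 1]] <- c(ri, ti)
    covers <- map(pairs, function(p) pair_cover(p[1], p[2]))
    while (length(uncovered) > 0) {
      gains <- map_int(covers, function(cv) length(intersect(cv, uncovered)))
      if (max(gains) == 0 || length(schedule) >= n) {
        abort(
          paste(
            "full coverage unattainable with this bank/records; missing:",
            paste(uncovered, collapse = ", ")
          ),
          class = "exoanno_coverage_error"
        )
      }
      best <- which.max(gains)
      schedule[[length(schedule) + 1]] <- pairs[[best]]
      uncovered <- setdiff(uncovered, covers[[best]])
    }
  }
  with_seed(profile$seed, {
    docs <- vector("list", n)
    for (i in seq_len(n)) {
      if (i <= length(schedule)) {
        ri <- schedule[[i]][1]
        ti <- schedule[[i]][2]
        forced <- TRUE
      } else {
        ri <- usable[[sample.int(length(usable), 1)]]
        ti <- elig[[ri]][[sample.int(length(elig[[ri]]), 1)]]
        forced <- FALSE
      }
      docs[[i]] <- render_document(
        records[ri, ], bank$templates[[ti]], profile,
        sprintf("doc-%05d", i),
        force_optionals = forced
      )
    }
    as_corpus(bind_rows(docs))
  })
}

#' Count entity and relation types across a corpus
#'
#' Supports the claim that a generated batch covers the full scheme:
#' zero-count types are listed explicitly, so `"full"` coverage holds iff
#' no `count` is zero.
#'
#' @param corpus a corpus tibble.
#' @return a tibble with columns `kind` (`entity`/`relation`), `type`,
#'   `count` — one row for each of the 16 + 7 types.
#' @export
coverage_report <- function(corpus) {
  ent <- if (nrow(corpus)) bind_rows(corpus$entities) else entity_tbl()
  rel <- if (nrow(corpus)) bind_rows(corpus$relations) else relation_tbl()
  bind_rows(
    tibble(
      kind = "entity", type = entity_types(),
      count = map_int(entity_types(), function(t) sum(ent$type == t))
    ),
    tibble(
      kind = "relation", type = relation_types()$type,
      count = map_int(relation_types()$type, function(t) sum(rel$type == t))
    )
  )
}
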