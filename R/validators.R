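# Russian clinical text freely mixes alphabets; upper/lower-case Cyrillic
# letters that look identical to Latin ones routinely leak into HGVS strings
# and identifiers. All notation validators map homoglyphs to Latin before
# matching and record that a substitution happened.
CYRILLIC_HOMOGLYPHS <- "АВСЕНКМОРТХУасеорух"
LATIN_TWINS <- "ABCEHKMOPTXYaceopyx"

strip_homoglyphs <- function(s) {
  out <- chartr(CYRILLIC_HOMOGLYPHS, LATIN_TWINS, s)
  list(text = out, changed = !identical(out, s))
}

AA3 <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

new_hgvs_parse <- function(level, raw, change_kind, position_text,
                           ref_allele = NA_character_,
                           alt_allele = NA_character_,
                           homoglyphs_normalized = FALSE) {
  structure(
    list(
      level = level, raw = raw, change_kind = change_kind,
      position_text = position_text, ref_allele = ref_allele,
      alt_allele = alt_allele, homoglyphs_normalized = homoglyphs_normalized
    ),
    class = "exoanno_hgvs"
  )
}

#' @export
print.exoanno_hgvs <- function(x, ...) {
  cat(sprintf(
    "<hgvs %s %s: %s at %s%s>\n", x$level, x$change_kind,
    render_hgvs(x), x$position_text,
    if (isTRUE(x$homoglyphs_normalized)) " [homoglyphs normalized]" else ""
  ))
  invisible(x)
}

invalid_notation <- function(s, index, what) {
  abort(
    sprintf("invalid %s notation '%s': unparseable at character %d", what, s, index),
    class = "exoanno_notation_error", index = index
  )
}

#' Parse HGVS variant notation (pragmatic clinical-report subset)
#'
#' These parsers accept the HGVS constructs attested in clinical exome
#' reports rather than the full standard: cDNA substitutions, deletions,
#' duplications, insertions and delins with plain, range (`n_m`) and
#' intronic-offset (`n+k`/`n-k`) positions; protein substitutions and
#' frameshifts in three-letter code; and genomic `chr<N>:<pos><ref>><alt>`
#' locations. Typographic whitespace (`G > A`, `p. Glu23Valfs`) and Cyrillic
#' homoglyph letters are normalized before matching; the canonical compact
#' rendering is what `render_hgvs()` returns and what `norm` payloads store.
#'
#' @param s notation string.
#' @return an `exoanno_hgvs` parse: `level`, `raw`, `change_kind`,
#'   `position_text`, `ref_allele`, `alt_allele`, `homoglyphs_normalized`.
#' @examples
#' parse_hgvs_cdna("c.5266dupC")
#' parse_hgvs_cdna("c.3671+1G>A")
#' parse_hgvs_protein("p. Glu23Valfs")
#' parse_genomic_loc("Chr13:32914438G > A")
#' @export
parse_hgvs_cdna <- function(s) {
  stopifnot(is_string(s))
  h <- strip_homoglyphs(s)
  compact <- gsub("\\s+", "", h$text)
  if (!startsWith(compact, "c.")) {
    invalid_notation(s, if (substr(compact, 1, 1) == "c") 2L else 1L, "cDNA")
  }
  rest <- substr(compact, 3, n_chars(compact))
  pos_re <- "^\\d+([+-]\\d+)?(_\\d+([+-]\\d+)?)?"
  m <- regexpr(pos_re, rest, perl = TRUE)
  if (m == -1) invalid_notation(s, 3L, "cDNA")
  pos <- regmatches(rest, m)
  body <- substr(rest, attr(m, "match.length") + 1L, n_chars(rest))
  at <- 3L + attr(m, "match.length")
  mb <- regmatches(
    body,
    regexec(
      "^(?:([ACGT]+)>([ACGT]+)|delins([ACGT]+)|del([ACGT]*)|dup([ACGT]*)|ins([ACGT]+))$",
      body,
      perl = TRUE
    )
  )[[1]]
  if (!length(mb)) invalid_notation(s, at, "cDNA")
  if (nzchar(mb[2]) || nzchar(mb[3])) {
    return(new_hgvs_parse("cdna", compact, "substitution", pos, mb[2], mb[3],
      homoglyphs_normalized = h$changed
    ))
  }
  if (startsWith(body, "delins")) {
    return(new_hgvs_parse("cdna", compact, "delins", pos,
      alt_allele = mb[4], homoglyphs_normalized = h$changed
    ))
  }
  if (startsWith(body, "del")) {
    return(new_hgvs_parse("cdna", compact, "deletion", pos,
      ref_allele = if (nzchar(mb[5])) mb[5] else NA_character_,
      homoglyphs_normalized = h$changed
    ))
  }
  if (startsWith(body, "dup")) {
    return(new_hgvs_parse("cdna", compact, "duplication", pos,
      alt_allele = if (nzchar(mb[6])) mb[6] else NA_character_,
      homoglyphs_normalized = h$changed
    ))
  }
  new_hgvs_parse("cdna", compact, "insertion", pos,
    alt_allele = mb[7], homoglyphs_normalized = h$changed
  )
}

#' @rdname parse_hgvs_cdna
#' @export
parse_hgvs_protein <- function(s) {
  stopifnot(is_string(s))
  h <- strip_homoglyphs(s)
  compact <- sub("^p\\.\\s+", "p.", str_trim(h$text))
  m <- regexec(
    "^p\\.([A-Z][a-z]{2})(\\d+)(?:([A-Z][a-z]{2})|(\\*|Ter))?(fs(?:\\*?\\d+|Ter\\d*)?)?$",
    compact,
    perl = TRUE
  )
  g <- regmatches(compact, m)[[1]]
  if (!length(g)) invalid_notation(s, 3L, "protein")
  ref <- g[2]
  alt3 <- g[4]
  ter <- g[5]
  fs <- g[6]
  if (!ref %in% AA3) invalid_notation(s, 3L, "protein")
  if (nzchar(alt3) && !alt3 %in% c(AA3, "Ter")) invalid_notation(s, 3L + 3L + n_chars(g[3]), "protein")
  alt <- if (nzchar(alt3)) alt3 else if (nzchar(ter)) "Ter" else NA_character_
  kind <- if (nzchar(fs)) "frameshift" else "substitution"
  if (!nzchar(fs) && is.na(alt)) invalid_notation(s, n_chars(compact) + 1L, "protein")
  new_hgvs_parse("protein", compact, kind, g[3], ref, alt,
    homoglyphs_normalized = h$changed
  )
}

#' @rdname parse_hgvs_cdna
#' @param allow_region lenient mode: accept a bare `chr<N>:<pos>` location
#'   with no ref/alt alleles (strict by default).
#' @export
parse_genomic_loc <- function(s, allow_region = FALSE) {
  stopifnot(is_string(s))
  h <- strip_homoglyphs(s)
  compact <- gsub("\\s+", "", h$text)
  m <- regexec(
    "^[Cc]hr([0-9]{1,2}|X|Y|MT):(\\d+)(?:([ACGT])>([ACGT]))?$",
    compact,
    perl = TRUE
  )
  g <- regmatches(compact, m)[[1]]
  if (!length(g)) invalid_notation(s, 1L, "genomic")
  chrom <- g[2]
  if (grepl("^[0-9]+$", chrom) && !(as.integer(chrom) %in% 1:22)) {
    invalid_notation(s, 4L, "genomic")
  }
  has_alleles <- nzchar(g[4])
  if (!has_alleles && !allow_region) {
    invalid_notation(s, n_chars(compact) + 1L, "genomic")
  }
  new_hgvs_parse(
    "genomic", paste0("chr", chrom, ":", g[3], if (has_alleles) paste0(g[4], ">", g[5])),
    if (has_alleles) "substitution" else "region",
    paste0(chrom, ":", g[3]),
    if (has_alleles) g[4] else NA_character_,
    if (has_alleles) g[5] else NA_character_,
    homoglyphs_normalized = h$changed
  )
}

#' Re-render a parse to its canonical compact notation
#'
#' `parse -> render -> parse` is a fixpoint: the rendered string re-parses
#' to the same fields.
#'
#' @param p an `exoanno_hgvs` parse.
#' @return the canonical compact notation string.
#' @export
render_hgvs <- function(p) {
  stopifnot(inherits(p, "exoanno_hgvs"))
  switch(p$level,
    cdna = paste0("c.", p$position_text, switch(p$change_kind,
      substitution = paste0(p$ref_allele, ">", p$alt_allele),
      deletion = paste0("del", if (!is.na(p$ref_allele)) p$ref_allele else ""),
      duplication = paste0("dup", if (!is.na(p$alt_allele)) p$alt_allele else ""),
      insertion = paste0("ins", p$alt_allele),
      delins = paste0("delins", p$alt_allele)
    )),
    protein = paste0(
      "p.", p$ref_allele, p$position_text,
      if (!is.na(p$alt_allele) && (p$change_kind != "frameshift" || p$alt_allele != "Ter")) p$alt_allele else "",
      if (p$change_kind == "frameshift") "fs" else ""
    ),
    genomic = paste0(
      "chr", p$position_text,
      if (p$change_kind == "substitution") paste0(p$ref_allele, ">", p$alt_allele) else ""
    )
  )
}

#' Validate and normalize knowledge-base identifiers
#'
#' OMIM identifiers accept an optional `OMIM` prefix and `#` and require
#' exactly 6 digits (the bare digits are returned); ClinVar accessions
#' require `RCV` followed by 9 digits; dbSNP identifiers require `rs`
#' followed by 1-10 digits and are returned lower-case.
#'
#' @param kind one of `"OMIM_ID"`, `"CLINVAR_ID"`, `"DBSNP_ID"`.
#' @param s identifier string.
#' @return the normalized identifier.
#' @examples
#' validate_identifier("OMIM_ID", "OMIM #618333") # "618333"
#' validate_identifier("DBSNP_ID", "RS123456")    # "rs123456"
#' @export
validate_identifier <- function(kind, s) {
  stopifnot(is_string(s))
  kind <- match.arg(kind, c("OMIM_ID", "CLINVAR_ID", "DBSNP_ID"))
  t <- str_trim(strip_homoglyphs(s)$text)
  bad <- function(pattern) {
    abort(
      sprintf("invalid %s identifier '%s': expected pattern %s", kind, s, pattern),
      class = "exoanno_identifier_error"
    )
  }
  switch(kind,
    OMIM_ID = {
      m <- regmatches(t, regexec("^(?:OMIM\\s*)?#?\\s*(\\d{6})$", t, perl = TRUE))[[1]]
      if (!length(m)) bad("[OMIM ][#]dddddd (6 digits)")
      m[2]
    },
    CLINVAR_ID = {
      if (!grepl("^RCV\\d{9}$", t)) bad("RCV + 9 digits")
      t
    },
    DBSNP_ID = {
      if (!grepl("^[Rr][Ss]\\d{1,10}$", t)) bad("rs + 1..10 digits")
      tolower(t)
    }
  )
}

# norm-payload validator dispatch by entity type; returns NULL when the
# type carries no validated payload (DISEASE, PHENOTYPE, free-text types).
validate_norm <- function(type, norm) {
  switch(type,
    GENE = {
      if (!grepl("^[A-Z][A-Z0-9-]{0,15}$", norm)) {
        abort(sprintf("'%s' is not an HGNC-style symbol", norm),
          class = "exoanno_identifier_error"
        )
      }
    },
    CDNA_PROT = {
      if (startsWith(norm, "p")) parse_hgvs_protein(norm) else parse_hgvs_cdna(norm)
    },
    VARIANT_LOC = parse_genomic_loc(norm, allow_region = TRUE),
    SIGNIFICANCE = vocab_check(norm, significance_values(), "significance code"),
    INHERITANCE_MODE = vocab_check(norm, inheritance_modes(), "inheritance mode"),
    OMIM_ID = validate_identifier("OMIM_ID", norm),
    CLINVAR_ID = validate_identifier("CLINVAR_ID", norm),
    DBSNP_ID = validate_identifier("DBSNP_ID", norm),
    NULL
  )
  invisible(TRUE)
}

violation <- function(code, message, offending_id = NA_character_) {
  tibble(code = code, message = message, offending_id = offending_id)
}

#' Validate a document against the annotation schema
#'
#' Runs every schema invariant and returns the violations as data, never as
#' exceptions: offset bounds, surface/text-slice agreement, vocabulary
#' membership, duplicate ids and duplicate `(start, end, type)` spans,
#' normalized-payload validity, dangling parents, and — only after the
#' entity layer — relation endpoints, self-loops and the domain/range
#' constraint table (entity annotation precedes relation annotation, so the
#' checks compose in that order).
#'
#' @param doc a one-row corpus tibble (see [document()]).
#' @return a tibble with columns `doc_id`, `code`, `message`,
#'   `offending_id`; zero rows iff the document is valid.
#' @export
validate_document <- function(doc) {
  stopifnot(nrow(doc) == 1)
  text <- doc$text[[1]]
  ents <- doc$entities[[1]]
  rels <- doc$relations[[1]]
  len <- n_chars(text)
  v <- list()

  # ---- entity layer -------------------------------------------------------
  dup <- unique(ents$id[duplicated(ents$id)])
  for (d in dup) v[[length(v) + 1]] <- violation("duplicate-entity-id", sprintf("entity id '%s' repeats", d), d)
  for (i in seq_len(nrow(ents))) {
    e <- ents[i, ]
    if (!e$type %in% entity_types()) {
      v[[length(v) + 1]] <- violation("unknown-entity-type", sprintf("entity '%s' has unknown type '%s'", e$id, e$type), e$id)
      next
    }
    if (is.na(e$start) || is.na(e$end) || e$start < 0 || e$start >= e$end || e$end > len) {
      v[[length(v) + 1]] <- violation(
        "offset-bounds",
        sprintf("entity '%s' offsets [%s,%s) out of bounds for text of length %d", e$id, e$start, e$end, len), e$id
      )
      next
    }
    slice <- substr(text, e$start + 1L, e$end)
    if (!identical(slice, e$surface)) {
      v[[length(v) + 1]] <- violation(
        "surface-mismatch",
        sprintf("entity '%s' surface '%s' != text slice '%s'", e$id, e$surface, slice), e$id
      )
    }
    if (!is.na(e$norm)) {
      ok <- tryCatch(
        {
          validate_norm(e$type, e$norm)
          TRUE
        },
        error = function(err) conditionMessage(err)
      )
      if (!isTRUE(ok)) {
        v[[length(v) + 1]] <- violation("norm-invalid", sprintf("entity '%s' norm payload: %s", e$id, ok), e$id)
      }
    }
    if (!is.na(e$parent_id) && !e$parent_id %in% ents$id) {
      v[[length(v) + 1]] <- violation("dangling-parent", sprintf("entity '%s' parent '%s' not in document", e$id, e$parent_id), e$id)
    }
  }
  key <- paste(ents$start, ents$end, ents$type)
  for (k in unique(key[duplicated(key)])) {
    ids <- ents$id[key == k]
    v[[length(v) + 1]] <- violation(
      "duplicate-span",
      sprintf("identical (start,end,type) span repeated: %s", paste(ids, collapse = ", ")), ids[1]
    )
  }

  # ---- relation layer (checked after entities) ----------------------------
  dup <- unique(rels$id[duplicated(rels$id)])
  for (d in dup) v[[length(v) + 1]] <- violation("duplicate-relation-id", sprintf("relation id '%s' repeats", d), d)
  for (i in seq_len(nrow(rels))) {
    r <- rels[i, ]
    if (!r$type %in% relation_types()$type) {
      v[[length(v) + 1]] <- violation("unknown-relation-type", sprintf("relation '%s' has unknown type '%s'", r$id, r$type), r$id)
      next
    }
    if (identical(r$head_id, r$tail_id)) {
      v[[length(v) + 1]] <- violation("self-relation", sprintf("relation '%s' links '%s' to itself", r$id, r$head_id), r$id)
      next
    }
    hi <- match(r$head_id, ents$id)
    ti <- match(r$tail_id, ents$id)
    if (is.na(hi) || is.na(ti)) {
      missing <- c(r$head_id, r$tail_id)[c(is.na(hi), is.na(ti))]
      v[[length(v) + 1]] <- violation(
        "dangling-endpoint",
        sprintf("relation '%s' references missing entity id(s): %s", r$id, paste(missing, collapse = ", ")), r$id
      )
      next
    }
    ok <- tryCatch(
      check_relation_constraint(r$type, ents$type[hi], ents$type[ti]),
      error = function(err) FALSE
    )
    if (!isTRUE(ok)) {
      v[[length(v) + 1]] <- violation(
        "relation-constraint",
        sprintf(
          "relation '%s' (%s) violates domain/range: %s -> %s",
          r$id, r$type, ents$type[hi], ents$type[ti]
        ), r$id
      )
    }
  }

  out <- if (length(v)) bind_rows(v) else violation(character(), character(), character())
  bind_cols(tibble(doc_id = rep(doc$doc_id[[1]], nrow(out))), out)
}

#' @rdname validate_document
#' @param x a corpus.
#' @return for `validate_corpus()`, the row-bound violation tibble over all
#'   documents.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "exoanno_corpus") || is.data.frame(x))
  if (nrow(x) == 0) {
    return(bind_cols(tibble(doc_id = character()), violation(character(), character(), character())))
  }
  bind_rows(lapply(seq_len(nrow(x)), function(i) validate_document(x[i, ])))
}
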