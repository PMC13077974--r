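#' Load structured variant-knowledge records
#'
#' Knowledge records are the structured gene-variant-disease rows that drive
#' synthetic report generation: gene symbol, cDNA/protein/genomic variant
#' notation, zygosity, ACMG/AMP significance, disease, OMIM/ClinVar/dbSNP
#' identifiers, inheritance mode, phenotype terms and recommendation-style
#' free text. The field vocabulary mirrors ClinVar column naming so that a
#' real ClinVar/OMIM export can later be substituted for the bundled
#' synthetic fixture.
#'
#' The TSV dialect is UTF-8 with a header row; the list-valued `phenotypes`
#' field is pipe-delimited. The JSONL alternative carries identical field
#' names, one record per line.
#'
#' @param path file path; default is the bundled 40-row synthetic fixture.
#' @param format `"tsv"` or `"jsonl"`.
#' @param strict if `TRUE` (default) a schema-violating row is a
#'   row-numbered error; if `FALSE` such rows are skipped with a warning.
#' @return a tibble of validated knowledge records, one per row, with
#'   `phenotypes` as a list-column.
#' @examples
#' k <- load_knowledge()
#' nrow(k) # 40
#' @export
load_knowledge <- function(path = knowledge_fixture_path(),
                           format = c("tsv", "jsonl"), strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("cannot read knowledge file '%s'", path), class = "exoanno_io_error")
  }
  raw <- if (format == "tsv") read_knowledge_tsv(path) else read_knowledge_jsonl(path)
  if (nrow(raw) == 0) {
    return(raw)
  }
  problems <- map(seq_len(nrow(raw)), function(i) check_record(raw[i, ], i))
  bad <- !map_lgl(problems, is.null)
  if (any(bad)) {
    msgs <- unlist(problems[bad])
    if (strict) {
      abort(
        paste0("invalid knowledge record(s):\n", paste(msgs, collapse = "\n")),
        class = "exoanno_record_error"
      )
    }
    warn(paste0("skipping invalid knowledge record(s):\n", paste(msgs, collapse = "\n")))
    raw <- raw[!bad, ]
  }
  raw
}

knowledge_cols <- function() {
  c(
    "gene", "hgvs_c", "hgvs_p", "genomic", "zygosity", "significance",
    "disease", "omim_id", "clinvar_rcv", "dbsnp", "inheritance",
    "phenotypes", "exon", "diagnostic_method", "recommendation",
    "retest_plan", "therapy", "disease_category"
  )
}

read_knowledge_tsv <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      exon = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  finalize_knowledge(x)
}

read_knowledge_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(str_trim(lines))]
  if (!length(lines)) {
    return(finalize_knowledge(tibble()))
  }
  rows <- imap(lines, function(l, i) {
    rec <- tryCatch(fromJSON(l, simplifyVector = TRUE), error = function(e) {
      abort(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)),
        class = "exoanno_io_error"
      )
    })
    rec$phenotypes <- paste(unlist(rec$phenotypes), collapse = "|")
    as_tibble(rec[!map_lgl(rec, is.null)])
  })
  finalize_knowledge(bind_rows(rows))
}

finalize_knowledge <- function(x) {
  for (col in setdiff(knowledge_cols(), names(x))) {
    x[[col]] <- if (col == "exon") NA_integer_ else NA_character_
  }
  x <- x[knowledge_cols()]
  x$exon <- as.integer(x$exon)
  x$phenotypes <- map(x$phenotypes, function(p) {
    if (is.na(p) || !nzchar(p)) character() else strsplit(p, "|", fixed = TRUE)[[1]]
  })
  as_tibble(x)
}

check_record <- function(r, i) {
  errs <- character()
  try_field <- function(field, fn) {
    tryCatch(
      {
        fn()
        NULL
      },
      error = function(e) sprintf("row %d, %s: %s", i, field, conditionMessage(e))
    )
  }
  add <- function(x) if (!is.null(x)) errs[[length(errs) + 1]] <<- x
  if (is.na(r$gene) || !nzchar(r$gene)) {
    add(sprintf("row %d, gene: missing", i))
  } else {
    add(try_field("gene", function() validate_norm("GENE", r$gene)))
  }
  if (is.na(r$hgvs_c) && is.na(r$genomic)) {
    add(sprintf("row %d: at least one of hgvs_c, genomic is required", i))
  }
  if (!is.na(r$hgvs_c)) add(try_field("hgvs_c", function() parse_hgvs_cdna(r$hgvs_c)))
  if (!is.na(r$hgvs_p)) add(try_field("hgvs_p", function() parse_hgvs_protein(r$hgvs_p)))
  if (!is.na(r$genomic)) add(try_field("genomic", function() parse_genomic_loc(r$genomic)))
  add(try_field("significance", function() vocab_check(r$significance, significance_values(), "significance code")))
  add(try_field("inheritance", function() vocab_check(r$inheritance, inheritance_modes(), "inheritance mode")))
  if (!is.na(r$omim_id)) add(try_field("omim_id", function() validate_identifier("OMIM_ID", r$omim_id)))
  if (!is.na(r$clinvar_rcv)) add(try_field("clinvar_rcv", function() validate_identifier("CLINVAR_ID", r$clinvar_rcv)))
  if (!is.na(r$dbsnp)) add(try_field("dbsnp", function() validate_identifier("DBSNP_ID", r$dbsnp)))
  if (length(errs)) paste(errs, collapse = "\n") else NULL
}

#' @rdname load_knowledge
#' @export
knowledge_fixture_path <- function() {
  system.file("extdata", "knowledge_records.tsv", package = "exoanno", mustWork = TRUE)
}

#' Write knowledge records back to disk
#'
#' Serialization inverse of [load_knowledge()]: writing then re-loading is
#' the identity.
#'
#' @param records knowledge tibble.
#' @param path output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @export
write_knowledge <- function(records, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  flat <- records
  flat$phenotypes <- map_chr(records$phenotypes, paste, collapse = "|")
  if (format == "tsv") {
    readr::write_tsv(flat, path, na = "", progress = FALSE)
  } else {
    lines <- map_chr(seq_len(nrow(records)), function(i) {
      rec <- as.list(records[i, ])
      rec$phenotypes <- as.list(records$phenotypes[[i]])
      rec <- rec[!map_lgl(rec, function(v) !is.list(v) && length(v) == 1 && is.na(v))]
      as.character(toJSON(rec, auto_unbox = TRUE, null = "null"))
    })
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Filter records by clinical significance
#'
#' Synthetic corpus construction keeps only records whose significance is in
#' a chosen set (typically pathogenic and likely pathogenic, mirroring
#' significance-based filtering of ClinVar exports); an optional free-text
#' `disease_category` predicate supports syndrome-level filtering of
#' OMIM-style rows.
#'
#' @param records knowledge tibble.
#' @param keep_significance non-empty character vector of significance
#'   codes to keep.
#' @param disease_category optional character vector; when given, only rows
#'   whose `disease_category` is in the set are kept.
#' @return the order-preserving subset of `records`.
#' @examples
#' k <- load_knowledge()
#' nrow(filter_records(k, c("PATHOGENIC", "LIKELY_PATHOGENIC"))) # 18
#' @export
filter_records <- function(records, keep_significance, disease_category = NULL) {
  if (length(keep_significance) == 0) {
    abort("keep_significance must be non-empty", class = "exoanno_vocab_error")
  }
  for (s in keep_significance) vocab_check(s, significance_values(), "significance code")
  out <- records[records$significance %in% keep_significance, ]
  if (!is.null(disease_category)) {
    out <- out[!is.na(out$disease_category) & out$disease_category %in% disease_category, ]
  }
  out
}
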