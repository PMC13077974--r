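# ---- Label Studio JSON ----------------------------------------------------

ls_span_item <- function(e) {
  item <- list(
    id = e$id, type = "labels", from_name = "label", to_name = "text",
    value = list(
      start = e$start, end = e$end, text = e$surface, labels = list(e$type)
    )
  )
  meta <- list()
  if (!is.na(e$norm)) meta$norm <- e$norm
  if (!is.na(e$parent_id)) meta$parent_id <- e$parent_id
  if (length(meta)) item$meta <- meta
  item
}

#' Convert between corpora and Label Studio task JSON
#'
#' One task per document: the text under `data.text` (with doc identity and
#' provenance alongside), entity spans as `labels` result items with
#' 0-based half-open offsets, and relation edges as `relation` result items
#' referencing span ids. The round-trip is lossless, including `norm`
#' payloads and `parent_id` nesting links (carried in item `meta`); foreign
#' task fields encountered on import are kept in a `.ls_extra` list-column
#' and re-emitted on export.
#'
#' @param corpus a corpus tibble.
#' @return `to_label_studio()`: a list of task objects (serialize with
#'   [write_label_studio()]); `from_label_studio()`: a corpus with a
#'   `validation` attribute holding the violation tibble from
#'   [validate_corpus()].
#' @export
to_label_studio <- function(corpus) {
  map(seq_len(nrow(corpus)), function(i) {
    ents <- corpus$entities[[i]]
    rels <- corpus$relations[[i]]
    result <- c(
      map(seq_len(nrow(ents)), function(j) ls_span_item(ents[j, ])),
      map(seq_len(nrow(rels)), function(j) {
        r <- rels[j, ]
        list(
          id = r$id, type = "relation", direction = "right",
          from_id = r$head_id, to_id = r$tail_id, labels = list(r$type)
        )
      })
    )
    task <- list(
      id = i,
      data = list(
        text = corpus$text[[i]], doc_id = corpus$doc_id[[i]],
        source = corpus$source[[i]], language = corpus$language[[i]]
      ),
      annotations = list(list(result = result))
    )
    if (".ls_extra" %in% names(corpus)) {
      task <- c(task, corpus$.ls_extra[[i]])
    }
    task
  })
}

#' @rdname to_label_studio
#' @param path JSON file path.
#' @export
write_label_studio <- function(corpus, path) {
  write_json(to_label_studio(corpus), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname to_label_studio
#' @param tasks a parsed task list or a path to a Label Studio JSON export.
#' @export
from_label_studio <- function(tasks) {
  if (is.character(tasks)) tasks <- read_json(tasks, simplifyVector = FALSE)
  known <- c("id", "data", "annotations", "predictions")
  docs <- imap(tasks, function(task, i) {
    text <- task$data$text %||% abort(sprintf("task %d has no data.text", i), class = "exoanno_io_error")
    doc_id <- task$data$doc_id %||% as.character(task$id %||% i)
    result <- (task$annotations[[1]] %||% list(result = list()))$result %||% list()
    spans <- keep(result, function(r) !identical(r$type, "relation"))
    rels <- keep(result, function(r) identical(r$type, "relation"))
    ents <- map(spans, function(s) {
      tibble(
        id = as.character(s$id),
        type = s$value$labels[[1]],
        start = as.integer(s$value$start), end = as.integer(s$value$end),
        surface = s$value$text %||% NA_character_,
        norm = s$meta$norm %||% NA_character_,
        parent_id = s$meta$parent_id %||% NA_character_
      )
    })
    ents <- if (length(ents)) bind_rows(ents) else entity_tbl()
    rel_rows <- imap(rels, function(r, j) {
      for (endpoint in c(r$from_id, r$to_id)) {
        if (!endpoint %in% ents$id) {
          abort(
            sprintf("document '%s': relation references missing span id '%s'", doc_id, endpoint),
            class = "exoanno_io_error"
          )
        }
      }
      tibble(
        id = as.character(r$id %||% paste0("r", j)),
        type = r$labels[[1]], head_id = r$from_id, tail_id = r$to_id
      )
    })
    rel_tbl <- if (length(rel_rows)) bind_rows(rel_rows) else relation_tbl()
    doc <- document(doc_id, text,
      entities = ents, relations = rel_tbl,
      source = task$data$source %||% "authentic",
      language = task$data$language %||% "ru"
    )
    extra <- task[setdiff(names(task), known)]
    doc$.ls_extra <- list(extra)
    doc
  })
  out <- as_corpus(bind_rows(docs))
  if (all(map_int(out$.ls_extra, length) == 0)) out$.ls_extra <- NULL
  attr(out, "validation") <- validate_corpus(out)
  out
}

# ---- JSONL stand-off dialect ----------------------------------------------

#' Convert between corpora and the JSONL stand-off dialect
#'
#' One UTF-8 JSON object per line with fields `doc_id`, `source`,
#' `language`, `text`, `entities[]`, `relations[]`; lossless round-trip
#' including `norm` payloads and `parent_id` links.
#'
#' @param corpus a corpus tibble.
#' @param path output path; when `NULL`, `to_jsonl()` returns the lines.
#' @return `to_jsonl()`: the lines (invisibly when written to `path`);
#'   `from_jsonl()`: a corpus.
#' @export
to_jsonl <- function(corpus, path = NULL) {
  lines <- map_chr(seq_len(nrow(corpus)), function(i) {
    as.character(toJSON(
      list(
        doc_id = corpus$doc_id[[i]], source = corpus$source[[i]],
        language = corpus$language[[i]], text = corpus$text[[i]],
        entities = corpus$entities[[i]], relations = corpus$relations[[i]]
      ),
      auto_unbox = TRUE, digits = NA, na = "null", null = "null"
    ))
  })
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' @rdname to_jsonl
#' @param x a path to a JSONL file or a character vector of lines.
#' @export
from_jsonl <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, encoding = "UTF-8", warn = FALSE) else x
  lines <- lines[nzchar(str_trim(lines))]
  if (!length(lines)) {
    return(empty_corpus())
  }
  docs <- imap(lines, function(l, i) {
    obj <- tryCatch(fromJSON(l, simplifyVector = TRUE), error = function(e) {
      abort(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)),
        class = "exoanno_io_error"
      )
    })
    for (field in c("doc_id", "text")) {
      if (is.null(obj[[field]])) {
        abort(sprintf("line %d: missing field '%s'", i, field), class = "exoanno_io_error")
      }
    }
    ents <- if (is.data.frame(obj$entities) && nrow(obj$entities)) {
      e <- as_tibble(obj$entities)
      entity_tbl(e$id, e$type, e$start, e$end, e$surface,
        norm = e$norm %||% NA_character_,
        parent_id = e$parent_id %||% NA_character_
      )
    } else {
      entity_tbl()
    }
    rels <- if (is.data.frame(obj$relations) && nrow(obj$relations)) {
      r <- as_tibble(obj$relations)
      relation_tbl(r$id, r$type, r$head_id, r$tail_id)
    } else {
      relation_tbl()
    }
    document(obj$doc_id, obj$text,
      entities = ents, relations = rels,
      source = obj$source %||% "authentic", language = obj$language %||% "ru"
    )
  })
  ids <- map_chr(docs, function(d) d$doc_id[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    lines_at <- which(ids %in% dup)
    abort(
      sprintf(
        "duplicated doc_id '%s' (lines %s)",
        paste(dup, collapse = ", "), paste(lines_at, collapse = ", ")
      ),
      class = "exoanno_io_error"
    )
  }
  as_corpus(bind_rows(docs))
}

# ---- BIO / CoNLL ----------------------------------------------------------

# outermost spans of each position: drop any span strictly contained in
# another, then resolve residual overlaps greedily by (start, longer first)
flatten_spans <- function(ents) {
  if (nrow(ents) <= 1) {
    return(list(outer = ents, inner = ents[0, ]))
  }
  contained <- map_lgl(seq_len(nrow(ents)), function(i) {
    any(
      ents$start <= ents$start[i] & ents$end[i] <= ents$end &
        (ents$end - ents$start) > (ents$end[i] - ents$start[i])
    )
  })
  outer <- ents[!contained, ]
  outer <- outer[order(outer$start, -(outer$end - outer$start)), ]
  keep_row <- rep(TRUE, nrow(outer))
  last_end <- -1L
  for (i in seq_len(nrow(outer))) {
    if (outer$start[i] < last_end) {
      keep_row[i] <- FALSE
    } else {
      last_end <- outer$end[i]
    }
  }
  list(outer = outer[keep_row, ], inner = ents[contained, ])
}

sentence_ranges <- function(text) {
  m <- gregexpr("[.!?…]+(\\s+|$)", text, perl = TRUE)[[1]]
  len <- n_chars(text)
  if (m[1] == -1) {
    return(tibble(start = 0L, end = len))
  }
  ends <- as.integer(m) - 1L + attr(m, "match.length")
  starts <- c(0L, head(ends, -1))
  out <- tibble(start = starts, end = ends)
  if (max(ends) < len) out <- bind_rows(out, tibble(start = max(ends), end = len))
  out
}

tag_tokens <- function(toks, spans) {
  tags <- rep("O", nrow(toks))
  if (nrow(spans) == 0 || nrow(toks) == 0) {
    return(tags)
  }
  spans <- spans[order(spans$start), ]
  for (i in seq_len(nrow(spans))) {
    hit <- which(toks$start < spans$end[i] & toks$end > spans$start[i])
    if (!length(hit)) next
    if (toks$start[hit[1]] != spans$start[i] || toks$end[hit[length(hit)]] != spans$end[i]) {
      warn(
        sprintf(
          "span [%d,%d) %s is not token-aligned; expanded to covering tokens",
          spans$start[i], spans$end[i], spans$type[i]
        ),
        class = "exoanno_bio_expand"
      )
    }
    tags[hit[1]] <- paste0("B-", spans$type[i])
    if (length(hit) > 1) tags[hit[-1]] <- paste0("I-", spans$type[i])
  }
  tags
}

#' BIO/CoNLL token tagging of a document
#'
#' Tokens are grouped into sentences (terminal-punctuation heuristic) and
#' tagged `B-`/`I-`/`O`. Nested annotations are flattened: only the
#' outermost span at each position is emitted; with `nested = TRUE` a
#' second layer carrying the contained spans is returned as well. Spans not
#' aligned to token boundaries are expanded to the smallest covering token
#' run with a warning.
#'
#' @param doc a one-row corpus tibble.
#' @param tokenizer tokenizer function.
#' @param nested emit the inner layer too.
#' @return a tibble with columns `sentence`, `token`, `tag`, `start`,
#'   `end`; with `nested = TRUE`, a list of such tibbles (`outer`,
#'   `inner`).
#' @export
to_bio <- function(doc, tokenizer = default_tokenizer, nested = FALSE) {
  stopifnot(nrow(doc) == 1)
  text <- doc$text[[1]]
  layers <- flatten_spans(doc$entities[[1]])
  sent <- sentence_ranges(text)
  layer_tbl <- function(spans) {
    rows <- map(seq_len(nrow(sent)), function(si) {
      seg <- substr(text, sent$start[si] + 1L, sent$end[si])
      toks <- tokenizer(seg)
      if (nrow(toks) == 0) {
        return(NULL)
      }
      toks$start <- toks$start + sent$start[si]
      toks$end <- toks$end + sent$start[si]
      tibble(
        sentence = si, token = toks$token,
        tag = tag_tokens(toks, spans), start = toks$start, end = toks$end
      )
    })
    bind_rows(rows)
  }
  if (nested) {
    list(outer = layer_tbl(layers$outer), inner = layer_tbl(layers$inner))
  } else {
    layer_tbl(layers$outer)
  }
}

#' @rdname to_bio
#' @param bio a BIO tibble from `to_bio()`.
#' @param path output path; token TAB tag lines, blank line between
#'   sentences.
#' @export
write_bio <- function(bio, path) {
  lines <- unlist(map(split(bio, bio$sentence), function(s) {
    c(paste(s$token, s$tag, sep = "\t"), "")
  }), use.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname to_bio
#' @return `bio_to_spans()`: the spans implied by the tags (equal to the
#'   flattened gold spans whenever those were token-aligned).
#' @export
bio_to_spans <- function(bio) {
  spans <- list()
  open <- NULL
  flush_span <- function() {
    if (!is.null(open)) spans[[length(spans) + 1]] <<- open
    open <<- NULL
  }
  for (i in seq_len(nrow(bio))) {
    tag <- bio$tag[i]
    if (tag == "O") {
      flush_span()
    } else if (startsWith(tag, "B-")) {
      flush_span()
      open <- tibble(type = substr(tag, 3, n_chars(tag)), start = bio$start[i], end = bio$end[i])
    } else {
      ty <- substr(tag, 3, n_chars(tag))
      if (is.null(open) || open$type != ty) {
        flush_span()
        open <- tibble(type = ty, start = bio$start[i], end = bio$end[i])
      } else {
        open$end <- bio$end[i]
      }
    }
  }
  flush_span()
  if (!length(spans)) {
    return(tibble(type = character(), start = integer(), end = integer()))
  }
  bind_rows(spans)
}
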