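#' F1 from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`, 0 when both are 0. Vectorized.
#'
#' @param precision,recall fractions in `[0,1]`.
#' @return F1 at full precision; round with [round_half_away()] for display.
#' @examples
#' round_half_away(f1_from_pr(0.84, 0.80), 2) # 0.82
#' @export
f1_from_pr <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE)) {
    abort("precision and recall must be in [0,1]", class = "exoanno_metric_error")
  }
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Unweighted macro average
#'
#' @param values non-empty numeric vector of fractions.
#' @return the arithmetic mean at full precision (3 decimals half-away-from-
#'   zero is the conventional display).
#' @examples
#' round_half_away(macro_average(c(0.91, 0.88, 0.85, 0.82, 0.79, 0.84, 0.76)), 3) # 0.836
#' @export
macro_average <- function(values) {
  if (length(values) == 0) {
    abort("values must be non-empty", class = "exoanno_metric_error")
  }
  mean(values)
}

#' Overall macro-F1 across the two extraction tasks
#'
#' The arithmetic mean of the NER macro-F1 and the RE macro-F1.
#'
#' @param ner_macro_f1,re_macro_f1 fractions in `[0,1]`.
#' @return the mean at full precision.
#' @examples
#' round_half_away(overall_macro(0.88, 0.836), 3) # 0.858
#' @export
overall_macro <- function(ner_macro_f1, re_macro_f1) {
  if (any(c(ner_macro_f1, re_macro_f1) < 0 | c(ner_macro_f1, re_macro_f1) > 1)) {
    abort("macro F1 values must be in [0,1]", class = "exoanno_metric_error")
  }
  (ner_macro_f1 + re_macro_f1) / 2
}

align_corpora <- function(gold, pred) {
  if (!setequal(gold$doc_id, pred$doc_id)) {
    diff <- c(setdiff(gold$doc_id, pred$doc_id), setdiff(pred$doc_id, gold$doc_id))
    abort(
      paste("gold and prediction cover different documents:", paste(diff, collapse = ", ")),
      class = "exoanno_alignment_error"
    )
  }
  pred <- pred[match(gold$doc_id, pred$doc_id), ]
  if (!identical(gold$text, pred$text)) {
    abort("gold and prediction disagree on document texts", class = "exoanno_alignment_error")
  }
  list(gold = gold, pred = pred)
}

# exact-match one-to-one counting: items are compared by a full key, so the
# strict greedy matching reduces to min(multiplicity) per distinct key
count_by_type <- function(keys_gold, types_gold, keys_pred, types_pred) {
  types <- sort(unique(c(types_gold, types_pred)))
  rows <- map(types, function(ty) {
    kg <- keys_gold[types_gold == ty]
    kp <- keys_pred[types_pred == ty]
    tg <- table(kg)
    tp_tab <- table(kp)
    shared <- intersect(names(tg), names(tp_tab))
    tp <- if (length(shared)) sum(pmin(tg[shared], tp_tab[shared])) else 0L
    tibble(
      type = ty, tp = as.integer(tp),
      fp = length(kp) - as.integer(tp), fn = length(kg) - as.integer(tp),
      support = length(kg)
    )
  })
  bind_rows(rows)
}

score_from_counts <- function(counts, task, strict) {
  per_type <- mutate(counts,
    precision = ifelse(.data$tp + .data$fp == 0, 1, .data$tp / (.data$tp + .data$fp)),
    recall = ifelse(.data$tp + .data$fn == 0, 1, .data$tp / (.data$tp + .data$fn)),
    f1 = f1_from_pr(.data$precision, .data$recall)
  )
  tp <- sum(per_type$tp)
  fp <- sum(per_type$fp)
  fn <- sum(per_type$fn)
  micro_p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  micro_r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  macro_types <- if (strict) per_type else per_type[per_type$support > 0, ]
  structure(
    list(
      task = task,
      per_type = per_type[c("type", "precision", "recall", "f1", "support", "tp", "fp", "fn")],
      micro = tibble(
        precision = micro_p, recall = micro_r,
        f1 = f1_from_pr(micro_p, micro_r)
      ),
      macro_f1 = if (nrow(macro_types)) macro_average(macro_types$f1) else NA_real_
    ),
    class = "exoanno_scores"
  )
}

#' Exact-match NER scoring
#'
#' A predicted span is a true positive iff an unmatched gold span with
#' exactly equal `(start, end, type)` exists in the same document
#' (one-to-one matching; with a full-equality key the strictest greedy
#' matching is multiplicity-respecting counting). Reports per-type and
#' micro precision/recall/F1 and the macro-F1; by default types with zero
#' gold support are excluded from the macro (set `strict_types = TRUE` to
#' average over every type with gold or predicted spans, counting absent
#' ones as their computed F1).
#'
#' @param gold,pred corpora over identical texts and doc_ids.
#' @param strict_types include zero-gold-support types in the macro.
#' @return an `exoanno_scores` object; see [tidy()] and [glance()].
#' @export
score_ner <- function(gold, pred, strict_types = FALSE) {
  al <- align_corpora(gold, pred)
  g <- span_table(al$gold)
  p <- span_table(al$pred)
  counts <- count_by_type(
    paste(g$doc_id, g$start, g$end, g$type), g$type,
    paste(p$doc_id, p$start, p$end, p$type), p$type
  )
  score_from_counts(counts, "ner", strict_types)
}

span_table <- function(corpus) {
  rows <- map(seq_len(nrow(corpus)), function(i) {
    e <- corpus$entities[[i]]
    if (nrow(e) == 0) {
      return(NULL)
    }
    tibble(doc_id = corpus$doc_id[[i]], start = e$start, end = e$end, type = e$type)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(doc_id = character(), start = integer(), end = integer(), type = character()) else out
}

relation_table <- function(corpus) {
  rows <- map(seq_len(nrow(corpus)), function(i) {
    r <- corpus$relations[[i]]
    if (nrow(r) == 0) {
      return(NULL)
    }
    e <- corpus$entities[[i]]
    hi <- match(r$head_id, e$id)
    ti <- match(r$tail_id, e$id)
    tibble(
      doc_id = corpus$doc_id[[i]], type = r$type,
      key = paste(
        corpus$doc_id[[i]], r$type,
        e$start[hi], e$end[hi], e$type[hi],
        e$start[ti], e$end[ti], e$type[ti]
      )
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(doc_id = character(), type = character(), key = character()) else out
}

#' Exact-match relation scoring
#'
#' A predicted relation is correct iff its type matches and both argument
#' spans equal a gold relation's arguments by exact `(start, end, type)`.
#' Per-relation-type F1 plus the macro over the canonical types present in
#' gold.
#'
#' @inheritParams score_ner
#' @return an `exoanno_scores` object.
#' @export
score_re <- function(gold, pred, strict_types = FALSE) {
  al <- align_corpora(gold, pred)
  g <- relation_table(al$gold)
  p <- relation_table(al$pred)
  counts <- count_by_type(g$key, g$type, p$key, p$type)
  score_from_counts(counts, "re", strict_types)
}

#' @export
print.exoanno_scores <- function(x, ...) {
  cat(sprintf(
    "<%s scores: micro F1 %.3f, macro F1 %.3f over %d type(s)>\n",
    toupper(x$task), x$micro$f1, x$macro_f1, nrow(x$per_type)
  ))
  print(x$per_type)
  invisible(x)
}

#' @rdname score_ner
#' @param x an `exoanno_scores` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.exoanno_scores <- function(x, ...) {
  x$per_type
}

#' @rdname score_ner
#' @exportS3Method generics::glance
glance.exoanno_scores <- function(x, ...) {
  tibble(
    task = x$task, micro_precision = x$micro$precision,
    micro_recall = x$micro$recall, micro_f1 = x$micro$f1,
    macro_f1 = x$macro_f1, n_types = nrow(x$per_type)
  )
}

#' Write a score report as JSON and a results-table TSV
#'
#' @param x an `exoanno_scores` object.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @param digits decimals for the TSV (half-away-from-zero).
#' @export
write_score_report <- function(x, json_path = NULL, tsv_path = NULL, digits = 3) {
  if (!is.null(json_path)) {
    write_json(
      list(
        task = x$task, per_type = x$per_type, micro = x$micro,
        macro_f1 = x$macro_f1
      ),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(tsv_path)) {
    tb <- mutate(x$per_type, across(c("precision", "recall", "f1"), function(v) round_half_away(v, digits)))
    macro <- tibble(
      type = "MACRO_AVERAGE", precision = NA_real_, recall = NA_real_,
      f1 = round_half_away(x$macro_f1, digits), support = NA_integer_,
      tp = NA_integer_, fp = NA_integer_, fn = NA_integer_
    )
    readr::write_tsv(bind_rows(tb, macro), tsv_path, na = "", progress = FALSE)
  }
  invisible(x)
}
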