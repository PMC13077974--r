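#' Deterministic Unicode-aware tokenizer
#'
#' Maximal runs of letters/digits plus standalone punctuation marks, with
#' character offsets preserved (0-based, half-open). This is the unit of
#' agreement for token-level kappa and the token stream for BIO export; any
#' function taking a `tokenizer` argument accepts a drop-in replacement
#' with the same signature.
#'
#' @param text a string.
#' @return a tibble with columns `token`, `start`, `end`.
#' @examples
#' default_tokenizer("Mutation c.5266dupC in BRCA1")
#' @export
default_tokenizer <- function(text) {
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble(
    token = regmatches(text, list(m))[[1]],
    start = starts, end = starts + lens
  )
}

#' @rdname default_tokenizer
#' @details `whitespace_tokenizer()` splits on maximal non-whitespace runs
#'   only, keeping variant notations like `c.5266dupC` as single tokens.
#' @export
whitespace_tokenizer <- function(text) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble(
    token = regmatches(text, list(m))[[1]],
    start = starts, end = starts + lens
  )
}

#' Bundle one annotator's entity annotations over a shared text collection
#'
#' @param annotator_id annotator label.
#' @param documents a tibble with columns `doc_id`, `text`, `entities`
#'   (list-column of [entity_tbl()]); a corpus works as-is.
#' @return an annotation set (class `exoanno_annset`).
#' @export
annotation_set <- function(annotator_id, documents) {
  stopifnot(all(c("doc_id", "text", "entities") %in% names(documents)))
  structure(
    list(
      annotator_id = annotator_id,
      documents = as_tibble(documents[c("doc_id", "text", "entities")])
    ),
    class = "exoanno_annset"
  )
}

align_sets <- function(a, b) {
  stopifnot(inherits(a, "exoanno_annset"), inherits(b, "exoanno_annset"))
  ida <- a$documents$doc_id
  idb <- b$documents$doc_id
  if (!setequal(ida, idb)) {
    diff <- c(setdiff(ida, idb), setdiff(idb, ida))
    abort(
      paste("annotation sets cover different documents:", paste(diff, collapse = ", ")),
      class = "exoanno_alignment_error"
    )
  }
  bd <- b$documents[match(ida, idb), ]
  if (!identical(a$documents$text, bd$text)) {
    abort("annotation sets disagree on document texts", class = "exoanno_alignment_error")
  }
  list(a = a$documents, b = bd)
}

count_matches <- function(ea, eb) {
  if (nrow(ea) == 0 || nrow(eb) == 0) {
    return(0L)
  }
  ka <- table(paste(ea$start, ea$end, ea$type))
  kb <- table(paste(eb$start, eb$end, eb$type))
  shared <- intersect(names(ka), names(kb))
  sum(pmin(ka[shared], kb[shared]))
}

#' Exact span-level agreement between two annotators
#'
#' `a` is the reference. A span matches iff `(start, end, type)` are all
#' equal (one-to-one); precision is matches over `|b|`, recall matches over
#' `|a|`, F1 their harmonic mean. An empty reference (or empty `b`) makes
#' the corresponding 0/0 ratio 1 by convention; F1 of (0, r) is 0.
#'
#' @param a,b annotation sets over the same texts.
#' @return a one-row tibble with `precision`, `recall`, `f1`, `matches`,
#'   `n_a`, `n_b`.
#' @export
span_agreement <- function(a, b) {
  al <- align_sets(a, b)
  matches <- sum(map2(al$a$entities, al$b$entities, count_matches) |> unlist())
  n_a <- sum(map_int(al$a$entities, nrow))
  n_b <- sum(map_int(al$b$entities, nrow))
  precision <- if (n_b == 0) 1 else matches / n_b
  recall <- if (n_a == 0) 1 else matches / n_a
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(
    precision = precision, recall = recall, f1 = f1,
    matches = as.integer(matches), n_a = n_a, n_b = n_b
  )
}

token_labels <- function(doc_text, entities, tokenizer, category) {
  toks <- tokenizer(doc_text)
  if (nrow(toks) == 0) {
    return(logical())
  }
  spans <- entities[entities$type == category, , drop = FALSE]
  if (nrow(spans) == 0) {
    return(rep(FALSE, nrow(toks)))
  }
  map_lgl(seq_len(nrow(toks)), function(i) {
    any(toks$start[i] < spans$end & toks$end[i] > spans$start)
  })
}

#' Token-level Cohen's kappa for one entity category
#'
#' Each token is labeled category-vs-OTHER per annotator (a token carries
#' the category iff any span of that category covers it); kappa is computed
#' from the 2x2 confusion matrix pooled over all documents as
#' `(p_o - p_e) / (1 - p_e)` with `p_e` the product-marginal chance
#' agreement. When both marginals are degenerate and identical (chance
#' agreement is 1), kappa is 1 by convention.
#'
#' @param a,b annotation sets over the same texts.
#' @param category entity type.
#' @param tokenizer tokenizer function, defaults to [default_tokenizer()].
#' @return kappa in `[-1, 1]`.
#' @export
token_kappa <- function(a, b, category, tokenizer = default_tokenizer) {
  vocab_check(category, entity_types(), "entity type")
  al <- align_sets(a, b)
  la <- unlist(map2(al$a$text, al$a$entities, token_labels, tokenizer = tokenizer, category = category))
  lb <- unlist(map2(al$b$text, al$b$entities, token_labels, tokenizer = tokenizer, category = category))
  n <- length(la)
  if (n == 0) {
    abort("kappa undefined: zero tokens", class = "exoanno_kappa_error")
  }
  p_o <- mean(la == lb)
  pa <- mean(la)
  pb <- mean(lb)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e >= 1) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Macro-average kappa with spread
#'
#' Unweighted arithmetic mean over categories with the *population*
#' standard deviation as the spread term (the category set is the full
#' population, not a sample). Values are kept at full precision; use
#' [round_half_away()] at reporting time (2 decimals is the conventional
#' display).
#'
#' @param kappas numeric vector (optionally named by category).
#' @return a list with `mean` and `std`.
#' @examples
#' macro_kappa(c(0.85, 0.81, 0.82, 0.77, 0.74, 0.76, 0.75, 0.79, 0.73))
#' @export
macro_kappa <- function(kappas) {
  if (length(kappas) == 0) {
    abort("kappas must be non-empty", class = "exoanno_kappa_error")
  }
  m <- mean(kappas)
  list(mean = m, std = sqrt(mean((kappas - m)^2)))
}

#' Percentage distribution of annotated tokens by category
#'
#' Percent of annotated tokens per category out of all tokens covered by
#' any span; tokens under nested spans count once per category, so the
#' percentages sum to at most 100 (more only when categories overlap).
#'
#' @param a an annotation set.
#' @param tokenizer tokenizer function.
#' @return a tibble with columns `category`, `percent` (categories with
#'   spans only).
#' @export
category_distribution <- function(a, tokenizer = default_tokenizer) {
  stopifnot(inherits(a, "exoanno_annset"))
  covered_total <- 0L
  by_cat <- stats::setNames(numeric(length(entity_types())), entity_types())
  for (i in seq_len(nrow(a$documents))) {
    text <- a$documents$text[[i]]
    ents <- a$documents$entities[[i]]
    toks <- tokenizer(text)
    if (nrow(toks) == 0 || nrow(ents) == 0) next
    any_cov <- rep(FALSE, nrow(toks))
    for (cat in unique(ents$type)) {
      lab <- token_labels(text, ents, tokenizer, cat)
      by_cat[[cat]] <- by_cat[[cat]] + sum(lab)
      any_cov <- any_cov | lab
    }
    covered_total <- covered_total + sum(any_cov)
  }
  present <- by_cat[by_cat > 0]
  if (!length(present) || covered_total == 0) {
    return(tibble(category = character(), percent = numeric()))
  }
  tibble(category = names(present), percent = 100 * unname(present) / covered_total)
}

#' Full inter-annotator agreement report
#'
#' Combines exact span-level precision/recall/F1, per-category token-level
#' Cohen's kappa, the macro kappa with its population spread, and each
#' annotator's percentage distribution of annotated tokens.
#'
#' @param a,b annotation sets over the same texts.
#' @param categories entity types to compute kappa for; defaults to the
#'   types annotated by either annotator.
#' @param tokenizer tokenizer function.
#' @return an `exoanno_agreement` object; see [tidy()] and [glance()]
#'   methods.
#' @export
iaa_report <- function(a, b, categories = NULL, tokenizer = default_tokenizer) {
  al <- align_sets(a, b)
  if (is.null(categories)) {
    categories <- intersect(
      entity_types(),
      unique(c(
        unlist(map(al$a$entities, function(e) e$type)),
        unlist(map(al$b$entities, function(e) e$type))
      ))
    )
  }
  kap <- map_dbl(categories, function(cat) token_kappa(a, b, cat, tokenizer))
  mk <- macro_kappa(kap)
  structure(
    list(
      annotators = c(a$annotator_id, b$annotator_id),
      span = span_agreement(a, b),
      kappa_by_category = tibble(category = categories, kappa = kap),
      macro_kappa = mk$mean, macro_kappa_std = mk$std,
      distribution = bind_rows(
        mutate(category_distribution(a, tokenizer), annotator = a$annotator_id),
        mutate(category_distribution(b, tokenizer), annotator = b$annotator_id)
      )
    ),
    class = "exoanno_agreement"
  )
}

#' @export
print.exoanno_agreement <- function(x, ...) {
  cat(sprintf(
    "<inter-annotator agreement %s vs %s>\n  span F1 %.2f (P %.2f, R %.2f)\n  macro kappa %.2f +/- %.2f over %d categories\n",
    x$annotators[1], x$annotators[2], x$span$f1, x$span$precision,
    x$span$recall, round_half_away(x$macro_kappa, 2),
    round_half_away(x$macro_kappa_std, 2), nrow(x$kappa_by_category)
  ))
  invisible(x)
}

#' @rdname iaa_report
#' @param x an `exoanno_agreement` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.exoanno_agreement <- function(x, ...) {
  pa <- x$distribution[x$distribution$annotator == x$annotators[1], c("category", "percent")]
  pb <- x$distribution[x$distribution$annotator == x$annotators[2], c("category", "percent")]
  out <- x$kappa_by_category
  out$pct_a <- pa$percent[match(out$category, pa$category)]
  out$pct_b <- pb$percent[match(out$category, pb$category)]
  out[c("category", "pct_a", "pct_b", "kappa")]
}

#' @rdname iaa_report
#' @exportS3Method generics::glance
glance.exoanno_agreement <- function(x, ...) {
  tibble(
    span_precision = x$span$precision, span_recall = x$span$recall,
    span_f1 = x$span$f1, macro_kappa = x$macro_kappa,
    macro_kappa_std = x$macro_kappa_std,
    n_categories = nrow(x$kappa_by_category)
  )
}

#' Write an agreement report to JSON and category-table TSV
#'
#' The TSV mirrors the conventional category table: one row per category
#' (annotator percentages and kappa) plus a final macro-average row.
#'
#' @param x an `exoanno_agreement` object.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @param digits decimals for the TSV (half-away-from-zero).
#' @export
write_agreement_report <- function(x, json_path = NULL, tsv_path = NULL, digits = 2) {
  if (!is.null(json_path)) {
    write_json(
      list(
        annotators = x$annotators,
        span = as.list(x$span),
        kappa_by_category = x$kappa_by_category,
        macro_kappa = x$macro_kappa, macro_kappa_std = x$macro_kappa_std,
        distribution = x$distribution
      ),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(tsv_path)) {
    tb <- tidy(x)
    tb <- mutate(tb, across(c("pct_a", "pct_b", "kappa"), function(v) round_half_away(v, digits)))
    macro <- tibble(
      category = "MACRO_AVERAGE", pct_a = NA_real_, pct_b = NA_real_,
      kappa = round_half_away(x$macro_kappa, digits)
    )
    readr::write_tsv(bind_rows(tb, macro), tsv_path, na = "", progress = FALSE)
  }
  invisible(x)
}
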