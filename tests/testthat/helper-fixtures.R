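# Builders and independent oracles shared across the suite. Oracles here are
# deliberately literal (loops, explicit confusion-matrix counting) and never
# call the implementation paths they check.

# one-sentence English document with a variant span and a gene span
brca_doc <- function(doc_id = "d1") {
  text <- "Mutation c.5266dupC in BRCA1"
  document(doc_id, text,
    entities = entity_tbl(
      id = c("e1", "e2"), type = c("CDNA_PROT", "GENE"),
      start = c(9L, 23L), end = c(19L, 28L),
      surface = c("c.5266dupC", "BRCA1"),
      norm = c("c.5266dupC", "BRCA1"),
      parent_id = c("e2", NA)
    ),
    relations = relation_tbl("r1", "VARIANT_IN_GENE", "e1", "e2"),
    source = "synthetic", language = "en"
  )
}

# annotation set over a synthetic token grid: text is n space-separated
# 2-letter tokens ("aa ab ac ..."); spans supplied as (start_token,
# end_token, type) in token indices (1-based, inclusive)
grid_text <- function(n_tokens) {
  paste(sprintf("w%02d", seq_len(n_tokens)), collapse = " ")
}

grid_span <- function(from, to, type, id) {
  # token i occupies characters [(i-1)*4, (i-1)*4 + 3)
  entity_tbl(
    id = id, type = type,
    start = (from - 1L) * 4L, end = (to - 1L) * 4L + 3L,
    surface = paste(sprintf("w%02d", from:to), collapse = " ")
  )
}

grid_set <- function(annotator, spans_by_doc, n_tokens = 10L) {
  docs <- tibble(
    doc_id = names(spans_by_doc),
    text = grid_text(n_tokens),
    entities = unname(spans_by_doc)
  )
  annotation_set(annotator, docs)
}

# literal Cohen's kappa oracle: explicit pooled 2x2 confusion matrix
oracle_kappa <- function(labels_a, labels_b) {
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_along(labels_a)) {
    if (labels_a[i] && labels_b[i]) {
      n11 <- n11 + 1
    } else if (labels_a[i] && !labels_b[i]) {
      n10 <- n10 + 1
    } else if (!labels_a[i] && labels_b[i]) {
      n01 <- n01 + 1
    } else {
      n00 <- n00 + 1
    }
  }
  n <- n11 + n10 + n01 + n00
  p_o <- (n11 + n00) / n
  pa <- (n11 + n10) / n
  pb <- (n11 + n01) / n
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e >= 1) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

# random single-document annotation pair over <= max_tokens tokens, labeled
# with one category; returns sets plus the literal token labelings
random_kappa_case <- function(max_tokens = 20L) {
  n <- sample(2:max_tokens, 1)
  la <- runif(n) < runif(1)
  lb <- runif(n) < runif(1)
  mk <- function(lab, who) {
    runs <- rle(lab)
    stops <- cumsum(runs$lengths)
    starts_tok <- c(1L, head(stops, -1) + 1L)
    spans <- list()
    for (j in seq_along(runs$values)) {
      if (runs$values[j]) {
        spans[[length(spans) + 1]] <- grid_span(
          starts_tok[j], stops[j], "GENE", paste0(who, j)
        )
      }
    }
    ents <- if (length(spans)) dplyr::bind_rows(spans) else entity_tbl()
    grid_set(who, stats::setNames(list(ents), "d1"), n_tokens = n)
  }
  list(a = mk(la, "A"), b = mk(lb, "B"), la = la, lb = lb)
}

tiny_knowledge <- function() {
  load_knowledge()[1:5, ]
}

strip_corpus_attrs <- function(x) {
  attr(x, "validation") <- NULL
  as.data.frame(x)
}

map_lgl_id <- function(templates, id) {
  vapply(templates, function(t) identical(t$id, id), logical(1))
}

map_int2 <- function(lst) vapply(lst, nrow, integer(1))

# the 318 + 5,000 hybrid build is used by several end-to-end checks; build once
.fixture_cache <- new.env(parent = emptyenv())
hybrid_corpus <- function() {
  if (is.null(.fixture_cache$hybrid)) {
    k <- load_knowledge()
    synthetic <- generate_corpus(k, profile = generation_profile(5000, seed = 101))
    authentic <- generate_corpus(
      k,
      profile = generation_profile(318, seed = 202, coverage_mode = "minimal")
    )
    authentic$source <- "authentic"
    authentic$doc_id <- sub("^doc-", "auth-", authentic$doc_id)
    .fixture_cache$hybrid <- as_corpus(dplyr::bind_rows(authentic, synthetic))
  }
  .fixture_cache$hybrid
}
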