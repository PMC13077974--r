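#' Deterministic 70/15/15 split arithmetic
#'
#' Both held-out parts get `round(ratio * n)` documents with halves rounded
#' away from zero, and training gets the remainder. This is the unique
#' simple rule consistent with partitioning both a 318-document set into
#' 222/48/48 (47.7 rounds to 48) and a 5,000-document set into
#' 3,500/750/750.
#'
#' @param n number of documents.
#' @param ratios train/dev/test proportions summing to 1.
#' @return named integer vector `(train, dev, test)`.
#' @examples
#' split_counts(5000) # 3500 750 750
#' split_counts(318) # 222 48 48
#' @export
split_counts <- function(n, ratios = c(0.70, 0.15, 0.15)) {
  stopifnot(n >= 0, length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  dev <- as.integer(round_half_away(ratios[2] * n))
  test <- as.integer(round_half_away(ratios[3] * n))
  train <- as.integer(n) - dev - test
  if (train < 0) {
    abort(sprintf("split of n = %d leaves a negative training set", n),
      class = "exoanno_split_error"
    )
  }
  c(train = train, dev = dev, test = test)
}

#' Stratified document-level train/dev/test split
#'
#' Documents are grouped by `source` (authentic vs synthetic) so templated
#' synthetic reports cannot leak between partitions; each group is shuffled
#' with a seed derived from the global seed plus a stable hash of the
#' source name (adding a new source never reshuffles existing ones),
#' partitioned by [split_counts()], and pooled. Assignment is always at the
#' document level, never the sentence level.
#'
#' @param corpus a corpus tibble.
#' @param ratios train/dev/test proportions.
#' @param seed integer seed.
#' @return an `exoanno_split`: lists `train`/`dev`/`test` of doc_ids,
#'   `per_source_counts`, and a `manifest` tibble (doc_id, source,
#'   partition).
#' @examples
#' k <- load_knowledge()
#' corp <- generate_corpus(k, profile = generation_profile(20, seed = 1))
#' sp <- stratified_split(corp, seed = 1)
#' lengths(sp[c("train", "dev", "test")])
#' @export
stratified_split <- function(corpus, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  parts <- list(train = character(), dev = character(), test = character())
  counts <- list()
  manifest <- list()
  for (src in unique(corpus$source)) {
    ids <- corpus$doc_id[corpus$source == src]
    k <- split_counts(length(ids), ratios)
    shuffled <- with_seed(derive_seed(seed, src), sample(ids))
    grp <- list(
      train = shuffled[seq_len(k[["train"]])],
      dev = shuffled[k[["train"]] + seq_len(k[["dev"]])],
      test = shuffled[k[["train"]] + k[["dev"]] + seq_len(k[["test"]])]
    )
    parts <- map2(parts, grp, c)
    counts[[length(counts) + 1]] <- tibble(
      source = src, n_train = k[["train"]], n_dev = k[["dev"]], n_test = k[["test"]]
    )
    manifest[[length(manifest) + 1]] <- tibble(
      doc_id = unlist(grp, use.names = FALSE), source = src,
      partition = rep(c("train", "dev", "test"), times = lengths(grp))
    )
  }
  structure(
    list(
      train = parts$train, dev = parts$dev, test = parts$test,
      per_source_counts = bind_rows(counts),
      manifest = if (length(manifest)) bind_rows(manifest) else tibble(doc_id = character(), source = character(), partition = character())
    ),
    class = "exoanno_split"
  )
}

#' @export
print.exoanno_split <- function(x, ...) {
  cat(sprintf(
    "<stratified split: %d train / %d dev / %d test>\n",
    length(x$train), length(x$dev), length(x$test)
  ))
  print(x$per_source_counts)
  invisible(x)
}

#' @rdname stratified_split
#' @param x an `exoanno_split`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.exoanno_split <- function(x, ...) {
  x$manifest
}

#' @rdname stratified_split
#' @param path TSV output path for the split manifest.
#' @export
write_split_manifest <- function(x, path) {
  readr::write_tsv(x$manifest, path, progress = FALSE)
  invisible(x)
}

estimate_sentences <- function(text) {
  n <- str_count(text, "[.!?…]+(\\s|$)")
  ifelse(n == 0 & nzchar(text), 1L, as.integer(n))
}

estimate_words <- function(text) {
  as.integer(str_count(text, "\\S+"))
}

#' Per-source corpus statistics with a totals row
#'
#' Reports, estimated sentence and word counts (terminal-punctuation and
#' whitespace heuristics), entity totals, and the 70/15/15 split sizes per
#' source, with a final `total` row summing the sources.
#'
#' @param corpus a corpus tibble.
#' @param ratios split proportions passed to [split_counts()].
#' @return a tibble with one row per source plus a `total` row.
#' @export
corpus_stats <- function(corpus, ratios = c(0.70, 0.15, 0.15)) {
  if (nrow(corpus) == 0) {
    return(tibble(
      group = "total", reports = 0L, sentences_est = 0L, words_est = 0L,
      total_entities = 0L, n_train = 0L, n_dev = 0L, n_test = 0L
    ))
  }
  per <- map(unique(corpus$source), function(src) {
    sub <- corpus[corpus$source == src, ]
    k <- split_counts(nrow(sub), ratios)
    tibble(
      group = src, reports = nrow(sub),
      sentences_est = sum(estimate_sentences(sub$text)),
      words_est = sum(estimate_words(sub$text)),
      total_entities = sum(map_int(sub$entities, nrow)),
      n_train = k[["train"]], n_dev = k[["dev"]], n_test = k[["test"]]
    )
  })
  add_totals_row(bind_rows(per))
}

#' @rdname corpus_stats
#' @param per_source a stats tibble with one row per source (any numeric
#'   columns); used to append the `total` row that sums sources. Exposed so
#'   externally tabulated per-source counts can be aggregated with the same
#'   arithmetic.
#' @export
add_totals_row <- function(per_source) {
  total <- summarise(per_source, across(where(is.numeric), sum))
  total$group <- "total"
  bind_rows(per_source, total[names(per_source)])
}
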