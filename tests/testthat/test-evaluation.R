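test_that("F1 arithmetic reproduces printed NER rows and handles edge cases", {
  b <- reference_benchmarks()$ner
  f1 <- round_half_away(f1_from_pr(b$precision, b$recall), 2)
  expect_equal(f1, c(0.82, 0.85, 0.88))
  expect_equal(f1_from_pr(0, 0.9), 0)
  expect_equal(f1_from_pr(0, 0), 0)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_error(f1_from_pr(1.2, 0.5), class = "exoanno_metric_error")
})

test_that("macro averages over the relation columns reproduce the task-level macros", {
  b <- reference_benchmarks()$re
  expect_equal(round_half_away(macro_average(b$RuBERT), 3), 0.714)
  expect_equal(round_half_away(macro_average(b$RuBioBERT), 3), 0.767)
  expect_equal(round_half_away(macro_average(b$ModernBERT), 3), 0.836)
  expect_equal(macro_average(rep(0.4, 7)), 0.4)
  expect_error(macro_average(numeric()), class = "exoanno_metric_error")
})

test_that("overall macro is the mean of the two task macros with half-away rounding", {
  expect_equal(round_half_away(overall_macro(0.82, 0.714), 3), 0.767)
  expect_equal(round_half_away(overall_macro(0.88, 0.836), 3), 0.858)
  # 0.8085 is an exact half at 3 decimals: away-from-zero gives 0.809
  expect_equal(round_half_away(overall_macro(0.85, 0.767), 3), 0.809)
  expect_equal(overall_macro(0.5, 0.5), 0.5)
  expect_error(overall_macro(1.5, 0.5), class = "exoanno_metric_error")
})

test_that("scoring gold against itself is perfect for both tasks", {
  corp <- generate_corpus(load_knowledge(), profile = generation_profile(20, seed = 31))
  for (fn in list(score_ner, score_re)) {
    sc <- fn(corp, corp)
    expect_true(all(sc$per_type$precision == 1))
    expect_true(all(sc$per_type$recall == 1))
    expect_equal(sc$micro$f1, 1)
    expect_equal(sc$macro_f1, 1)
  }
})

test_that("NER scoring counts exact (start,end,type) matches one-to-one", {
  # gold: 4 GENE spans over 2 docs; pred misses one
  mk <- function(spans_by_doc) {
    docs <- lapply(names(spans_by_doc), function(id) {
      document(id, grid_text(10), entities = spans_by_doc[[id]], language = "en")
    })
    as_corpus(dplyr::bind_rows(docs))
  }
  gold <- mk(list(
    g1 = dplyr::bind_rows(grid_span(1, 1, "GENE", "e1"), grid_span(3, 3, "GENE", "e2")),
    g2 = dplyr::bind_rows(grid_span(1, 1, "GENE", "e1"), grid_span(5, 5, "GENE", "e2"))
  ))
  pred <- mk(list(
    g1 = dplyr::bind_rows(grid_span(1, 1, "GENE", "p1"), grid_span(3, 3, "GENE", "p2")),
    g2 = grid_span(1, 1, "GENE", "p1")
  ))
  sc <- score_ner(gold, pred)
  row <- sc$per_type[sc$per_type$type == "GENE", ]
  expect_equal(row$recall, 0.75)
  expect_equal(row$precision, 1)
  expect_equal(row$support, 4L)

  # the 3-gold / 4-pred / 2-match configuration gives micro F1 = 4/7
  gold <- mk(list(d = dplyr::bind_rows(
    grid_span(1, 1, "GENE", "e1"), grid_span(3, 3, "DISEASE", "e2"),
    grid_span(5, 5, "PHENOTYPE", "e3")
  )))
  pred <- mk(list(d = dplyr::bind_rows(
    grid_span(1, 1, "GENE", "p1"), grid_span(3, 4, "DISEASE", "p2"),
    grid_span(5, 5, "PHENOTYPE", "p3"), grid_span(7, 7, "GENE", "p4")
  )))
  sc <- score_ner(gold, pred)
  expect_equal(sc$micro$f1, 4 / 7)
  # micro counts equal the sum of per-type counts
  expect_equal(sum(sc$per_type$tp), 2L)
  expect_equal(sum(sc$per_type$fp), 2L)
  expect_equal(sum(sc$per_type$fn), 1L)
})

test_that("RE scoring requires type match and exact argument spans", {
  corp <- generate_corpus(load_knowledge(), profile = generation_profile(5, seed = 41))
  # shift one relation's head span by one character: both fp and fn
  pred <- corp
  i <- which(map_int2(pred$relations) > 0)[1]
  e <- pred$entities[[i]]
  r <- pred$relations[[i]]
  hid <- r$head_id[1]
  e$start[e$id == hid] <- e$start[e$id == hid] + 1L
  e$surface[e$id == hid] <- substr(
    corp$text[[i]], e$start[e$id == hid] + 1L, e$end[e$id == hid]
  )
  pred$entities[[i]] <- e
  sc <- score_re(corp, pred)
  ty <- r$type[1]
  row <- sc$per_type[sc$per_type$type == ty, ]
  expect_equal(row$fp, 1L)
  expect_equal(row$fn, 1L)
  expect_lt(sc$macro_f1, 1)

  # recovering 1 of 2 gold relations with no spurious predictions: F1 = 2/3
  gold <- document("d", grid_text(10),
    entities = dplyr::bind_rows(
      grid_span(1, 1, "CDNA_PROT", "v1"), grid_span(3, 3, "GENE", "g1"),
      grid_span(5, 5, "CDNA_PROT", "v2"), grid_span(7, 7, "GENE", "g2")
    ),
    relations = relation_tbl(
      c("r1", "r2"), "VARIANT_IN_GENE", c("v1", "v2"), c("g1", "g2")
    ),
    language = "en"
  )
  pred <- gold
  pred$relations[[1]] <- pred$relations[[1]][1, ]
  sc <- score_re(gold, pred)
  expect_equal(sc$per_type$f1[sc$per_type$type == "VARIANT_IN_GENE"], 2 / 3)
})

test_that("macro skips zero-gold-support types unless strict", {
  gold <- document("d", grid_text(10), entities = grid_span(1, 1, "GENE", "e1"), language = "en")
  pred <- document("d", grid_text(10),
    entities = dplyr::bind_rows(grid_span(1, 1, "GENE", "p1"), grid_span(3, 3, "DISEASE", "p2")),
    language = "en"
  )
  sc <- score_ner(gold, pred)
  expect_equal(sc$macro_f1, 1) # DISEASE has no gold support, excluded
  sc_strict <- score_ner(gold, pred, strict_types = TRUE)
  expect_lt(sc_strict$macro_f1, 1)
})

test_that("misaligned corpora are rejected", {
  a <- brca_doc("d1")
  b <- brca_doc("d2")
  expect_error(score_ner(a, b), class = "exoanno_alignment_error")
  b <- brca_doc("d1")
  b$text[[1]] <- paste0(b$text[[1]], "!")
  expect_error(score_re(a, b), class = "exoanno_alignment_error")
})

test_that("score reports tidy, glance and serialize", {
  corp <- generate_corpus(load_knowledge(), profile = generation_profile(5, seed = 51))
  sc <- score_ner(corp, corp)
  expect_named(
    tidy(sc),
    c("type", "precision", "recall", "f1", "support", "tp", "fp", "fn")
  )
  expect_equal(glance(sc)$task, "ner")
  ts <- withr::local_tempfile(fileext = ".tsv")
  write_score_report(sc, tsv_path = ts)
  tab <- readr::read_tsv(ts, show_col_types = FALSE)
  expect_equal(tab$type[nrow(tab)], "MACRO_AVERAGE")
})
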