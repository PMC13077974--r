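test_that("cDNA parser handles the attested construct inventory", {
  p <- parse_hgvs_cdna("c.5266dupC")
  expect_equal(p$change_kind, "duplication")
  expect_equal(p$position_text, "5266")
  expect_equal(p$alt_allele, "C")
  expect_equal(p$level, "cdna")

  p <- parse_hgvs_cdna("c.3671+1G>A")
  expect_equal(p$change_kind, "substitution")
  expect_equal(p$position_text, "3671+1")
  expect_equal(p$ref_allele, "G")
  expect_equal(p$alt_allele, "A")
  # the typographically spaced print form normalizes to the same parse
  expect_equal(parse_hgvs_cdna("c.3671 + 1G > A")[1:6], p[1:6])

  p <- parse_hgvs_cdna("c.68_69delAG")
  expect_equal(p$change_kind, "deletion")
  expect_equal(p$position_text, "68_69")
  expect_equal(p$ref_allele, "AG")

  expect_equal(parse_hgvs_cdna("c.100_101insTT")$change_kind, "insertion")
  expect_equal(parse_hgvs_cdna("c.100delinsGA")$change_kind, "delins")
  expect_equal(parse_hgvs_cdna("c.100-2A>T")$position_text, "100-2")

  err <- expect_error(parse_hgvs_cdna("g.12345A>T"), class = "exoanno_notation_error")
  expect_true(is.numeric(err$index))
  expect_error(parse_hgvs_cdna("c.abc"), class = "exoanno_notation_error")
  expect_error(parse_hgvs_cdna("c.100delinsXY"), class = "exoanno_notation_error")
})

test_that("protein parser accepts three-letter code with optional frameshift and spacing", {
  p <- parse_hgvs_protein("p.Glu23Valfs")
  expect_equal(p$change_kind, "frameshift")
  expect_equal(p$ref_allele, "Glu")
  expect_equal(p$alt_allele, "Val")
  expect_equal(p$position_text, "23")
  # the paper-style space after "p." is tolerated and normalized away
  expect_equal(parse_hgvs_protein("p. Glu23Valfs")[1:6], p[1:6])

  expect_equal(parse_hgvs_protein("p.Arg97Ter")$alt_allele, "Ter")
  expect_equal(parse_hgvs_protein("p.Trp26*")$alt_allele, "Ter")
  expect_error(parse_hgvs_protein("p.Xyz10Ala"), class = "exoanno_notation_error")
  expect_error(parse_hgvs_protein("p.Glu23"), class = "exoanno_notation_error")
})

test_that("genomic locations accept chr1-22/X/Y/MT and optional spacing", {
  p <- parse_genomic_loc("Chr13:32914438G > A")
  expect_equal(p$level, "genomic")
  expect_equal(p$position_text, "13:32914438")
  expect_equal(p$ref_allele, "G")
  expect_equal(p$alt_allele, "A")
  expect_equal(parse_genomic_loc("Chr13:32914438G>A")[1:6], p[1:6])
  expect_equal(parse_genomic_loc("chrMT:100A>G")$position_text, "MT:100")

  expect_error(parse_genomic_loc("chr0:1A>T"), class = "exoanno_notation_error")
  expect_error(parse_genomic_loc("chr23:1A>T"), class = "exoanno_notation_error")
  # region-only locations need the lenient flag
  expect_error(parse_genomic_loc("chr13:32914438"), class = "exoanno_notation_error")
  expect_equal(parse_genomic_loc("chr13:32914438", allow_region = TRUE)$change_kind, "region")
})

test_that("Cyrillic homoglyphs are mapped to Latin and recorded", {
  # "с" and "С" here are Cyrillic
  p <- parse_hgvs_cdna("с.5266dupС")
  expect_true(p$homoglyphs_normalized)
  expect_equal(p$raw, "c.5266dupC")
  expect_false(parse_hgvs_cdna("c.5266dupC")$homoglyphs_normalized)
  expect_equal(validate_identifier("CLINVAR_ID", "RСV000255123"), "RCV000255123")
})

test_that("parse-render-parse is a fixpoint on accepted strings", {
  cdna <- c("c.5266dupC", "c.3671+1G>A", "c.68_69delAG", "c.12_14insGGT", "c.9delinsAA", "c.55-2T>C")
  for (s in cdna) {
    p <- parse_hgvs_cdna(s)
    expect_equal(parse_hgvs_cdna(render_hgvs(p))[1:6], p[1:6], info = s)
  }
  for (s in c("p.Glu23Valfs", "p.Arg97Ter", "p.Ala10Gly")) {
    p <- parse_hgvs_protein(s)
    expect_equal(parse_hgvs_protein(render_hgvs(p))[1:6], p[1:6], info = s)
  }
  p <- parse_genomic_loc("Chr13:32914438G > A")
  expect_equal(parse_genomic_loc(render_hgvs(p))[1:6], p[1:6])
})

test_that("identifier validators normalize and reject by pattern", {
  expect_equal(validate_identifier("OMIM_ID", "OMIM #618333"), "618333")
  expect_equal(validate_identifier("OMIM_ID", "618333"), "618333")
  expect_equal(validate_identifier("OMIM_ID", "#618333"), "618333")
  expect_equal(validate_identifier("CLINVAR_ID", "RCV000255123"), "RCV000255123")
  expect_equal(validate_identifier("DBSNP_ID", "rs123456"), "rs123456")
  expect_equal(validate_identifier("DBSNP_ID", "RS123456"), "rs123456")
  err <- expect_error(validate_identifier("OMIM_ID", "61833"), class = "exoanno_identifier_error")
  expect_match(conditionMessage(err), "6 digits")
  expect_error(validate_identifier("CLINVAR_ID", "RCV123"), class = "exoanno_identifier_error")
  expect_error(validate_identifier("DBSNP_ID", "rs"), class = "exoanno_identifier_error")
})

test_that("document validation reports violations as data, entities before relations", {
  expect_equal(nrow(validate_document(brca_doc())), 0)

  # reversed relation direction -> constraint violation
  d <- brca_doc()
  d$relations[[1]]$head_id <- "e2"
  d$relations[[1]]$tail_id <- "e1"
  v <- validate_document(d)
  expect_equal(v$code, "relation-constraint")

  # surface not equal to the text slice
  d <- brca_doc()
  d$entities[[1]]$surface[2] <- "BRCA2"
  v <- validate_document(d)
  expect_equal(v$code, "surface-mismatch")
  expect_equal(v$offending_id, "e2")

  # out-of-bounds offsets
  d <- brca_doc()
  d$entities[[1]]$end[2] <- 999L
  expect_equal(validate_document(d)$code, "offset-bounds")

  # dangling relation endpoint
  d <- brca_doc()
  d$relations[[1]]$tail_id <- "missing"
  v <- validate_document(d)
  expect_equal(v$code, "dangling-endpoint")
  expect_match(v$message, "missing")

  # invalid norm payload
  d <- brca_doc()
  d$entities[[1]]$norm[1] <- "not-hgvs"
  expect_equal(validate_document(d)$code, "norm-invalid")

  # duplicated (start,end,type) triple
  d <- brca_doc()
  d$entities[[1]] <- dplyr::bind_rows(
    d$entities[[1]],
    entity_tbl("e3", "GENE", 23L, 28L, "BRCA1")
  )
  expect_true("duplicate-span" %in% validate_document(d)$code)

  # a document failing both layers reports entity violations first
  d <- brca_doc()
  d$entities[[1]]$surface[1] <- "oops"
  d$relations[[1]]$tail_id <- "missing"
  v <- validate_document(d)
  expect_equal(v$code, c("surface-mismatch", "dangling-endpoint"))
})

test_that("document validation is idempotent and side-effect-free", {
  d <- brca_doc()
  d$entities[[1]]$surface[2] <- "BRCA2"
  v1 <- validate_document(d)
  v2 <- validate_document(d)
  expect_identical(v1, v2)
  # fixing the named violation empties the report
  d$entities[[1]]$surface[2] <- "BRCA1"
  expect_equal(nrow(validate_document(d)), 0)
})
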