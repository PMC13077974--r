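# exoanno

A tidyverse-native toolkit for multi-level stand-off annotation of clinical
exome-sequencing (WES) reports. Genetic diagnostic conclusions carry dense,
highly structured content — a variant in HGVS notation, its gene, the
associated disease, ACMG/AMP clinical significance, zygosity, inheritance
mode, phenotype terms and knowledge-base identifiers — yet they circulate as
free text. exoanno is for corpus builders and clinical-NLP researchers who
need that structure made explicit, validated, generated at scale, and
scored.

Each document is modeled as a triple $(X, Y, R)$: the report text $X$, a
set of typed character-offset entity spans $Y$ (16 closed types, from
`GENE` and `CDNA_PROT` to `RETEST_PLAN`), and a set of directed typed
relations $R$ (7 types, e.g. `VARIANT_IN_GENE`:
{`CDNA_PROT`,`VARIANT_LOC`} → {`GENE`}), with relation annotation composed
on top of entity annotation ($\Phi = \Phi_r \circ \Phi_e$). The package
provides:

* **schema + validators** — the closed vocabularies, the relation
  domain/range constraint table, pragmatic HGVS cDNA/protein/genomic
  parsers (whitespace- and Cyrillic-homoglyph-tolerant), OMIM/ClinVar/dbSNP
  identifier validators, and `validate_document()`, which returns every
  violated invariant as data;
* **knowledge + generator** — a ClinVar-style knowledge-record table with
  significance filtering, and a seeded template-based generator that
  renders records into Russian-style report text with gold character
  offsets computed during rendering (every generated document validates
  cleanly; full-coverage mode guarantees all 16 + 7 types per batch);
* **agreement** — exact span-level F1 between annotators, per-category
  token-level Cohen's κ = (p₀ − pₑ)/(1 − pₑ) from the pooled 2×2 confusion
  matrix, and the macro κ with population spread;
* **evaluation** — exact-match NER and RE scoring with per-type/micro/macro
  precision, recall and F1, and the overall macro-F1 (mean of the two task
  macros), rounded half-away-from-zero only at reporting time;
* **corpus ops + io** — stratified 70/15/15 document-level splitting,
  corpus statistics, and lossless converters for Label Studio JSON, a JSONL
  stand-off dialect, and BIO/CoNLL.

## Worked example

```r
library(exoanno)

k <- load_knowledge()                                   # bundled 40-row synthetic fixture
path <- filter_records(k, c("PATHOGENIC", "LIKELY_PATHOGENIC"))   # 18 records
corp <- generate_corpus(path, profile = generation_profile(100, seed = 42))
corp
#> <annotated corpus: 100 document(s), 742 entities, 395 relations>

corp$text[[2]]
#> Методом полноэкзомное секвенирование (WES) в гене COL1A1 выявлен вариант
#> c.964+1C>G (rs382735) в состоянии heterozygous. Согласно критериям ACMG/AMP
#> вариант классифицирован как патогенный (ClinVar: RCV000326271). ...

corp$entities[[2]]
#> # A tibble: 12 × 7
#>   id    type              start   end surface                    norm  parent_id
#> 1 e1    DIAGNOSTIC_METHOD     8    42 полноэкзомное секвенирова… <NA>  e3
#> 2 e2    GENE                 50    56 COL1A1                     COL1… <NA>
#> 3 e3    CDNA_PROT            73    83 c.964+1C>G                 c.96… <NA>
#> 4 e4    DBSNP_ID             85    93 rs382735                   rs38… e2
#> ...

stratified_split(corp, seed = 42)
#> <stratified split: 70 train / 15 dev / 15 test>

# score a degraded copy of the gold standard against it
pred <- corp
pred$entities <- lapply(corp$entities, function(e) e[seq_len(nrow(e)) %% 7 != 0, ])
glance(score_ner(corp, pred))
#> # A tibble: 1 × 6
#>   task  micro_precision micro_recall micro_f1 macro_f1 n_types
#> 1 ner                 1        0.912    0.954    0.910      16
```

The entity table reads directly: span `e3` is the cDNA variant
`c.964+1C>G` at characters [73, 83) with its canonical HGVS form as the
normalized payload; `e4` (the dbSNP id) is nested under the gene span via
`parent_id`. Dropping every seventh gold span costs recall (0.912) but no
precision, and the micro-F1 of 0.954 is their harmonic mean.

A thin command-line front end over the same functions ships at
`inst/cli/exoanno.R` (subcommands `generate`, `validate`, `convert`,
`split`, `stats`, `iaa`, `score-ner`, `score-re`), and
`vignettes/annotation-model.Rmd` documents the model, the generator's
assumptions and the numerical conventions.

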