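---
title: "The annotation model, generator and metrics behind exoanno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The annotation model, generator and metrics behind exoanno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoanno)
```

## The problem and the model

Clinical whole-exome sequencing (WES) reports are short narrative texts that
carry highly structured content: a variant in HGVS notation, the gene it
falls in, the associated disease, its ACMG/AMP significance, zygosity,
inheritance mode, phenotype terms, knowledge-base identifiers (OMIM,
ClinVar, dbSNP) and clinician recommendations. exoanno formalizes a report
as a triple — the text, a set of typed character-offset entity spans, and a
set of directed typed relations between spans. A corpus is a tibble with
one document per row; entities and relations live in list-columns so the
whole object pipes through dplyr.

The entity inventory is a closed set of 16 types and the relation inventory
a closed set of 7, each relation constrained by a domain/range table
(`relation_types()`): for example `VARIANT_IN_GENE` only accepts a
`CDNA_PROT` or `VARIANT_LOC` head and a `GENE` tail. `validate_document()`
enforces every invariant and returns violations as data rather than
exceptions, checking the entity layer before the relation layer — relation
annotation is defined on top of entity annotation, so a dangling or
ill-typed span is reported before any edge that touches it.

Two further design points deserve a note:

* **Offsets are 0-based and half-open.** This matches Label Studio's export
  convention and makes `surface == substr(text, start + 1, end)` a testable
  equality in R.
* **Nesting is stored redundantly.** A governed span (say, an `OMIM_ID`
  inside a disease parenthetical) carries a `parent_id`; when the pair also
  corresponds to a canonical relation, that relation is materialized as an
  edge as well. Consumers that only read edges and consumers that only read
  the hierarchy both see the link.

The published description of this scheme uses divergent lower-case relation
names in one of its results tables (`disease_inheritance`,
`disease_omim_link`, plus two — `variant_linked_to_omim`,
`retest_recommended_for` — that appear in no inventory). The 7-type
constraint table is treated as canonical here; `normalize_relation_alias()`
resolves the two reconcilable synonyms and refuses everything else loudly.
Whether `RETEST_PLAN` spans participate in any canonical relation is left
unstated by the scheme; exoanno links them to their gene via `parent_id`
only, which the redundant-nesting rule explicitly allows.

## Notation validators

The HGVS grammar implemented is a pragmatic clinical-report subset, not the
full standard: cDNA substitutions, deletions, duplications, insertions and
delins with plain, range (`68_69`) and intronic-offset (`3671+1`)
positions; protein substitutions and frameshifts in three-letter code; and
genomic `chr13:32914438G>A` locations. Two tolerances reflect how these
strings actually appear in reports: typographic whitespace (`G > A`,
`p. Glu23Valfs`) is normalized away, and Cyrillic homoglyph letters
(А, С, Е, Р, ...) are mapped to their Latin twins before matching, with the
substitution recorded on the parse. Region-only genomic locations
(`chr13:32914438` with no alleles) are rejected by default and accepted
under an explicit lenient flag, since the scheme shows the allele form but
labels the type by chromosome prefix alone. `render_hgvs()` emits the
canonical compact form, which is what `norm` payloads store;
parse–render–parse is a fixpoint and is tested as such.

Identifier validators are strict by pattern: 6-digit OMIM (optional
`OMIM #` prefix), `RCV` + 9 digits, `rs` + 1–10 digits (lower-cased). No
reference genome, HGNC service or OMIM/ClinVar API is consulted — the
validators check form, not biological truth.

## The synthetic generator

The generator is the constructive realization of the two-phase annotation
composition: it renders a structured knowledge record (gene, variant,
disease, significance, identifiers, phenotypes, recommendation texts)
through a template bank and emits the gold entity spans *during* rendering,
never by post-hoc string search, so offsets are correct by construction and
every generated document passes `validate_document()` — a property the test
suite checks over a thousand seeded documents.

Choices that shape the output:

* **Template bank.** Ships in Russian (the report genre's language, with
  Latin-script HGVS and gene symbols embedded, as real reports mix
  alphabets) plus a parallel English bank used in documentation and tests.
  Four Russian report templates cover the genre's range: a full-form
  report whose sentences jointly realize all 16 entity and 7 relation
  types, a standard mid-length form, a genomic-coordinate form, and a
  one-sentence minimal form. Slot values are embedded verbatim (no
  morphological inflection of slot contents); agreement is carried by the
  surrounding template wording, so offsets and validator checks stay
  stable.
* **Sampling.** Records are sampled with replacement, templates uniformly
  among those the record can fill, and optional report elements
  (phenotype sentence, protein notation, recommendations, ...) are included
  with probability 0.7 by default — a value chosen to make long, complete
  reports common but not universal, which is how the genre reads in
  practice. In `coverage_mode = "full"` (the default), (record, template)
  pairs covering still-missing types are scheduled first with all optional
  elements on, so even small batches exercise the whole scheme; the batch
  errors, listing the missing types, if the bank/records cannot reach
  full coverage.
* **Determinism.** Generation is a pure function of (records, bank,
  profile) including the seed; the split derives per-source seeds from a
  stable hash of the source name so adding a source never reshuffles an
  existing one.
* **The bundled knowledge fixture** is 40 hand-written synthetic rows: real
  HGNC gene symbols with invented but grammar-valid variants, identifiers
  and Russian disease/phenotype strings, with a fixed significance profile
  (10 pathogenic, 8 likely pathogenic, 12 VUS, 6 benign, 2 likely benign,
  1 protective, 1 risk factor, none drug-response). Field names mirror
  ClinVar column vocabulary so a real export can be swapped in later.

What the generator deliberately does **not** emulate: free narrative
variation beyond the template bank, discontinuous or overlapping entity
mentions, annotation noise, and the stylistic diversity of authentic
clinical prose. Tests passing on generated corpora therefore demonstrate
the correctness of the *machinery* (offsets, constraints, round-trips,
metric arithmetic) — they do not certify extraction quality on real
reports, and the published model scores on the real corpus are not
reproducible from this package (they require the unpublished annotations
and GPU fine-tuning, both out of scope).

## Agreement metrics

Span-level agreement is exact: a span matches iff `(start, end, type)` are
all equal, with precision over the second annotator, recall over the
reference, and the 0/0 conventions (empty vs empty is perfect agreement; an
empty side alone contributes 1 to its own degenerate ratio and the F1 of
(0, r) is 0).

Per-category agreement is Cohen's kappa. The published protocol reports
kappa per entity category without stating the unit of agreement; exoanno
adopts a token-level reading as the standard reproducible choice: each
token is labeled category-vs-OTHER per annotator (a token carries the
category iff any span of that category covers it) and kappa is computed
from the 2×2 confusion matrix pooled over documents. Span-level kappa is
deliberately not offered — without a fixed item universe over spans the
chance term is ill-defined. The default tokenizer is a deterministic
Unicode rule (maximal letter/digit runs plus standalone punctuation) and is
pluggable; a whitespace tokenizer is also exported. The macro kappa is the
unweighted mean with the *population* standard deviation as the ± term,
because the category set is the full population, not a sample.

One arithmetic discrepancy is worth surfacing rather than hiding: the nine
published per-category kappas (0.85, 0.81, 0.82, 0.77, 0.74, 0.76, 0.75,
0.79, 0.73) average to 0.78 (population sd 0.038, displayed 0.04), while
the source table's macro row prints 0.79 ± 0.04. exoanno reports the
computed 0.78 ± 0.04; the acceptance script recomputes it from the bundled
table at run time.

```{r}
mk <- macro_kappa(reference_benchmarks()$iaa$kappa)
round_half_away(mk$mean, 2)
round_half_away(mk$std, 2)
```

## Extraction scoring

NER scoring is exact-match: a predicted span is a true positive iff an
unmatched gold span with equal `(start, end, type)` exists in the same
document. Matching is one-to-one; because the key is full equality, the
strictest greedy matching reduces to multiplicity-respecting counting per
distinct key, which is what is implemented. Relation scoring requires the
relation type and both argument spans to match exactly. Reports carry
per-type precision/recall/F1 with supports, micro scores from pooled
counts, and the macro-F1 over types with nonzero gold support (a strict
flag averages over all scored types instead, so tiny corpora don't silently
inflate). The overall score is the mean of the NER and RE macro-F1.

All arithmetic is carried at full precision; rounding happens only at
reporting time, half away from zero — 2 decimals for NER-style tables,
3 for RE and overall tables. That rule is load-bearing in one place: an
overall macro of (0.85 + 0.767)/2 = 0.8085 displays as 0.809.

## Corpus operations

The 70/15/15 split gives both held-out parts `round(0.15 n)` documents
(half away from zero) and training the remainder — the unique simple rule
consistent with partitioning 318 documents as 222/48/48 (47.7 → 48) and
5,000 as 3,500/750/750. A side effect worth knowing: because both held-out
parts round at the same n, a unit increase of n can shrink the training
set by one document (n = 9 trains 7, n = 10 trains 6); training size is
non-decreasing over steps of two. Splitting is stratified by document
source (authentic vs synthetic) at the document level, so templated
synthetic text cannot leak across partitions. Corpus statistics estimate
sentences by terminal-punctuation runs followed by whitespace and words by
non-whitespace runs — the same class of heuristic the published corpus
tables label as estimates; the per-source sentence/word figures of the real
corpus are not reproduced here since the underlying texts are not at hand.

## Interchange formats

Label Studio JSON (the full-export span/relation result schema, with `norm`
and `parent_id` carried in item `meta` and foreign task fields preserved),
a JSONL stand-off dialect (one document per line), and BIO/CoNLL token
tagging all round-trip generated corpora losslessly, which the suite checks
across seeds. BIO flattens nesting to the outermost span per position (a
two-layer mode emits the contained spans as a second pass) and expands
spans that cross token boundaries to the smallest covering token run with a
warning. Import never silently repairs data: a span whose stored text
disagrees with the text slice is reported in the attached validation table.

## Problem sizes and limits

The test suite generates batches of up to 1,000 documents for the
gold-validity property and a single 318 + 5,000 hybrid build for the
split/statistics checks; the acceptance script regenerates the hybrid build
from scratch at the same sizes, which reflect the published corpus
composition. Known limitations: the HGVS subset excludes complex
rearrangements and protein-level constructs beyond substitution/frameshift;
the generator offers no paraphrase diversity beyond its template bank;
token-level kappa is one defensible reading of the published per-category
agreement, not the only one; and nothing here validates variants against a
reference genome or live HGNC/OMIM/ClinVar services.
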