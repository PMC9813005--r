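---
title: "Extracting methodological study characteristics from JATS articles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting methodological study characteristics from JATS articles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studychar)
```

## What the package does

`studychar` extracts methodological study characteristics from scientific
articles encoded in NISO-JATS XML (the tagging standard used by PubMed
Central, and the output format of PDF-conversion tools such as CERMINE).
The features it targets are the ones that describe how a frequentist
analysis was set up and reported: the alpha-level, the test power,
corrections for multiple testing, interaction/mediation/moderation
analyses, the test direction, outlier-exclusion rules expressed in
standard deviations, mentioned statistical assumptions, the analysis
software, the statistical methods, and the number of sub-studies an
article reports.

All extraction is heuristic and rule-based — regular expressions over
normalized, sentence-split text — rather than model-based NLP. The
trade-off is deliberate: rules are transparent, deterministic, and every
miss or false alarm can be traced to a specific pattern.

## Section-aware text selection

Introductions cite other people's alpha-levels and discussions recommend
analyses nobody ran, so extraction is restricted to a *surface*: the
methods and results sections plus (for most numeric features) figure and
table captions. The reference list is isolated at parse time and can
never reach a surface. Three choices here were genuinely open and are
resolved as follows:

* **Title keywords.** Section titles are bucketed by case-insensitive
  substring sets (methods ← method, material, procedure, participant,
  sample, measure, design, apparatus, analysis plan; results ← result,
  finding, analys; discussion ← discussion, conclusion, limitation,
  implication; introduction ← introduction, background, theory), checked
  in the fixed order methods → results → discussion → introduction. The
  sets reproduce the conventional structure of empirical psychology
  articles, the genre the heuristics were tuned for.
* **Nested sections.** A subsection whose own title matches no bucket
  inherits the bucket of its nearest classified ancestor, so
  "Study 1 > Stimuli" lands in methods. This is a convention of ours, not
  something the JATS standard prescribes.
* **Degraded input.** PDF-converted XML often loses every section title.
  When both the methods and results buckets are empty, the whole
  unclassified body becomes the surface: a degraded file is still
  processed, at the cost of a somewhat noisier text base. Table cell
  content is parsed but enters the surface only when
  `sc_config(include_tables = TRUE)` — column names and cell text are a
  known source of missed values, and the flag lets users trade recall for
  noise.

## The normalization layer

Every extractor works on text that has passed `letter_convert()`,
`text2sentences()` and (where numbers matter) `text2num()`:

* `letter_convert()` decodes HTML/hex entities, maps all space-like code
  points (the full Unicode `Zs` category plus zero-width characters such
  as U+200B) to a plain space, repairs Greek letters that PDF conversion
  mangles in statistical contexts (`v2(3) = 12.4` → `χ2(3) = 12.4`), and
  inserts a `<=>` placeholder where an operator between a statistic
  symbol and a number was lost (`t 1.2` → `t <=> 1.2`). The placeholder
  is understood as an operator by the numeric extractors, which is what
  lets operator-stripped documents still yield values. The repair
  catalogue is a documented, extensible subset of the conversion errors
  seen in the wild; the function is idempotent.
* `text2sentences()` splits after sentence-final punctuation followed by
  whitespace and an upper-case letter or digit, protecting decimals
  (`p = .05`), a curated abbreviation list (`et al.`, `e.g.`, `Fig.`,
  ...) and single-letter initials. Joining the sentences reproduces the
  input's non-whitespace character sequence.
* `text2num()` rewrites number words (one…twenty plus the tens and
  hyphenated composites), percentages, simple fractions, powers of ten
  and e-notation as plain decimals (`five percent` → `0.05`, `0.05/5` →
  `0.01`). A word fused to a following term (`one-sided`) is left alone;
  a fraction with denominator zero is left unchanged. Larger number words
  pass through — values beyond the reporting range never matter for the
  features extracted here.

## The extractors and their tunable parameters

**Alpha-level** (`extract_alpha`, surface incl. captions). Synonyms
(alpha level, level of significance, significance threshold/criterion,
level of confidence/probability, type-1 error) are unified before numeric
capture. A fraction report (`α = 0.05/4`) returns both the nominal 0.05
and the corrected 0.0125; which label a *bare* unusual value deserves
cannot be decided reliably, so the merged `max_alpha`/`min_alpha` fields
are the primary output and a value in a sentence that talks about
correction or adjustment is filed as corrected. `p2alpha` (default on)
also accepts significance-threshold statements about p-values
("Results with p-values < 0.05 are considered significant.") — but only
in sentences with a declarative trigger (considered, defined, set, ...),
which keeps ordinary significant results out. `x%` confidence intervals
contribute `(100 − x)/100`. Asterisk-coded p-value legends are ignored.
All values are constrained to (0, 1).

**Test power** (`extract_power`, full text). Sentences where power is
physical (volts, amps, Hz, watts, ...) are dropped. Values outside
[0, 1] are discarded — an erroneous "power of 80" is never returned.
Beta-error reports are converted via 1 − β and flagged.

**Multiple-testing correction** (`extract_multiple_comparison`, surface
incl. captions). Two stages: only sentences containing *adjust*,
*correct*, *post-hoc* or *multiple* are searched for twelve author names
and four procedure names. Misspellings (Bonfferoni, Tuckey, Scheffe,
...) are matched by tolerant patterns but returned canonically. A
"Bonferroni test" without a trigger word is not a correction report.

**Interaction effects** (`detect_interaction`). Sentences about
interactions of organisms (mother, infant, peer, cell, ...) are removed
before the keyword families for interaction, mediation and moderation are
applied; `any` is their disjunction.

**Test direction** (`extract_test_direction`). Works on sentences with a
test/hypothesis trigger, minus known false-alarm contexts (paper, page,
pathway, "one-sided aggression"). The phrase "two tails" is *not* an
inclusion pattern in the default mode — it is a documented miss of the
faithful rule set; `extended_patterns = TRUE` adds it.

**Outlier definition** (`extract_outlier_def`). Sentences with a removal
or outlier term and a number (numeric or word) followed by "standard
deviation(s)"/"SD"; ± tolerated. The result space defaults to [1, 10]:
larger distances indicate measurement error, smaller ones are mostly
capture noise. Both bounds are arguments.

**Assumptions** (`extract_assumptions`). A 20-entry gazetteer searched
longest-label-first with matched text consumed, so "missing completely at
random" does not additionally emit "missing at random". Phrases outside
the dictionary (e.g. homogeneity of covariance matrices) yield no hit.

**Software** (`extract_software`). A 55-entry dictionary tuned to each
tool's in-text appearance; the R language requires a version number,
"R Core Team" or an "the R environment/language/…" context so the bare
letter never fires. `add` terms are matched verbatim and reported
separately.

**Methods** (`extract_methods`). Sentences containing an identifier term
(test, correlation, regression, anova, method, theorem, interval,
algorithm, analysis, model, estimator) yield, per hit, up to seven
preceding words with the identifier at the end, clipped at clause
boundaries and cleaned with a curated redundant-word list (articles,
auxiliaries, common verbs, numbers). The redundant-word list was built
iteratively against generated and example text and is versioned with the
package. Bare identifiers are dropped, which also keeps stand-alone
descriptive measures out. Unknown procedures are picked up whenever their
name ends in an identifier (a "quickfit algorithm").

**Study count** (`count_studies`, titles + abstract). The maximum
enumeration attached to study/experiment headings, with word numbers
("Study One") converted first; 1 when nothing is enumerated. Because a
count is always returned, this feature has no correct negatives — its
output can only be right or wrong.

## The method taxonomy

`categorize_methods()` maps raw mentions onto named categories
(ANOVA, Logistic regression, ...) through a shipped pattern table. The
published search expressions use an idiosyncratic anchor notation; we
transcribe carets conservatively as start-of-phrase/preceding-space
anchors and keep lazy quantifiers, and the transcription is pinned by
unit tests (a "manova" mention must not count as ANOVA, "one sample t
test" must not count as independent t-test). Two categories (correlation
comparison test, multilevel logistic regression) are unreachable from the
default extraction output and ship as documented expected-zeros.
`tabulate_methods()` counts *articles*, not mentions.

## Evaluation protocol

Extractions are scored per article and feature as value sets against a
gold coding (CSV: `article_id`, `feature`, `value`): correct positives
are exact matches, misses are false negatives, surplus extractions false
positives, and an article with neither gold nor extracted values is one
correct negative — so with gold {5%, 10%} and extraction {5%, 1%} an
article contributes CP = 1, FN = 1, FP = 1, and totals may exceed the
number of articles. Repeated identical values are treated as sets, since
a repeatedly detected feature is reported once. The summary measures are
sensitivity = CP/(CP+FN), specificity = CN/(CN+FP), accuracy =
(CP+CN)/(CP+FN+CN+FP); a measure with a zero denominator is undefined
and reported as `NA` (the study count has no specificity). Reported
metrics are rounded half-up to two decimals.

## The synthetic corpus generator

`fixture_spec()`/`generate_corpus()` produce JATS articles with
declaratively planted features and the exactly matching gold rows, so the
simulate → extract → evaluate loop closes without any external data.
Design points:

* **Templates are data.** Every feature has a small pool of templated
  sentences (in `extdata/templates.json`); all templates of one style
  plant identical gold values, so the gold standard depends only on the
  spec, never on the sampled template. Where a template unavoidably
  introduces an extractable mention of its own (a confidence-interval
  sentence is also a method mention, "confidence intervals"), that
  induced value is part of the gold.
* **Default frequencies are the field's.** Feature presence rates follow
  the empirical profile of psychology articles: about half report some
  alpha-level (confidence intervals being the most common style), ~16%
  a power value, ~22% a correction, ~9% an SD outlier rule, ~12% a test
  direction, ~69% some interaction-type analysis, ~63% a software
  package, and the study count distribution is dominated by single-study
  articles (roughly 70% one study, tailing off to six). These rates are
  fixed generator defaults, not tuning knobs.
* **Corruption emulates PDF conversion.** Four classes:
  `drop_section_titles` (sectioning lost → surfaces fall back, the study
  count returns its default of 1), `strip_operators` (comparison
  operators deleted between symbols and numbers; `letter_convert()`'s
  `<=>` placeholder recovers some), `break_greek` (α→a, β→b, χ2→v2; the
  chi-square form is repairable, the others are genuine misses) and
  `insert_invisible_spaces` (zero-width characters; fully repaired by
  normalization). By construction corruption causes *misses*, never
  false alarms — mirroring the low-false-positive profile the heuristics
  are built for.
* **Randomness** exists only in template choice, filler placement and
  feature sampling, all under a single integer seed; generation is
  byte-for-byte reproducible.

What the generator does **not** emulate: real articles' linguistic
variety ("The statistical power was very high (0.99)" defeats the power
rule), tables that carry values in cells, non-English text, and the full
breadth of CERMINE's structural damage. A perfect score on the synthetic
corpus therefore demonstrates that the pipeline is lossless end-to-end on
the templated phrasings — not that real-world recall is 1.

## Problem sizes and numerical choices

The shipped test suite closes the loop on a 200-article clean corpus and
a 60-article corruption-injected corpus (both a comfortable size for the
properties being asserted: every feature occurs dozens of times), checks
idempotence and conservation properties on generated text, and verifies
the summary-measure formulas against published confusion-count rows.
Numeric values are compared after rounding to 6 decimals and
canonicalized to plain decimal strings ("0.050" ≡ "0.05"); metric
rounding is half-up; ties in section classification are broken by the
fixed bucket order; all extractor outputs are lexicographically sorted,
de-duplicated sets so serialization is stable.

## Known limitations

* Methods with a specifying term *after* the identifier ("test for
  homogeneity of variances") are not harvested.
* Corrected and nominal alpha-levels cannot be reliably distinguished
  outside fraction reports; use `max_alpha`/`min_alpha` when in doubt.
* English-language text only.
* The dictionaries are curated subsets tuned for psychology; other
  disciplines will want to extend them via the dictionary file
  arguments.
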