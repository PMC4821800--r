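---
title: "Mining the reporting of mouse sex and age: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the reporting of mouse sex and age: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micereport)
```

## The problem and the approach

Whether a paper states the sex and the age of the mice it used is a simple,
binary property of its text — which makes it measurable at corpus scale by
rule-based extraction, with no training data and with every decision
inspectable. `micereport` implements that measurement in four stages:
mention extraction, document-level unification, evaluation against a manual
gold standard, and corpus analytics. This vignette records the model behind
each stage, the tunable parameters and their defaults, the synthetic-data
generator's assumptions, and the design decisions taken where the design
was genuinely open.

## The extraction model

Extraction is deliberately asymmetric between the two characteristics.

**Sex** is matched by a small dictionary: phrases that name females, males
or both sexes (`"female mice"`, `"mice of either sex"`, `"both sexes"`,
`"male and female"` and so on — 14 rules in the default set). Matching is
case-insensitive over the raw concatenated text, with no lemmatization, no
coreference and no inference. Two consequences are accepted as part of the
model rather than patched:

* sex implied only by proxy words (e.g. *pregnant*) is **not** detected —
  a known false-negative class;
* bare `male`/`female` tokens match wherever they occur, including
  husbandry sentences about breeding crosses — a known false-positive
  class.

**Age** is matched by lexical patterns (18 in the default set) that all
require three ingredients: a numeral — digits or the number words
*one…twelve* — or a numeral range; a time unit restricted to
**day / week / month** (with the short forms `d`, `wk`, `mo`); and an age
clue (`aged …`, `… old`, `… of age`, attributive `…-old`, `age: …`,
`at the age of …`, `between … and … of age`, …). Range connectors accept
`to`, `and` and the hyphen/en-dash/em-dash family. Because a *closed*
numeric range is required, open-ended spans (*"postnatal day (P) 7 to
several months"*) and bare numeral–unit pairs without a clue
(*"15-d timed-pregnant"*) yield no mention — the documented
false-negative behaviour. Units outside day/week/month (*hours*, *years*)
and embryonic-stage notation are excluded by default; an `"extended"`
profile adds postnatal-day expressions, and `decimal_ages = TRUE` admits
decimal numerals (`"6.5 weeks old"`). Both are off by default because the
default profile is meant to reproduce the documented behaviour of the
minimal rule set, not to improve on it.

Rules are plain data (`default_rules()` returns a tibble; `write_rules()` /
`read_rules()` give a TSV config), so the set can be audited, edited or
replaced wholesale.

Within one kind, overlapping candidate matches are resolved
leftmost-longest: candidates are ordered by start offset, then by
decreasing length, and any candidate overlapping an already-kept one is
dropped. Offsets are 0-based and half-open over the concatenated document
text, and every mention satisfies
`surface == substr(text, start + 1, end)` — a property the test suite
checks directly.

## Unification

A document may contain many candidate mentions per characteristic; the
document-level annotation keeps exactly one: the mention with the maximal
span length, ties broken by the smallest start offset. The longest mention
is usually the most informative (`"female mice"` over `"female"`). The
rule is order-free and idempotent (property-tested). Two edge cases are
worth recording:

* A document with separate `male` and `female` mentions but no both-sexes
  phrase resolves to whichever single mention wins. This may under-count
  both-sex studies; such documents are logged when
  `options(micereport.verbose = TRUE)`.
* The distinction between both-sexes-mixed and both-sexes-separated cannot
  in general be decided from one unified mention. The mention carries a
  qualifier (`mixed` / `separated` / `unspecified`) only when the phrase
  itself encodes it (e.g. *"separated by sex"*); analytics aggregate all
  of them as `both`.

## Evaluation

Scoring is at the document level. For each characteristic: gold reported
and system reported with agreeing values is a true positive; a system
report with the wrong value or with no gold counterpart is a false
positive; a missed gold report is a false negative; agreement on absence
is a true negative — so the four cells always sum to the number of
documents, and a wrong value costs exactly one false positive (not also a
false negative). Sex values agree on category; age values agree after
normalization to days (1 day = 1, 1 week = 7, 1 month = 30) with exact
range equality by default and an optional `age_tolerance_days`.

Precision, recall and F-score are computed on the percent scale and
**presented to one decimal by truncation**, with the presented F-score
computed from the presented P/R pair. Truncation, not rounding, is the
presentation convention because it is the only rule consistent with how
such evaluation tables are printed in this literature
(90.625 → 90.6, 96.875 → 96.8, 88.571 → 88.5, and an F of 92.46 → 92.4);
raw unrounded values are always exposed alongside. Undefined metrics
(zero denominators) are signalled and returned as `NA`, never as 0.

One caution on invariants: swapping the roles of system and gold exchanges
false positives and false negatives **only** when all disagreements are
presence/absence disagreements. A wrong-value document is a false positive
from either side. The property test is therefore restricted to
presence/absence pairs, and wrong-value behaviour is pinned by a
hand-scored micro-set instead.

## Corpus analytics

Documents — never mice — are the unit of analysis.

* **Reporting breakdown**: each document falls in exactly one of
  `both`, `sex_only`, `age_only`, `none`; counts and percentages (two
  decimals) per stratum (year, journal, disease group, subgroup). A
  document belonging to several disease groups counts once in each
  group's stratum.
* **Trends**: per-year fractions (category count over that year's article
  count, so fractions sum to 1 within a year) and their ordinary
  least-squares slope via `stats::lm()`.
* **Sex-bias ratio**: female-only vs male-only document counts,
  majority:minority with the direction named; both-sex documents are
  excluded from both sides. Ties give ratio 1 with direction `none`.
* **Binomial proportion test**: two-sided exact test
  (`stats::binom.test`) of p = 0.5 on the female count; the 95% CI for
  the female share uses the normal approximation
  p̂ ± 1.96·√(p̂(1−p̂)/n) on the percent scale. The conventional
  two-decimal multiplier 1.96 is used at the default level (other levels
  use `qnorm`); Clopper–Pearson is available via `ci_method = "exact"`.
* **Two-way ANOVA without replication** (`stats::aov`): the classical
  partition SS_total = SS_rows + SS_cols + SS_residual with df (r−1),
  (c−1), (r−1)(c−1); the residual plays the role of the interaction. It
  is run on the per-stratum *percentage* table, since reporting quality
  is a composition and strata differ in size. A constant table leaves
  only rounding noise in the residual; a scale-relative zero test
  (MS_resid < 10⁻¹²·max(1, mean²)) flags the F statistics as undefined
  rather than reporting noise ratios.
* **Spearman correlation** (`stats::cor.test`, `exact = FALSE`): Pearson
  correlation of mid-ranks with the two-sided t-approximation p-value,
  used to relate the per-journal reporting index (articles reporting sex
  and/or age over articles reporting neither; journals with a zero
  denominator are excluded with a note) to journal metrics.

The test suite cross-checks each of these against independent oracles:
textbook sum-of-squares formulas, a rank-then-Pearson covariance formula,
exact binomial tail enumeration, the closed-form OLS slope, and a
brute-force per-document confusion tally.

## The synthetic corpus generator

`synth_config()` describes a corpus; `generate_corpus()` realizes it
reproducibly under a seed. The defaults are the package's reference study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_docs` | 2000 | large enough for 3-SE recovery tests, small enough for CI runtimes |
| `p_both / p_sex_only / p_age_only / p_none` | 0.45 / 0.10 / 0.25 / 0.20 | about a fifth of articles reporting neither variable, age reported more often than sex, roughly half reporting both |
| `sex_mix` | female 0.49, male 0.36, both 0.15 | female:male odds ≈ 1.36, matching the observed female-majority pattern; both-sex studies are the rarest |
| `age_unit_mix` | day 0.10, week 0.80, month 0.10 | weeks dominate Methods-section age statements |
| `distractor_rate` | 0.15 | hard cases are a minority of documents |
| `group_sex_mix` | male 2.25:1 (cardiovascular), female 3.54:1 (infectious), male 1.57:1 (diabetes), mild female bias in cancer/lung, mild male bias in neurological | encodes the strongest documented group-level biases; the mild values are the package's own choice where no figure is stated |
| `p_second_group` | 0 | a document's sex is drawn from its group's mix, so group-level tallies recover the configured mixes; multi-group membership (nonzero values) dilutes strata by construction and is exercised separately |

Each document is filler prose (a fixed, trigger-free sentence pool — no
external corpus) plus 0–2 informative sentences drawn from an
**in-grammar** template tier guaranteed matchable by the default rules,
plus, at `distractor_rate`, one sentence from the **hard-case** tier:
pregnancy-implied sex, an embryo-crossing sentence, or an open-ended
postnatal age span. Gold annotations reflect only the informative
sentences. The two tiers are kept strictly separate: a template may not
silently straddle them. Informative sex phrases are all longer than the
distractor's bare `male`/`females` tokens, so a distractor can never win
unification in a document that truly reports sex; consequently, with
distractors enabled, sex false positives arise only in embryo-crossing
documents whose gold sex is absent, and age is immune — which is exactly
what the error-class test asserts.

What the generator does **not** emulate: real scientific prose, section
structure beyond a Methods-like block, mention-frequency effects (real
papers repeat sex/age statements), reference lists, tables and captions,
and the long tail of age phrasings outside the template grammar. Perfect
scores on distractor-free synthetic corpora therefore demonstrate
*internal consistency* of rules, unification and scoring — not real-world
recall, which on real corpora is bounded by phrasing variety.

## Numerical and degenerate-input conventions

* Undefined precision/recall/F, bias ratios with no single-sex documents,
  and reporting indices with a zero denominator are signalled (`NA` plus
  a warning or error), never silently 0.
* Age normalization uses the declared 1/7/30-day convention; it is
  monotone and property-tested.
* Truncation to one decimal for presented evaluation metrics; two
  decimals for percentages in analytics tables.
* Corpus loading never silently drops input: every file ends up in the
  documents or in the rejects report (non-UTF-8 and unreadable files are
  rejected with a warning); duplicate document ids are a hard error.
* JATS parsing accepts both full OA-package and front-matter-only
  variants; a missing `<body>` yields an empty text with a warning. Body
  paragraph order is preserved (sentinel-tested); tables and figure
  captions inside the body are included, since no principled exclusion
  rule exists. Reference lists are kept: extraction operates on the whole
  text, which is also why the breeding-cross false-positive class exists.
* Pipeline commands compute everything before writing, and write through
  temp-then-rename, so failures leave no partial outputs.

## Problem sizes used in checks

The shipped test suite uses corpora of up to 2,000 synthetic documents
(extraction perfection, 3-standard-error prevalence recovery) and 4,000
(per-group bias recovery under sex-enriched settings); the acceptance
script uses 6,000, at which the single-sex document count per disease
group (~450) puts the bias-ratio recovery at roughly a 10% standard
error. Ratio estimators are noisy and skewed at small counts — at 2,000
documents a configured 3.54:1 can legitimately realize near 2.3:1 — which
is why bias-recovery checks either enlarge the corpus or widen the
stratum, while prevalence checks use exact 3-SE binomial bounds.

## Known limitations

* Recall on real text is limited by the template-like rule grammar; the
  rule file is editable precisely so users can extend it.
* Sex inference (pregnancy, strain conventions, gonadectomy vocabulary)
  is out of scope by design.
* The both-sexes mixed/separated split is only partially recoverable from
  a single unified mention.
* Month-to-day conversion (30 days) is a convention, not a calendar.
* No mention-level (span-overlap) scoring; evaluation is document-level
  only.
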