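---
title: "Temporal type disambiguation of relative expressions in clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal type disambiguation of relative expressions in clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternr)
```

## The problem and the model

Temporal expression recognition and normalization (TERN) turns the time
phrases of a clinical note into typed, ISO-8601-normalized TIMEX3
annotations. Explicit dates and clock times are largely a parsing problem.
The persistent difficulty is *relative* expressions — "a week ago",
"postoperative day three", "the day of admission" — which must first be
assigned the right temporal **type**: DATE if the phrase names a point in
time, DURATION if it measures a span. Only after that can a normalized
value be computed, so a type error guarantees a value error downstream.

`ternr` implements a pipeline in which a rule/dictionary recognizer emits
fine-grained SCATE-style entities; quantity+unit entities (Period) and
bare-unit entities (Calendar-Interval) — exactly the ambiguous ones — are
routed through a **temporal type disambiguation (TTD)** classifier during
conversion to TimeML. Without a classifier the converter falls back to the
naive rule that types every such entity DURATION; this rule is kept as the
explicit baseline because its failure on relative DATEs is the phenomenon
the classifier exists to fix.

The classifier is a linear SVM over a fixed-length feature vector per
phrase. DATE is the positive class (+1), DURATION the negative (−1).
Features come from contextual subword embeddings resolved in two steps:

1. **Token resolution.** Each whitespace token is represented by its
   *last* subword's embeddings from the *last four* hidden layers,
   concatenated shallowest-first: 4·H dimensions (3,072 at H = 768).
   Averaging or summing subwords are known alternatives; only the
   last-subword rule is implemented.
2. **Phrase features.** *Phrase-Only* is the elementwise mean of the
   phrase's token vectors (4·H). *Phrase+Context* brackets it with the
   means of up to three tokens immediately before and after the phrase in
   the same sentence (12·H = 9,216). A window with no available tokens —
   phrase at a sentence edge, or spanning the whole sentence — is replaced
   by the phrase vector itself; with 1–2 available tokens only those are
   averaged. Windows never cross sentence boundaries.

Assumptions worth stating: the recognizer only emits contiguous spans, so
non-contiguous phrases are rejected at the feature layer; and the layer
order inside the concatenation is a fixed convention (the rules care about
*which* layers, not their order, but a fixed order is required for weights
to transfer between sessions).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| SVM cost `C` | 1, linear kernel | standard soft-margin default; the task is near-linearly separable in embedding space, so the kernel stays linear and `C` is exposed rather than tuned here |
| feature variant | `PhraseOnly` | adding context mostly helps encoders with no clinical pre-training; both variants are first-class |
| context window | 3 tokens each side | the span within which cue words ("prior", "ago", "until") occur |
| hidden size `H` | 768 | the standard base-encoder width; tests also run H ∈ {4, 16} to prove shape-independence |
| approximate quantities | couple = 2, few = 3, several = 3, many = 7 | conventional readings of vague quantity words; a config file, not constants |
| 2-place-date year fill | admission year if within ±183 days, else nearer of admission/discharge years | month/day forms like "01/10" carry no year; the admission date is the natural anchor of a discharge summary, and the window guards against wrapping a December note's "01/10" into the wrong year |
| slash-date order | month-first (`mdy`) | US clinical corpora; `dmy` is a flag |
| `drop_adverbs` | TRUE | bare temporal adverbs ("before", "often") are real temporal signals but unannotated in i2b2-style gold standards; dropping them raises precision without touching recall |
| bootstrap | B ≥ 100, percentile, document resampling | documents are the exchangeable unit in a corpus evaluation |

All lexicons (abbreviations, adverbs, months/weekdays/holidays,
approximate quantities) are plain text files under
`inst/extdata/lexicons/`, deliberately editable: they are approximations
of conventions, not ground truth.

## The SVM implementation

No SVM library is assumed. `ttd_svm()` minimizes the L2-regularized
*squared* hinge loss `0.5‖w‖² + C Σ max(0, 1 − yᵢ(w·xᵢ + b))²` with
L-BFGS from a zero start. The squared hinge makes the objective
differentiable, so a quasi-Newton fit is deterministic — no SGD schedule,
no seed — and for a linear decision rule at moderate `C` it yields the
same verdicts as the standard hinge in practice. The model records the
embedding provider id and seed so a serialized model
(`write_ttd_model()`, JSON) can be re-attached to a reproducible feature
pipeline; predictions refuse features of the wrong variant or dimension.

## Evaluation semantics

Matching is lenient span overlap, resolved greedily one-to-one by maximal
overlap with ties to the earliest system start — "overlap" alone does not
define a matching, so the tie policy is fixed and documented rather than
left to chance. Class-based metrics are computed from a gold × verdict
confusion matrix with an `na` column: an unmatched gold annotation counts
as a false negative for its class, while system-only annotations are
excluded from class metrics entirely (they are span errors, not type
errors). Summaries across DATE and DURATION are weighted by gold support.

Class-based *accuracy* deserves a note: the textbook formula uses true
negatives, which do not exist in a two-class-plus-na confusion. It is
therefore implemented as the agreement rate over matched pairs — an
interpretation, flagged as such.

Value comparison happens after canonicalization (case, whitespace,
leading zeros in duration magnitudes), and value errors are only counted
for pairs whose label is already correct: a mislabeled annotation cannot
have a meaningful value, and counting it twice would double-charge one
mistake.

## The synthetic corpus: what it does and does not establish

`generate_corpus()` produces sectioned discharge summaries (HISTORY /
HOSPITAL COURSE / DISCHARGE INSTRUCTIONS) with admission/discharge
reference dates and a phrase mixture that follows the type proportions of
a clinical TERN evaluation corpus: roughly two thirds DATEs (about 65/35
explicit/relative within them), a fifth DURATIONs, and small
TIME/FREQUENCY/abbreviation shares. Phrase templates are drawn from the
families that make clinical TERN hard: "2 weeks prior to admission",
"postoperative day three", "POD#2", "day of life 4", "the day of
admission", vague quantities ("several days"), dosing abbreviations
("b.i.d."). Every annotation's span slices the note exactly, every value
obeys the ISO grammar, and bookkeeping records each phrase's family and
explicit/relative status — the ground truth the filter tests compare
against. Generation is byte-identical under a fixed seed.
`generate_system_run()` perturbs gold at stated Bernoulli rates (drop /
add / type-flip / value-corrupt) and returns the perturbation log, so
evaluation code is tested against known error compositions.

The mock embedding provider is a pure function of (subword surface,
position, layer) and a seed, with the positional component down-weighted
(×0.1) so a token's lexical identity dominates its vector. Relative DATE
and DURATION templates use different cue vocabularies, which makes the
class signal linearly recoverable — by design: it lets tests verify that
the *feature machinery and classifier* recover a recoverable signal. A
green disambiguation test therefore establishes the correctness of the
pipeline, **not** clinical-grade accuracy: real notes have spelling noise,
section-dependent anchors, genuinely ambiguous phrases ("until 3 days
ago") and annotation disagreement, none of which templates reproduce. The
real-corpus headline numbers are correspondingly not claimed by any test;
the package recomputes reference confusion-matrix arithmetic instead.

Fine-tuning of the embedding encoder is a *contract*:
`finetune_provider()` returns a new deterministic provider derived from
the base provider, the dataset hash and the seed, so sequential
fine-tuning (binary → Seq2Seq) is plain composition and downstream code
is exercised at tiny scale. Training a real transformer is explicitly out
of scope.

## Numerical and degenerate-input choices

* Empty denominators in precision/recall/F1 yield 0, never NaN.
* `segment("")` is an empty list; a document with zero annotations is
  valid everywhere.
* Overlapping recognizer matches resolve longest-first, ties to the
  earlier start, then to the more specific rule family (explicit date >
  2-place date > period > frequency > adverb).
* Phrases that cannot be normalized (a bare month name, a clock time with
  no date) convert with an empty value rather than failing: conversion is
  total.
* Relative phrases judged DATE keep an empty value — anchor-time and
  delta-value resolution is future work, and a wrong guessed value is
  worse than an honest empty one.
* The RelIV explicitness test is rule-based (digit-bearing date forms,
  clock times, month/weekday/holiday names); the boundary it draws is
  documented and testable, but edge phrases a human annotator might judge
  differently will follow the rules, not the annotator.

## Limitations

Beyond the scope cuts above: the recognizer grammar covers the documented
rule families, not the full grammar of a mature tagger; sentence
segmentation is a deterministic rule with an abbreviation guard, adequate
for note-style text but not general prose; and the all-DURATION baseline,
the TTD improvement direction, and every number in the README are
computed by the package's own tests and scripts on synthetic data — no
external corpus results are reproduced or implied.
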