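# ternr — temporal expression recognition and normalization for clinical text

Clinical narratives order events in time mostly through *temporal
expressions*: explicit dates ("2/4/2013"), clock times, durations ("for 3
days"), frequencies ("b.i.d.") and — hardest of all — relative phrases
("2 weeks prior to admission", "postoperative day three") whose calendar
meaning depends on another time or event. Building a patient timeline
requires recognizing these phrases, typing them with the TimeML TIMEX3
scheme (DATE, TIME, DURATION, FREQUENCY) and normalizing their values to
ISO-8601. The recurrent failure mode of rule-based taggers is **temporal
type disambiguation (TTD)**: deciding whether a relative phrase such as "a
week ago" denotes a point in time (DATE) or a span (DURATION). A fixed
rule that maps every quantity+unit phrase to DURATION is wrong whenever
the phrase anchors an event instead of measuring one.

`ternr` is an R toolkit for this task, for clinical-NLP researchers who
need a complete, testable TERN pipeline without access to data-use-
restricted corpora:

* **Recognition** — a rule/dictionary front end producing fine-grained
  SCATE-style entities (Period, Calendar-Interval, explicit/2-place dates,
  frequencies, clinical abbreviations, temporal adverbs).
* **Conversion** — SCATE → TimeML TIMEX3 with ISO-8601 values
  (`iso_duration()`, year filling for 2-place dates, approximate
  quantities flagged `APPROX`).
* **Disambiguation** — a linear SVM over phrase features built from
  per-subword, per-layer contextual embeddings: each whitespace token is
  the last-4-layer concatenation of its last subword (4·H dims, 3,072 at
  H = 768); a phrase is the mean of its token vectors (Phrase-Only), or
  that mean bracketed by up-to-3-token context window means
  (Phrase+Context, 12·H = 9,216). DATE is the positive class:
  sign(w·x + b) ∈ {+1 → DATE, −1 → DURATION}.
* **Filters and evaluation** — DD-TIMEX (DATE+DURATION only) and
  RelIV-TIMEX (relative/implicit/vague) corpus filters; lenient
  span-overlap matching; class-based precision/recall/F1 with unmatched
  gold counted as false negatives and gold-support weighted averages

  `weighted(s) = (s_DATE·w_DATE + s_DURATION·w_DURATION) / (w_DATE + w_DURATION)`;

  error-category analysis (value/label/missed/added), difficult-file
  selection, and percentile bootstrap confidence intervals over documents.
* **Synthetic corpus** — a deterministic generator of sectioned discharge
  summaries with gold standoff annotations and full bookkeeping, so every
  stage is exercised end to end by plain `R CMD check`-able tests.

## Worked example

```r
library(ternr)

# generate a synthetic annotated corpus of discharge summaries
corpus <- generate_corpus(generator_config(n_documents = 20, seed = 42))

# train the DATE/DURATION disambiguator on mock-embedding phrase features
provider <- mock_provider(seed = 7, hidden_size = 64)
train <- ttd_training_data(corpus$documents, provider, "PhraseOnly")
model <- ttd_svm(train$features, train$labels, provider_id = provider$id)
model
#> <ttd_svm> linear SVM, 256-dim PhraseOnly features, C = 1, 150 training phrases
#>   provider: mock-h64-l12-s7

# annotate with the naive all-DURATION rule vs. with the TTD model
naive <- annotate_corpus(corpus$documents)
ttd <- annotate_corpus(corpus$documents,
                       conv_config = conversion_config(ttd_model = model),
                       provider = provider)
round(rbind(naive = run_phase("end2end", corpus$documents, naive),
            with_ttd = run_phase("end2end", corpus$documents, ttd)), 3)
#>          precision recall f1 type_accuracy value_accuracy
#> naive            1      1  1         0.793          0.793
#> with_ttd         1      1  1         1.000          1.000
```

Span precision/recall/F1 are identical in both rows — the TTD module only
re-types phrases, it never moves spans — while type accuracy rises because
relative DATE phrases ("2 weeks prior to admission", "POD#2") are no
longer forced to DURATION. The numbers are optimistic in the way a
training-set demo always is: the model was trained on the same synthetic
corpus it annotates here (the test suite does proper held-out splits), and
synthetic phrases are far more regular than real clinical text.

The class-based view on the relative/implicit/vague subset:

```r
phase2 <- run_phase("system-timex", corpus$documents, ttd)
phase2$confusion
#>          DATE DURATION na
#> DATE       35        0  0
#> DURATION    0       36  0
round(phase2$metrics$weighted, 3)
#> precision    recall        f1
#>         1         1         1
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, with the installed package, the gold-support weighted
class-based precision/recall/F1 from the two reference DATE/DURATION
confusion matrices shipped in `inst/extdata/reported_confusions.csv`
(a TTD-integrated hybrid recognizer and the MSRA hybrid system, both
evaluated on a relative-expression subset with unmatched gold in the `na`
column), after first running the synthetic pipeline end to end. Results go
to `--out` as JSON.

## Command line

`inst/cli/tern.R` is a thin Rscript over the exported functions with
subcommands `synth`, `annotate`, `filter-dd`, `filter-reliv`, `restrict`,
`train-ttd` and `evaluate` (exit codes: 0 ok, 2 config error, 3
validation error).

## Scope

Anchor-time and delta-value resolution for relative DATEs (placing "2
weeks prior to admission" on the calendar) is intentionally out of scope;
relative DATE values are emitted empty. FREQUENCY values are normalized
only for lexicon abbreviations. See `vignettes/temporal-disambiguation.Rmd`
for the design rationale, parameter defaults and limitations.
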