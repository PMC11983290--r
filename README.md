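# abcscore

Rule-based clinical NLP for identifying problematic opioid use in
electronic health record (EHR) notes. `abcscore` automates the 20-item
**Addiction Behaviors Checklist (ABC)** — a clinician-completed instrument
for aberrant opioid-related behaviors in chronic-pain patients — by turning
each item into a small set of regular expressions with clinically motivated
filters, scoring patients over their whole note history, and evaluating the
result against manual chart-review labels and an ICD diagnosis-code
baseline.

It is aimed at EHR phenotyping and health-services researchers who need an
*interpretable* alternative to ICD codes (notoriously insensitive for
opioid use disorder) and to black-box text classifiers: every point a
patient scores is traceable to a concrete text span, its sentence, and the
filter decisions that let it survive.

## Method

For each ABC item *i* and each sentence of each note, a hit survives a
four-stage chain:

1. **core expression** — a case-insensitive regular expression for the
   item's concept (e.g. variations of *hoard*, *stash*, *stockpil* for the
   hoarding item);
2. **opioid-context filter** — the sentence must also contain an opioid
   term or drug name (for the hoarding item the opioid term must *follow*
   the trigger);
3. **negation exclusion** — no negating term (*denies*, *no*, *not*,
   *without*, ...) may precede the trigger within the sentence;
4. **false-positive prefix exclusion** — hits preceded in the note by a
   section header such as *"discharge instructions"* are dropped.

A patient's item flag is `1` when at least one surviving match exists in
any in-window note; the total score is

```
S_p = sum_i 1[ item i matched for patient p ],   S_p in 0..20
```

and the binary indicator is `S_p >= tau` (the operating threshold `tau` is
chosen by an F1 sweep and is expected to differ between sites). The
evaluation battery provides sensitivity, specificity, PPV, NPV, F1
(harmonic mean of PPV and sensitivity), the tie-corrected rank AUC
(`P(S_case > S_control) + 1/2 P(tie)`; for a binary predictor this equals
`(sensitivity + specificity)/2`), recall-precision curves, pairwise item
phi coefficients

```
phi = (n11 n00 - n10 n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00))
```

patient-level percentile-bootstrap confidence intervals, and prevalence of
a diagnosis-code indicator stratified by total score.

The published instrument's exact lexicons and 27 expressions are not
public; the packaged pattern configuration (`abc_patterns()`,
`inst/extdata/abc_patterns.yaml`) is a clearly labeled reconstruction and
fully replaceable via `load_pattern_config()`. A synthetic corpus
generator (`simulate_corpus()`) plants template mentions, negated
mentions, decoys and discharge-header decoys with exactly known ground
truth, so the whole pipeline is testable without any protected data.

## Worked example

```r
library(abcscore)

corpus <- simulate_corpus(sim_config(n_patients = 100, seed = 11))
res <- run_pipeline(corpus$notes, labels = corpus$labels,
                    diagnoses = corpus$diagnoses, threshold = 2,
                    patients = corpus$patients$patient_id,
                    bootstrap_B = 500, seed = 7)
#> stage match: 444 notes against 20 items
#> stage match: 175 surviving matches
#> stage score: 100 patients scored (3 without notes)
#> stage evaluate: n=97, F1=0.696, AUC=0.674
#> stage evaluate: ICD baseline AUC=0.56

res$evaluation$metrics
#> # A tibble: 5 × 4
#>   metric      estimate ci_low ci_high
#> 1 sensitivity    0.672  0.558   0.777
#> 2 specificity    0.615  0.443   0.767
#> 3 ppv            0.722  0.603   0.852
#> 4 npv            0.558  0.413   0.703
#> 5 f1             0.696  0.596   0.780

head(res$matches[, c("patient_id", "item_id", "matched_text")], 3)
#>   patient_id item_id matched_text
#> 1 P0001           15 noncompliant
#> 2 P0001           12 prescription was stolen
#> 3 P0002            9 sedated
```

Here 97 of 100 simulated patients had notes and entered evaluation; at a
threshold of 2 the automated checklist reaches F1 0.70 against the
simulated adjudication labels, while the 2-distinct-day ICD-code baseline
manages only AUC 0.56 — the qualitative gap the instrument is designed to
expose. Each match row is an audit record: the matched span, its sentence
and the filter trail explain *why* the patient scored.

A command-line wrapper with `cohort`, `match`, `score`, `evaluate`,
`simulate` and `run` subcommands is installed as `exec/abc-autoscore`.

## Package layout

- `R/corpus-io.R` — note/diagnosis/label readers, cohort builder
- `R/pattern-config.R`, `inst/extdata/abc_patterns.yaml` — pattern set
- `R/pattern-engine.R` — sentence segmentation and the four-stage matcher
- `R/abc-scoring.R` — patient-level scoring, classification, F1 sweep
- `R/evaluation.R` — metrics, curves, phi, ICD baseline, bootstrap
- `R/synthetic-notes.R` — corpus generator and template bank
- `R/pipeline.R` — `run_pipeline()` orchestration and output writers
- `vignettes/abc-automation.Rmd` — the methods vignette
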