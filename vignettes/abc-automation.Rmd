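---
title: "Automating the Addiction Behaviors Checklist: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automating the Addiction Behaviors Checklist: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcscore)
```

## The problem and the model

Opioid use disorder (OUD) is badly under-captured by diagnosis codes:
stigma and billing practice make ICD-based OUD phenotypes insensitive even
when precise. Clinical notes, by contrast, routinely document the aberrant
behaviors clinicians observe — running out of medication early, requesting
early refills, obtaining prescriptions from several providers. The
Addiction Behaviors Checklist (ABC) is a validated 20-item instrument that
structures exactly those observations, which makes it a natural target for
automation: each item can be expressed as text patterns over the notes a
clinician would otherwise read.

`abcscore` implements that automation as a deliberately *interpretable*
rule pipeline rather than a statistical classifier. For every item, every
sentence of every note passes through four stages:

1. **Core expression.** One or more case-insensitive regular expressions
   capture the item's concept. The packaged set has 27 expressions across
   the 20 items.
2. **Opioid context.** For items whose trigger words are not intrinsically
   opioid-specific (hoarding, running out early, early refills, ...), the
   sentence must also contain an entry of the opioid lexicon — term stems
   such as `pain med`, `narc`, `analges` (including intentional
   misspellings like `opiod` that occur in real notes) or a drug name. Two
   items additionally require the opioid term to *follow* the trigger
   (`trigger_before_term`), matching the "followed by" phrasing of the
   hoarding rule.
3. **Negation.** A hit is discarded when a negation term (`denies`,
   `denied`, `no`, `not`, `without`, `never`, `negative for`) occurs in
   the same sentence strictly before the trigger. Terms match as whole
   words, so `not` never fires inside `cannot` and `no` never inside
   `noted`.
4. **Prefix exclusion.** Hits preceded anywhere in the note by a
   false-positive header phrase — by default `discharge instructions` —
   are discarded. This scan is note-wide, not sentence-wide, because such
   phrases are section headers that govern everything after them.

A patient's item flag is true when at least one surviving match exists in
any in-window note; multiplicity is deliberately ignored (the instrument
is a checklist, not a count of mentions). The total score is the number of
flagged items, and the binary OUD indicator is `total_score >= tau`.

Every surviving match is an audit record carrying its character span
(0-based, half-open), the matched text, the containing sentence and a
filter trail (`core=pass;opioid_context=pass;...`). `matched_text` always
equals the note-text slice at the span — an invariant that is
property-tested — so a reviewer can always reconstruct why a patient
scored.

## Cohort and time-window rules

The chronic-pain cohort rule requires qualifying ICD codes on at least two
*distinct calendar dates* (one repeated-day code is treated as possibly
spurious), and age of at least 13 completed years at the earliest
qualifying code. Two interpretation choices were open and are resolved as
follows: "different days" means distinct dates after truncating any time
component, and patients with qualifying codes but no recorded birth date
are excluded with a warning rather than assumed adult — the conservative
reading. Only four chronic-pain codes are shipped as the default
(`338.2`, `338.21`, `G89.2`, `G89.21`); the full institutional list behind
the original cohort is not public and is not guessed at. Users supply
their own code sets.

Scoring accepts an optional cutoff date (`cutoff_date`), mirroring
consent-anchored designs where only notes up to each patient's consent
date may be used; notes with date-only timestamps are admitted since the
cutoff needs only calendar dates.

## Threshold selection and evaluation

The operating threshold is chosen by sweeping every `tau` in 0..20 and
maximizing F1 — the harmonic mean of PPV (precision) and sensitivity
(recall) — which operationalizes "best balance between sensitivity and
positive predictive value". Ties break to the smallest `tau`, favoring
sensitivity. The full sweep table is always returned; thresholds with no
positive calls have undefined precision and cannot win. Different sites
should expect different optimal thresholds: documentation volume and style
shift the score distribution, so the sweep is part of the deployment
procedure, not a one-time constant.

The evaluation battery follows standard phenotyping practice:

- **Confusion metrics** with the convention that a zero-denominator metric
  is `NA`, never silently 0. F1 is 0 when there are positives but no true
  positives, `NA` when precision itself is undefined.
- **Rank AUC**: the tie-corrected Mann-Whitney statistic
  `P(S_case > S_control) + 1/2 P(tie)`, computed from midranks. For
  integer scores the ROC curve enumerates every achievable threshold
  rather than interpolating, so the rank and trapezoidal formulations
  coincide; for a binary predictor the statistic collapses exactly to
  `(sensitivity + specificity)/2`, which is how the diagnosis-code
  baseline's AUC is computed.
- **Recall-precision curves**, one point per achievable threshold, with
  undefined-precision points omitted.
- **Pairwise phi coefficients** between item flags — the Pearson
  correlation of binary variables, computed from the 2x2 cell counts.
  Zero-variance items give flagged-undefined cells (`NA`) rather than an
  imputed value.
- **Bootstrap confidence intervals**: nonparametric patient-level
  resampling with percentile 2.5/97.5 bounds, default `B = 2000`, seed
  mandatory and recorded in outputs. The published-style CIs do not name
  an estimator; the percentile bootstrap was chosen as the assumption-free
  default. Resamples on which a statistic is undefined (e.g. a resample
  with no cases) are redrawn and counted. Empirical coverage for
  sensitivity is verified in the test suite: about 95% over 500 simulated
  replicates of 200 patients at `B = 200`.
- **ICD baseline and score stratification**: the code indicator uses the
  same 2-distinct-day logic as the cohort rule, and
  `stratify_by_score()` reports its prevalence per total-score level —
  the gradient one expects if the score tracks true OUD burden.

## The synthetic corpus generator

`simulate_corpus()` exists so that the entire pipeline is exercisable and
testable without any protected health information. Per patient it draws a
heavy-tailed (negative binomial) number of notes — emulating the strongly
right-skewed note counts of real EHR cohorts, at desk scale (default mean
4 rather than hundreds) — and plants, per item:

- a **positive** template sentence with probability `p_mention[i]`
  (defaults concentrate mass on the general-addiction and
  analgesic-discussion items, the behaviors most often documented, with
  modest rates elsewhere);
- a **negated** template (negation term before the trigger) with
  probability `negated_mention_rate` (default 0.15);
- a **non-opioid decoy** (same trigger, non-opioid object) with
  probability `non_opioid_decoy_rate` (default 0.10);
- with probability `discharge_decoy_rate` (default 0.10), a dedicated
  discharge-instructions decoy note. Discharge decoys live in their own
  notes by design: the prefix filter is note-wide, so a header inside a
  regular note would also (correctly) suppress genuine mentions after it
  and make the planted truth ambiguous.

Labels follow a logistic link `P(case) = plogis(-1.0 + 0.8 * total)`,
giving roughly the case prevalence of adjudicated chronic-pain test sets
at the default mention rates; case/control status then drives emission of
a 2-distinct-day OUD code (12% vs 1%), plus occasional single-day codes
that exercise the distinct-day rule. A small fraction of patients (2%)
have no notes at all, mirroring real cohorts; they carry a `no_notes_flag`
and are excluded from evaluation by default (an `include_no_notes` switch
scores them as 0).

Every template is engineered — and regression-tested — to interact with
exactly one item of the packaged pattern set: positives survive for their
item only, negated/decoy/discharge templates survive nowhere, and filler
boilerplate matches nothing. Ground truth is therefore exact by
construction, and the generator/engine consistency check
(`end_to_end_check()`) demands 100% recovery of planted flags. A
`hard_mode` flag plants paraphrases *outside* the expression set
(squirreling away tablets, getting hooked on the pills) to create known
false negatives for benchmarking; hard-mode corpora are excluded from the
exact-recovery property.

What passing these tests shows — and what it does not: exact recovery
demonstrates that the matcher implements its specification faithfully
(filters fire when and only when they should), not that the reconstructed
expressions capture the variety of real clinical language. Real notes
contain paraphrases, typos, copy-forward artifacts and section structures
the template bank deliberately does not model; site-specific review of
match audits remains essential before any substantive use.

## Numerical and implementation choices

- **Sentence segmentation** splits at `.`, `!`, `?` runs followed by
  whitespace and at newline runs, with a short abbreviation stop-list
  (`Dr.`, `mg.`, `e.g.`, ...). Spans are trimmed and partition the
  non-whitespace text; all filters operate within one sentence (matching
  is performed per sentence slice, so gap patterns cannot leak across
  boundaries).
- **Offsets** are 0-based half-open everywhere in the public interface,
  converted internally from R's 1-based strings.
- **Negation window** is the whole sentence before the trigger ("preceding"
  with no stated token distance); **opioid order** `trigger_before_term`
  requires the term to begin at or after the trigger's end.
- **Determinism**: matching is pure; the generator and all bootstrap
  routines take mandatory seeds and restore the caller's RNG state;
  re-running the pipeline on identical inputs reproduces byte-identical
  CSV/JSON outputs (the manifest records input digests, the pattern-config
  digest, seed and tool version).
- **Duplicate hits** from multiple expressions of one item at identical
  spans are collapsed; distinct spans are kept as separate audit records.
- **Problem sizes** used throughout tests and examples — 200-patient
  corpora, `B = 200`-500 bootstrap resamples, 100-repetition oracle
  loops — were chosen as the smallest sizes at which the checked
  properties are non-trivial; defaults for real use are larger
  (`B = 2000`).

## Known limitations

- The packaged lexicons and expressions are reconstructions from the
  instrument's published item concepts and the documented examples, not
  the original instrument's exact set; per-item filter assignments beyond
  the documented hoarding walkthrough are defaults, all overridable in
  the YAML config.
- Negation handling is positional within a sentence; scoped constructs
  ("cannot rule out", conditional instructions) are not modeled.
- The ABC was developed for chronic-pain patients prescribed opioids; the
  automation inherits that scope and says nothing about OUD acquired
  outside prescription contexts.
- The generator's realism is structural (multi-note patients, decoys,
  heavy-tailed volumes), not linguistic; it must not be used to estimate
  real-world operating characteristics.
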