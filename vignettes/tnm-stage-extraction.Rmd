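---
title: "Patient-level TNM stage extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-level TNM stage extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmstager)
```

## The problem

Cancer stage drives prognosis and treatment choice, yet registries and
EHR structured fields are missing stage for a large fraction of prostate
cancer patients even when the staging evidence sits in plain sight inside
free-text notes: an operative note may say "Staging: cT2aN0M0", a pathology
report may describe "extracapsular extension", a progress note may say
"he has t3a prostate cancer" without saying whether that is a clinical or a
pathological stage. `tnmstager` extracts **patient-level, dichotomized**
clinical and pathological TNM stage from such text and uses the extractions
to fill (never overwrite) missing registry fields.

Five binary tasks are exposed, following the AJCC 7th-edition prostate
conventions and the usual dichotomization used when raw stage categories are
too imbalanced to model individually:

| task | categories | abstracted from |
|------|------------|-----------------|
| cT   | T1-2 vs T3-4 | operative, history & physical, discharge/transfer, progress notes |
| cN   | N0 vs N1     | same |
| cM   | M0 vs M1     | same |
| pT   | T2 vs T3-4   | pathology, history & physical, progress notes |
| pN   | N0 vs N1     | same |

Pathological M is deliberately unsupported: pathological M1 is vanishingly
rare in a prostatectomy population, so no meaningful binary task exists;
`dichotomize("pathological", "M", …)` raises an error rather than inventing
one. Overall-stage phrases ("stage 1 prostate cancer") are recorded as
mentions but never converted to TNM values — they are an ambiguity source,
not a signal, because the stage-group mapping depends on information
(grade, PSA) the phrase does not carry.

## The rule-based engine

**Compact pattern grammar.** One regular grammar recognizes an optional
kind prefix (`c`, `p`, or `yp`, case-insensitive) followed by any non-empty
in-order subset of `T<digit><a–c>?`, `N<digit>`, `M<digit>`, contiguous or
whitespace-separated. The prefix distributes over all components of one
pattern. Out-of-range numerals (`T5`, `N4`, `M2`) produce *no* mention:
silence is safer than a guess. Prefix-less patterns are flagged
`ambiguous`, since the writer did not say which staging they meant.

**Narrative lexicon.** A curated target-term lexicon (bundled,
plain-text, user-replaceable; 114 entries of which 69 carry a mapped stage
value) translates guideline criteria and common synonyms into axis/value
pairs — "extracapsular extension" is T3, "lymph node involvement" is N1,
"organ confined" is pathological T2, and so on. Matching is
case-insensitive, longest-match-wins at word boundaries, with
non-overlapping spans. Terms may carry a stage-kind hint (e.g. "organ
confined" is a specimen description) that acts as a soft prefix. Which
terms carry values and which merely anchor context is configurable per
entry; anchor terms produce no mentions.

**Contextual flags.** A ConText-style pass assigns `negated`,
`historical`, `hypothetical` and `experiencer_other` flags. Each trigger
("no evidence of", "history of", "if", "family history of", …) opens a
scope in its direction, bounded by the sentence boundary, the nearest
termination trigger ("but", "however", …) or the next trigger of the same
type; pseudo-triggers ("no increase", "history of present illness") consume
their text and open nothing. Trigger matching is longest-match, so "family
history of" wins over "history of" and yields an experiencer flag, not a
historical one.

**Patient-level resolution.** The aggregation from mentions to one value
per patient and axis is where most design freedom lies, and we made the
following choices:

1. Negated, hypothetical and other-experiencer mentions are discarded.
   **Historical mentions are retained**: a stage assigned in the past is
   still the stage at diagnosis; discarding them would throw away exactly
   the re-statements long records are full of.
2. Mentions are routed to a stage kind by prefix; unspecified prefixes are
   resolved by note type (pathology report → pathological, otherwise
   clinical). This mirrors how clinicians disambiguate the same phrases.
3. Among survivors the **modal numeral** wins; ties go to the **most
   recent** mention (later date; dateless notes sort last and count most
   recent; remaining ties broken by note id, sentence index and character
   offset, so resolution is deterministic and invariant to input order).
   The mode resists transcription noise; recency reflects staging
   refinement over time.
4. If only negated evidence exists on a **binary** axis, the complementary
   benign value is asserted: "no evidence of distant metastasis" with no
   positive M mention yields M0. This is never done for T (negating one T
   value does not imply another) and the provenance records
   `from_negation = TRUE` so downstream users can drop these if they
   disagree with the convention.
5. Clinical mentions are taken from the full longitudinal record, not only
   pre-treatment notes; no time-windowing is applied.

Clinical staging draws only on operative, history & physical,
discharge/transfer and progress notes; pathological staging only on
pathology, history & physical and progress notes. Radiology reports and
unknown note types pass neither filter — conservative, and it keeps an
imaging impression from silently becoming a stage assignment.

## Pre-processing

The rule engine runs on **raw** sentence text: punctuation and short tokens
("pT1N2M0.", "t3a") are staging-bearing, so normalization would destroy the
signal. Normalization feeds only the ML arm: lowercase; punctuation-only
tokens dropped; single-letter alphabetic tokens dropped (we read "words
shorter than two letters" as alphabetic-only, because mixed alphanumerics
like `t2a` carry staging signal and are preserved intact); integers 0–20
map to single number words and larger integers and all decimals are spelled
digit-wise ("4.5" → `four point five`), so every spelled number parses back
to its numeral. Sentence splitting is rule-based with a fixed clinical
abbreviation list ("Dr.", "vs.", …) — deterministic, no learned model, for
reproducibility; spans are exact offsets into the note so every sentence
can be traced back to its source.

## The ML arm

**Embeddings.** Token embeddings (dimension 100, symmetric window 5,
minimum count 2) are computed as a truncated SVD of the positive pointwise
mutual information (PPMI) co-occurrence matrix, i.e. the count-based
closed form of skip-gram-with-negative-sampling training. We chose the
closed form deliberately: it is exactly reproducible (no sampling, no
thread nondeterminism), fast at clinical-corpus vocabulary sizes, and its
sign convention is fixed (largest-magnitude loading positive per
component), so identical corpora give byte-identical vectors. When the
vocabulary supports fewer than 100 informative components the remaining
dimensions are zero, keeping the vector length contract.

**Patient vectors.** For each task, the keyword-bearing sentences in the
task-appropriate note subset are the patient's *context*: a sentence
counts if it contains a value-bearing target term of the task's axis or a
compact pattern component on that axis. Each context sentence is the mean
of its in-vocabulary token vectors, and the patient vector is the mean
over context sentences — so it is invariant to sentence order and to
duplicated non-context text, and its norm never exceeds the largest token
norm. Anchor-only terms are excluded from the keyword set by default
(`include_anchors = FALSE`): anchors fire on boilerplate ("bone scan",
"lymph nodes") and mostly dilute the class signal. A patient with no
context sentence is *degenerate*: zero vector, excluded from training,
and an **abstention** at prediction time — imputation accounting must
distinguish "no evidence" from "predicted".

**Classifiers.** One binary SVM per task over patient vectors. Data are
split stratified 80/20 (stratification is our addition — N1 prevalence is
~3%, and an unstratified split regularly loses the minority class from one
partition); 50 random hyperparameter draws (kernel linear/RBF, cost
log-uniform on [1e-2, 1e2], RBF bandwidth log-uniform on [1e-3, 1e1],
optional balanced class weights) are scored by mean macro-F1 over
stratified 5-fold cross-validation on the training portion; the winner is
refit and held-out metrics reported. Everything is seed-controlled, and a
fold whose training part degenerates to one class scores NA and is
ignored. One embedding model is shared per stage kind; one keyword subset
is used per axis (whether one global set would match the original design
is unknowable from the description; axis subsets are the conservative
reading).

## The synthetic corpus generator

Institutional clinical text cannot be shared, so the generator is a
first-class module that emulates the statistical structure the extractors
rely on: per-patient longitudinal, date-ordered, typed notes (history &
physical first; progress, radiology, discharge notes after; operative and
pathology reports for the ~33% of patients who undergo prostatectomy);
stage-bearing sentences rendered from a plain-text template bank in
compact, narrative or ambiguous style; contextual noise (negated benign
findings, historical re-statements of the true stage, hypothetical
discussions, overall-stage phrases) at configurable rates; distractor
sentences (labs, medications) so matching is exercised against negatives;
and a registry table with missingness **independent** of note
documentation, so some missing registry fields are recoverable from text
and some are not — making imputation a nontrivial measurement.

Default marginals encode the stage distribution of a large US academic
prostate-cancer cohort: cT1 44%, cT2 19%, cT3 3%, cT4 1% (33% truly
unstaged); cN0 61%, cN1 3%; cM0 62%, cM1 5%; prostatectomy fraction 33%
with pT2 51% and pT3–4 30% — split as pT3 25% / pT4 5%, since pT4 disease
is rare in surgical series and the source marginal does not separate them.
Noise defaults (10% negation, 5% historical, 5% hypothetical, 10%
ambiguous phrasing, 50% compact rendering, 15% missing documentation, 25%
independent registry blanking) were fixed once as plausible clinical
documentation rates.

**What passing tests do and do not show.** The generator's language is by
construction fully covered by the bundled lexicon and grammar, so the rule
engine achieves near-perfect synthetic F1 — an upper bound that says the
pipeline wiring is correct, *not* that real-world F1 would be comparable;
real notes contain phrasings no lexicon anticipates. Conversely, compact
shorthand tokens (`ct1`, `ct3`) are distributionally interchangeable, so
context-based embeddings cannot separate them — a real property of
distributional semantics, which is why the ML arm's parameter-recovery
check uses narrative-only rendering (the "planted class-specific keyword
sentences" condition) and why, on corpora with rare minorities and
ambiguity noise, the rule engine's minority-class F1 dominates the ML
arm's. That ordering structurally mirrors what one expects on real data
for T and N staging; the generator does not attempt to reproduce the
settings where ML wins (e.g. highly variable metastasis phrasing beyond
any lexicon).

## Numerical and degenerate-input conventions

* Zero-denominator precision/recall/F1 are `NA` ("undefined-marked"),
  never silently 0; abstentions are excluded pairwise from scoring but
  always counted, so denominators stay visible.
* Cohen's kappa is computed per task on the dichotomized categories and is
  `NA` when either labeling is constant over the paired data.
* Imputation writes only empty registry cells, marks provenance per cell,
  counts conflicts with populated cells separately, and is idempotent.
* Unknown note types map to `other` and pass neither stage-kind filter.
* A "patient encounter" is equated with a note for the minimum-encounter
  cohort filter (the two are not distinguishable in a note-level corpus).
* Malformed corpus rows are rejected with line numbers, never silently
  dropped.

## Problem sizes used by the test and acceptance suites

The shipped checks run at sizes chosen to make the statistics meaningful
at desk scale: exact-recovery on a noise-free corpus of 200 patients;
simulator fidelity (±2 percentage points on every configured category
fraction) at 10,000 patients; ML parameter recovery at 1,000 patients
with the full 50-draw search; the rule-vs-ML minority comparison as a
3-seed median at 600 patients. `scripts/acceptance.R` recomputes all of
these from scratch under a caller-supplied seed.

## Known limitations

* AJCC 7th-edition semantics only; no stage-group (I–IV) assignment, no
  Gleason or PSA extraction, no cross-sentence coreference.
* The bundled lexicon is a functional stand-in curated from staging
  guidelines and common synonyms, not a site-validated dictionary; users
  with institutional term lists should load their own
  (`load_lexicon(targets, modifiers)`).
* Patient-level resolution has no access to treatment timelines, so a
  post-treatment clinical re-statement can outvote a pre-treatment one.
* The ML arm deliberately uses sentence-averaged static embeddings; it is
  a baseline architecture, not a contextual language model.
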