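---
title: "Rule-based preprocessing and multilabel classification for ICD-10 coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based preprocessing and multilabel classification for ICD-10 coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoicd)
```

# The coding problem

Hospital disease coders read a discharge summary and assign a variable-size
set of ICD-10-CM diagnosis codes and ICD-10-PCS procedure codes — typically
1 to 20 codes per hospitalization drawn from label spaces of thousands.
Treated as machine learning, this is extreme multilabel text
classification, and it is hard for exactly the reasons coders find it
slow: the evidence for a code is scattered across heterogeneous sections
of the summary, much of the text is uninformative for coding, and coding
*rules* (not just surface text) decide which code is correct.

`autoicd` implements a coding pipeline in which a pluggable multilabel
classifier is wrapped in rule-based preprocessing that encodes what
coders actually do. The five input sections are:

* **DD** — discharge diagnoses: the principal diagnoses, short and dense.
* **SM** — surgical method: procedure descriptions, present only when a
  major procedure was performed.
* **SE** — special examination: ultrasound, radiology, endoscopy and EEG
  reports; long, and mostly without procedure-code consequences.
* **MH** — medical history: long narrative; the usual place where chronic
  diseases (hypertension, chronic kidney disease) are mentioned when the
  DD omits them.
* **CC** — comorbidity and complication: empty for uncomplicated stays,
  decisive when present.

# Pipeline stages

## Common cleaning

`clean_text()` replaces punctuation with spaces (so `"infection,site"`
cannot fuse into one token), strips characters outside basic Latin
letters/digits/space (bilingual records interleave non-Latin names of
people, places and transfer hospitals, which carry no coding signal),
collapses whitespace and lowercases. `drop_null_and_duplicates()` removes
documents that are empty after cleaning and exact section-tuple
duplicates.

## Essential-number conversion

Most numerals in a record (dates, lab values, line headers) are noise, but
a few are decisive: disease *type* (type 1 vs type 2 diabetes), *stage*
(chronic kidney disease stage 1 vs 4), *grade*, pregnancy *weeks*, and
clinical *scales*. `convert_numbers()` first rewrites the configured
essential patterns with the number in English words ("stage 4" → "stage
four") and then deletes every remaining token containing a digit. The
output is digit-free and the operation is idempotent. The pattern table is
deliberately small and user-extensible (`{n}` marks the integer slot;
`{w}` receives the number word) because the set of "known essential
numbers" is a curated clinical artifact, not a closed list. Roman-numeral
grades ("grade II") contain no digits and pass through untouched; no
normalization between "grade 2" and "grade II" is attempted.

## Keyword extraction (MH and SE)

The MH narrative is about five times the length of the DD, and the SE is
about three times; concatenating them whole would bury the signal and
overflow any bounded-input encoder. Instead, curated keyword rules map
pre-cleaned phrases to codes, and only matched phrases are kept:
whole-phrase matches at word boundaries, longest phrase first (so
"chronic kidney insufficiency" beats "kidney insufficiency"),
deduplicated, in first-occurrence order. The shipped tables are
illustrative starters; production tables are curated with disease coders.

## Combination-code filter

Coding rules demand a single *combination code* where a diagnosis and
specific comorbidities co-occur: hypertension together with chronic kidney
disease and heart failure is one code (I13.0), not three. A classifier
trained on surface text will happily emit the three component codes.
`apply_combination_filter()` checks, for each rule, that the trigger
phrase and at least one alternative from every companion group are
present; if so it deletes those mentions and inserts the combination
code's definition at the trigger's position. Only the matched spans are
rewritten — the rest of the document remains as evidence for its other
codes (the alternative reading, replacing the entire document text, would
destroy that evidence). The label set is never touched by this transform.

## External-cause label removal

Codes V01–Y98 describe the circumstances of injuries. They are rarely
supported by discharge-summary text and do not affect disease-related-group
payment, so `remove_external_cause_codes()` drops them from the gold label
sets — in both training and evaluation splits, since a label that cannot
be predicted from the text only adds irreducible false negatives.
Membership is decided lexicographically on the 3-character category.

## Definition pretraining

Record phrasing approximates, but differs from, the official code
definitions. `build_definition_pairs()` turns a definition table into
single-label training examples ("urinary tract infection site not
specified" → N39.0), and `pretrain_on_definitions()` fits the classifier
on them before the corpus phase (strictly sequential, not mixed).

## Section-combination strategies for procedures

For ICD-10-PCS, five input compositions are supported
(`pcs_strategies()`): DD only; SM only; SM with DD fallback; SM plus SE
keywords with DD fallback; and SM plus SE keywords with DD-plus-SE-keywords
fallback. SE always enters via the keyword extractor, never as full text.
SE keywords are appended after the primary section in first-occurrence
order (the source design does not fix this order; appending is this
package's convention).

# The classifier

## Desk backend

The default backend is a bag-of-words, independent-per-label linear model
with sigmoid outputs: a document is a binary term-presence vector, and
each code has a weight vector and bias. The loss is the sum over labels of
binary cross-entropies, averaged over documents — the standard multilabel
reading of cross-entropy against one-hot label sets. Optimization is
full-batch Adam (learning rate 0.1, at most 100 epochs) with early
stopping when the monitored loss changes by less than `1e-4` for 10
consecutive epochs. An L2 penalty (`l2 = 1e-3`) on the feature weights —
the standard regularizer for one-vs-rest logistic scorers — is essential
at desk scale: without it the model memorizes co-occurring filler tokens
and generalizes poorly. Weights start at zero, so training is
deterministic given (data, config); the seed is recorded in provenance
and scopes any stochastic component.

Two transfer details matter for the definition warm start:

* the definition task is *single-label*, so the negative between-code
  evidence it learns (every other code's definition head scores against a
  label) is an artifact that does not hold for multi-code records — only
  the nonnegative weights are carried into the corpus phase, and the bias
  is re-estimated under the corpus label prior;
* features with zero support in a phase keep their starting weights
  rather than being decayed, so definition knowledge attached to tokens
  the corpus never shows survives fine-tuning.

## Contextual backend

The `CONTEXTUAL` backend realizes the same head over a user-supplied
encoder: texts are truncated to `max_tokens` (default 512), the encoder
returns one pooled representation per text, and the linear layer, loss,
Adam optimizer (default learning rate 5e-5) and early-stop contract are
unchanged. The encoder is pluggable because the package ships no
pretrained transformer weights; everything downstream (prediction,
thresholding, evaluation, ablation) is backend-agnostic.

## Score-to-set conversion

Published systems report set-valued predictions without stating a
thresholding rule; here a label is predicted iff its sigmoid score is at
least `threshold` (default 0.5, exposed in `train_config()`), which makes
predicted sets monotone shrinking in the threshold.

# Evaluation

Micro-averaging pools every document-label cell before computing
precision (`tp / (tp + fp)`), recall (`tp / (tp + fn)`) and F1 (their
harmonic mean); degenerate zero denominators return 0 by convention,
which extreme label sparsity can reach. Micro-AUROC ranks the flattened
cell scores against the flattened indicators with mid-rank tie handling,
so constant scores give exactly 0.5.

Confidence intervals use a percentile bootstrap that resamples
*documents* with replacement (the document is the exchangeable unit;
resampling cells would break within-document dependence), with 100
replicates by default and the replicate metrics' 2.5/97.5 percentiles as
the 95% band. A replicate on which a metric is undefined is redrawn, with
a cap of ten times the replicate count. Everything is deterministic given
the seed.

The ablation harness (`run_cm_ablation()`, `run_pcs_ablation()`) trains
and evaluates every configuration on one shared split so that row
differences reflect preprocessing alone; a failing configuration yields an
error-carrying row without aborting the table. For strategies that cannot
compose an input for some documents (SM only, when a case has no SM),
those documents are kept with empty predictions so the validation set is
identical across rows.

# The synthetic generator

Real hospital coding corpora are protected health data, so the package is
exercised end to end on synthetic discharge summaries
(`generate_world()`, `generate_corpus()`). Text is template-based —
code phrases slotted among filler words — because the tests need exact
control over which phrases appear in which section. Each structural
mechanism the preprocessing targets is generated explicitly and recorded
per gold code in a manifest (`corpus_manifest()`), so downstream tests
read ground truth instead of re-inferring it:

* chronic codes whose phrase appears only in MH (15% of documents, the
  reported rate of chronic diseases missing from DD);
* external cause codes in gold with no textual evidence (2.73% — the
  reported share of cases — of the vocabulary and of documents);
* combination cases mentioning trigger plus companions while gold carries
  the combination code;
* stage-groups of three codes whose phrases differ only in an essential
  number, written with the digit form in raw text;
* mentions phrased like the official definition instead of the record
  phrasing (15% of realizations);
* SM present in 58% of documents (the reported share) carrying procedure
  phrases; SE present in half, mixing keyword-bearing procedure phrases
  with uninformative narrative; procedures leak a status-post mention
  into DD 30% of the time, making a DD-only procedure model weak but not
  useless;
* digit/date/non-Latin noise injected at rates 0.5/0.3/0.3 per section.

Mean section word counts target 31/11/86/149/5 (DD/SM/SE/MH/CC), the
reported means. Fractions without a reported value (CC presence 0.35,
combination cases 0.10, number-sensitive codes 0.20, definition phrasing
0.15, SE presence 0.5, DD leakage 0.3, noise rates) were fixed once at
values realistic for inpatient records and are configuration fields, not
constants.

What the generator does *not* emulate: clinical language style, the ICD
hierarchy's semantics, realistic code co-occurrence, negation, or
abbreviations. A pipeline that passes every test here has demonstrated
that its mechanics are correct and that each preprocessing rule rescues
the failure mode it targets — not that its scores transfer to any real
corpus.

# Problem sizes and numerical choices

The study-scale checks run on 2,000 synthetic documents with a 9:1
train/validation split at seed 42 and the desk backend; module tests use
40–1,000 documents. At that scale the fully preprocessed CM pipeline
exceeds the no-preprocessing baseline by several F1 points, each
mechanism improves micro-F1 on the manifest-identified documents it
targets, and the procedure-strategy ordering (DD only worst, SM plus SE
keywords with DD-plus-SE fallback best) is recovered. Bootstrap coverage
is verified on a binomial-noise predictor with a known generating F1.
Degenerate inputs are handled by explicit conventions: zero-denominator
metrics return 0, AUROC refuses all-positive or all-negative gold,
splitting refuses corpora with fewer than 2 documents, and empty pipeline
outputs raise errors naming the document.

Ties and determinism: lexicographic label order fixes one-hot positions;
keyword overlap resolves longest-phrase-first with earlier table rows
winning among equals; combination rules apply in table order, each at
most once. All randomness flows from named seeds fanned out from a single
top-level seed.

# Known limitations

* Rule tables are inputs, not learned artifacts; the shipped defaults are
  illustrative starters, not any hospital's rules.
* The desk backend is a linear bag-of-words model: it cannot represent
  word order or long-range context, and its ceiling on real clinical text
  would be far below a fine-tuned contextual encoder's.
* The split is unstratified; with rare codes, a validation split can miss
  a code entirely.
* The generator's invertibility (phrase lookup reconstructs gold) holds
  only without combination and external-cause mechanisms, which by design
  break the text-to-label correspondence.
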