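---
title: "Methods: dosage prediction from free-text sigs and treatment-period construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage prediction from free-text sigs and treatment-period construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Many prescription registers (the Nordic registers are the canonical
example) record what was dispensed — drug, strength, package size,
number of packages, date — but not the prescribed daily dosage or the
treatment duration. The dosage lives in an unstructured free-text
dosing instruction (the "sig"), written in the prescriber's language:
"1 tablett 2 gånger dagligen", "½ tablett på morgonen", or nothing
useful at all ("enligt ordination"). Pharmacoepidemiological questions
about dose and persistence — who stays on ADHD medication, at what
mg/day — require turning those texts plus the dispensation stream into
per-day exposure.

`sigdose` implements a full pipeline for this: text → daily dosage in
pills → daily dosage in mg → continuous treatment periods → usage
analyses. Because real register extracts are access-restricted, the
package ships a seeded generator of synthetic Swedish-style registers
with gold labels; every stage is developed and tested against it.

## Preprocessing

Records returned to the pharmacy are removed, and records whose text
indicates a non-target indication (configurable keyword list, substring
match on the case-folded text) are set aside for audit. Titrated
texts — stepwise dose schedules inside one prescription — are detected
by keywords on word boundaries and split at connectives ("därefter",
"sedan", "sen") so each dose interval becomes its own classification
entry; a segment's stated duration ("i 2 veckor", "första veckan") is
parsed as days with week = 7 and month = 30 days. A titration keyword
without a splittable boundary yields a single segment flagged for
review rather than a silent pass-through.

Text normalization lowercases, removes punctuation while protecting
dose-bearing tokens ("0,5" → `0.5`, "½" and "halv" → `0.5`, "1-2" stays
one token), removes a Swedish stop-word list that deliberately keeps
quantity-bearing function words ("en", "ett", "halv"), and stems the
remaining words with a compact ordered suffix stripper
("tabletten"/"tabletter" → "tablett", "dagligen" → "dag"). The stemmer
is rule-based and scoped to dosing vocabulary; it is a fixed point on
its own output, which keeps normalization idempotent. Tokens are
integer-coded against a vocabulary built from the training corpus
(index 0 reserved for padding, 1 for out-of-vocabulary; remaining ids
assigned by descending frequency with lexicographic tie-break so the
mapping is reproducible) and post-padded to 40 tokens — the longest
synthetic sig is about 25 tokens, so truncation (from the end, with a
warning) is a safety valve rather than an expected path.

## The two-stage classifier

Stage 1 estimates the probability that an entry is non-informative;
stage 2 assigns one of 16 daily-dosage classes (0.5, 1, ..., 9 pills
per day, then 10–11, 12–13, 14–15, 16–17, 18–19, 20+; high dosages are
pooled because they are rare). Both stages use the same architecture:
an embedding layer (dimension 32), a flattening layer, one hidden layer
of 64 rectified units, and a sigmoid (1 node) or softmax (16 nodes)
output, trained by minibatch back-propagation with Adam (learning rate
1e-3, batch 32, 10 epochs, 10% of entries held aside for the training
history). These hyperparameters are engineering defaults, all
configurable through `nlp_hyper()`; at the default corpus size (8000
entries) the task is well within this capacity. Training and
prediction are deterministic given (corpus, configuration, seed) on
CPU.

The decision cascade uses 0.5 thresholds: stage-1 probability above
0.5 marks the entry non-informative; otherwise the stage-2 argmax class
is accepted only if its probability reaches 0.5, else the entry is
treated as non-informative too. A probability of exactly 0.5 counts as
informative (stage 1) and as confident (stage 2). Argmax ties break
toward the lower dosage class, the same minimum-dose convention used
for range ("1-2 tabletter") and add-on ("vid behov ytterligare 1")
instructions, whose gold dosage is the minimum taken per day. Interval
classes convert to pills/day by their lower bound (10–11 → 10, 20+ →
20). A titrated record is text-resolved only when every one of its
segments is; its record-level dosage (used for carry-forward history
and dose summaries) is the final segment's — the maintenance dose.

## Resolving non-informative dispensations

Unresolved dispensations go through a two-step fallback, processed in
date order within person so that earlier resolutions feed later ones:

1. **Carry-forward**: the most recent resolved dosage of the same
   medication (same ATC) strictly before the index date and within 365
   days is assumed still current. The rule never consults
   dispensations on or after the index date.
2. **Random forest**: 100 classification trees on bootstrap samples,
   trained on the dispensations the text models resolved confidently,
   with six structured predictors: age, sex, prescriber specialty (6
   classes), county (20 classes), Nordic article number, and the
   sequence number of the dispensation within a 6-month treatment
   window (operationalized as 1 + the count of same-drug dispensations
   in the trailing 183 days). Prediction is the majority vote over the
   per-tree votes, re-tallied so that ties break toward the lower
   class; categories unseen at training time map to a dedicated
   "unknown" level. Tree growth uses standard forest defaults
   (unconstrained depth, √p features per split).

After this cascade every dispensation has a pills/day value, and its
provenance (`nlp2`, `carry_forward`, `forest`) is retained for audit.

## From dispensations to continuous treatment periods

Per dispensation: expected supply length = dispensed pills / daily
dosage; lengths are clamped to [1, 90] days (at most a three-month
supply is reimbursed at once) and, when clamped, the dosage is updated
to pills / clamped length so pills are conserved; the clamped length is
stretched by an adherence coefficient of 7/5 (weekday dosing with
weekend omissions). Titrated dispensations walk their stated schedule
— duration × dose pills per segment, remaining pills at the final
segment's dose, early exhaustion ends the walk — and clamping scales
segment durations proportionally (doses inversely).

Within one person and medication a running supply-end date is
maintained: a dispensation on or before the running end is a
stockpiling instance and its supply is appended at the running end; a
dispensation after it opens a new period. This single running-end rule
implements both the stockpiling join and the
supply-reaches-next-dispensation join. Different medications are
independent streams assumed consumed simultaneously. Periods are
stratified by changes in mg/day (pills/day × strength), merging
adjacent equal-dose strata; supply lengths are rounded to whole days
(minimum 1, nearest-day rounding distributed over titration segments so
strata tile the period exactly) because register dates have day
resolution. Interval ends are exclusive. The module never truncates at
an administrative censoring date — censoring belongs to the analysis
layer. Whether the adherence extension should apply before or after
stockpiling checks is not dictated by the workflow itself; it is
applied per dispensation before joining, and no cap is placed on
accumulated stockpile.

## Validation metrics

Accuracy is reported with both the Wilson score interval and the Wald
normal approximation, labelled — validation reports in this literature
use either, and printed intervals are not always the method named in
the text, so both are first-class and the report records which is
which. The weighted g-means statistic is defined here as the
prevalence-weighted sum over classes of √(recall × specificity)
(one-vs-rest), with zero-prevalence classes excluded and weights
renormalized; it punishes collapsed minority-class recall that raw
accuracy hides. Overall accuracy follows the convention "one minus the
share of erroneous predictions among prescriptions classified as
informative" (a truly non-informative prescription classified
informative counts as an error); an all-prescription variant and a
full-cascade variant (final pills/day from any source vs. the true
dosage) are reported alongside. Prediction errors are cross-tabulated
by gold class and relative size with bins (0, 20%], (20%, 50%],
(50%, ∞); exact predictions are not errors.

## The synthetic register

The generator emulates what the pipeline consumes, not the full
richness of real registers. Per person it draws demographics, one ATC
(81.25% methylphenidate, 6.25% each atomoxetine, amfetamine,
dexamfetamine — the 6500:500:500:500 mix of the intended training
corpus), an article from a small strength/package catalog, and a
dosage trajectory over the 16 classes (defaults skewed toward 1–3
pills/day, occasional ±1-class changes at refills). Sig texts are
drawn from a curated template grammar: quantity × frequency phrases,
morning/night splits, ranges, add-ons, titration chains with stated
durations, and a non-informative pool whose true dosage continues the
trajectory (so carry-forward is learnable). Refill gaps are drawn
around the extended supply length (early refills create stockpiling),
occasional long pauses open new periods, and per-refill discontinuation
hazards are highest for young adults. Returned dispensations and
non-target-indication texts are injected to exercise the filters.
Defaults were fixed once to mirror the intended study conditions
(8000 training / 1000 validation sigs, ~6.5% titrated, 10%
non-informative) and are not tuned against test outcomes.

Because generator and classifier see the same grammar, passing
accuracy thresholds on synthetic data demonstrates that the pipeline
machinery is sound — splitting, encoding, training, thresholds,
cascade — not that any particular accuracy would be attained on real
prescriptions, whose text distribution is unknown here. Label
soundness is guarded by an independent regex oracle in the test suite
(sharing no code with the generator) that re-derives every gold dosage
from the generated text; timeline recoverability is guarded by a
noiseless mode (`exact_refills = TRUE`, adherence 1, no pauses or
hazards) in which the period engine must reproduce the generator's
true period boundaries exactly; and the period engine is checked
against a brute-force day-walk simulator on 1000 random histories.

## Usage-pattern analyses

Incident users in a calendar year are persons whose first in-window
dispensation has no same-study-drug dispensation in the preceding 365
days (wash-out), aged ≥ 6 at index; age bands are 6–12, 13–17, 18–29,
30–49 and 50+ (the open band read as ages ≥ 50). Follow-up runs from
index to the end of the continuous treatment episode — the union of
the person's treatment periods across study medications — or
administrative censoring at the window end. Discontinuation is the end
of the *first* episode; a later restart does not undo the event. The
Kaplan–Meier curves use `survival::survfit` (the hand-computed
product-limit value is the test oracle, not the implementation). A
sensitivity cohort drops users with a single dispensation from index
to window end. The person-level methylphenidate dose is the
duration-weighted mean mg/day over the strata of the person's longest
period (ties to the earliest), categorised as low (≤ 30 mg), medium
(30–60] and high (> 60 mg).

## Numerical choices and degenerate inputs

* Probability exactly 0.5: informative at stage 1, confident at stage 2.
* All argmax and vote ties: lower dosage class.
* Calendar rounding: nearest whole day, minimum 1; banker's rounding as
  provided by R's `round`.
* Wilson bounds are snapped to exactly 0/1 at 0 or n successes (the
  analytic values) to avoid floating-point dust.
* Empty inputs: filters, joins and exporters pass empty frames
  through; `proportion_ci` requires n ≥ 1; an all-non-informative
  validation set leaves the informative-denominator accuracy undefined
  and reported as absent rather than 0.
* A titrated text whose pills run out inside the first interval
  contributes a single-segment profile at the starting dose; a
  titrated record with no usable stated durations is treated as
  regular at its maintenance dose and flagged.

## Problem sizes in the shipped tests

The default study used by the acceptance suite and the acceptance
script runs 1250 synthetic persons (≈ 10,000 dispensations, ≈ 10,500
entries), trains on 8000 entries and validates on 1000 records from
disjoint persons, three seeds for the end-to-end recovery checks; the
day-walk comparison uses 1000 random small histories and the oracle
re-parse about 2400 records. These sizes were chosen as the smallest
that exercise every code path at the intended corpus scale.

## Known limitations

* The sig grammar is a template list, not a model of real Swedish
  prescription language; vocabulary and length distributions of real
  sigs are unknown here.
* The stemmer and keyword lists are scoped to dosing vocabulary and
  must be extended for other drug areas or languages.
* No cross-medication switching episodes are constructed (e.g.
  methylphenidate → lisdexamfetamine continuity), and dose tapering is
  inferred only from explicit titration text.
* The fallback forest's signal on synthetic data is limited to the
  structural features the generator actually correlates with dose;
  its synthetic performance says little about real registers.
* Consumption is assumed to follow dispensation; returned-but-consumed
  or dispensed-but-unconsumed medication is invisible, as in any
  register-based method.
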