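---
title: "Shortening the ADI-R: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortening the ADI-R: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adirshort` studies whether the case/control classification produced by the
full 93-item Autism Diagnostic Interview–Revised (ADI-R) can be reproduced
from a small item subset. This vignette is the package's account of the
underlying models, the tunable parameters and their defaults, the synthetic
data it trains on, and the design decisions taken where the problem was
genuinely open. It states no empirical numbers beyond those the test suite
and `scripts/acceptance.R` themselves compute.

## The instrument layer

Answer sheets are tibbles with one row per subject: `subject_id`,
`age_months` (integer months; year-valued interfaces convert at 12 months
per year and all age windows are half-open), `verbal` (logical),
`diagnosis`, and one raw-code column per item. Raw codes are 0–3
(ordinary severity) plus the exception codes 7 ("definite abnormality not
of the type specified"), 8 ("not applicable") and 9 ("not known"). For
scoring and classification, `recode_answer()` maps 3 to 2 and all
exception codes to 0, so recoded scores live in {0, 1, 2};
`recode_cohort()` applies this elementwise and attaches the class label,
with the sign convention autism = −1 / non-spectrum = +1 chosen so that a
negative classifier score reads as autism by construction.

Items answered mostly with exception codes carry little usable
information; `identify_excluded_items()` removes an item when the fraction
of exception codes *strictly* exceeds a threshold (default 0.5 — "a
majority" read as strict majority, so an item at exactly 50% is
retained), plus any abbreviations force-listed in configuration (the
special-isolated-skills and optional hand-written items of the real
instrument; the canonical list is not public, so it is configuration, not
code). Exclusion depends only on per-item marginals, hence is invariant to
subject order.

The instrument's own diagnostic algorithm sums recoded scores in three
behavioural domains and declares autism when **all** totals meet or exceed
their cutoffs: 10 for social interaction, 8 (verbal) or 7 (nonverbal) for
communication, 3 for restricted/repetitive behaviours. "Exceed the
minimum cutoff" is implemented as ≥, the standard convention — a strict
`>` would make the nominal cutoff values themselves unreachable. Two
caveats are deliberate: the ADI-R's age-of-onset criterion is out of scope,
and the item→domain mapping shipped with the package (15 social, 13
communication, 8 restricted/repetitive items, chosen to include the
seven-item published subset in plausible domains) is **synthetic and
non-canonical** — the licensed algorithm's item lists are not reproduced.
The mapping is an input everywhere it is consumed. Item 86 (`ageabn`,
age when abnormality first evident) is treated on the same recoded 0–2
scale as every other item; its native coding is ambiguous and we flag
rather than guess it.

## The ADTree classifier

```{r}
library(adirshort)
rec <- recode_cohort(generate_cohort(cohort_config(), seed = 1))
model <- fit_adtree(rec, iterations = 10)
tidy(model)    # per-round: chosen rule, Z, child values, exponential loss
autoplot(model)
```

An alternating decision tree interleaves prediction nodes (real additive
contributions) and splitter nodes (one-item threshold tests). Scoring sums
the contributions of all reached prediction nodes; classification is the
sign of the score (exactly 0 resolves to non-spectrum and is always
flagged); the amplitude is the confidence, with scores inside a band
(default half-width 0.5, configurable — chosen so that scores of order
0.1–0.2 read as borderline) flagged for closer inspection.

Training parameters and conventions:

* **Rounds `T = 10`** (the classical default for this learner). Each round
  adds one splitter, so the model has at most `T` splitters and repeats of
  an item are possible and meaningful.
* **Smoothing `ε = 1`** inside every half-log-ratio
  `a = ½·log((W₊+ε)/(W₋+ε))`, guarding empty partitions. The root is rule
  0: its value is the smoothed class-weight log-ratio and it updates the
  record weights like any other rule.
* **Search space**: every existing prediction node is a precondition;
  candidate thresholds are midpoints between consecutive observed scores
  of an item *among the records reaching that node*. The selected rule
  minimises `Z(c1,c2) = 2[√(W₊W₋)|c1∧c2 + √(W₊W₋)|c1∧¬c2] + W(¬c1)`.
* **Tie-breaking**: candidates within `1e-12` of the minimal `Z` are
  treated as tied (floating-point sums are not associative) and resolved
  by lowest item index, then lowest threshold, then earliest-created
  path — making training fully deterministic.
* **Record-order invariance**: training canonically re-sorts records by
  label and scores, so a permuted cohort yields a bit-identical model.
* **Degenerate inputs**: an empty matrix errors; a single-class cohort
  with `T > 0` warns and returns the root-only model (whose sign is the
  majority class); training stops early with a warning if no admissible
  split remains.

Models serialise to nested JSON at 17 significant digits, which makes the
double → text → double round-trip exact: a read-back model scores any
sheet identically. Decision stumps and OneR rule learners are provided as
baselines under the same fit/predict contract (constant confidence 1);
their value-level ties resolve toward autism, the costlier error direction
for a screening instrument.

## Evaluation

`kfold_cv()` uses **stratified** folds (per-class sizes differing by at
most one, seeded shuffle): with a ~12:1 class imbalance, unstratified
folds are occasionally control-free, which silently corrupts the false
positive rate. If a class is smaller than `k` it falls back to
unstratified folds with a warning. Metrics treat autism as the positive
class; a metric with a zero denominator is reported `NA`, never coerced
to 0 or 1. Rates are computed unrounded and rounded only at the
presentation layer (rates to 3 decimals, accuracy as a percentage with 2).
`compare_classifiers()` accepts externally computed `(FPR, TPR, accuracy)`
rows verbatim so published results for learners outside the package can
sit in the same table; `score_profile()` tabulates signed scores against
age in years for the scatter view of classification stability across age.

## The synthetic cohorts

The repositories behind the original analyses are access-restricted, so
the package trains on synthetic cohorts that emulate their published
shape: 891 cases and 75 controls aged 5–17 with log-normal ages fitted to
the reported quartiles (cases 6.44/8.06/10.84 years, controls
6.38/9.24/11.88; the exact age law is unspecified, a log-normal matched to
three quartiles and truncated to the window is our choice), a verbal
fraction of 0.8 (unreported; most school-age interviewees are verbal),
exception codes injected at rate 0.02, and two designated items answered
with exception codes 75% of the time so that data-driven exclusion is
exercised end to end.

Class separation is *planted* in seven informative items (defaulting to
the published seven-item subset). The construction is ordinal: an
informative item scores 2 with probability 0.9 (cases) / 0.05 (controls),
and otherwise scores 1 with conditional probability 0.7 (cases) / 0.25
(controls). Both thresholds of an informative item therefore separate the
classes, as they do for genuinely discriminative severity-coded items — a
construction in which only the score-2 probability differs leaves the
1-vs-0 threshold uninformative and the planted signal exhausts after one
split per item. All other items share one background distribution
(0.55/0.25/0.15/0.05 over raw codes 0–3) in both classes. Every generated
case is re-drawn until it satisfies, and every control until it fails,
the domain-cutoff algorithm under the configured mapping, so generated
labels agree with the instrument's own algorithm by construction; an
unsatisfiable configuration errors after a bounded number of batches,
naming the most-violated domain.

What passing tests on these cohorts do **not** show about real data: real
item responses are mutually correlated far beyond seven items, real
controls include neurodevelopmental conditions near the spectrum, and the
acceptance/rejection step induces a slight label dependence in
domain-mapped background items that real data would not share. One known
consequence, measured honestly by the test suite: with `T = 10` fixed,
the planted signal typically separates training within about seven
rounds, and later rounds may fit residual background fluctuation, so the
fitted tree occasionally includes one background item besides the planted
seven. The suite and the acceptance script report the recovery rate over
20 seeds rather than hiding it.

Two control simulators probe specificity beyond the 75 observed controls:

* `resample_controls()` draws each item independently, uniformly with
  replacement, from the per-item answer multisets of observed controls
  (`build_control_pool()`), guaranteeing pool-matched marginals; a
  whole-row mode preserving inter-item correlation is available for
  sensitivity analysis.
* `simulate_near_cutoff_controls()` draws, per sheet and domain, a target
  total uniformly from `[max(0, cutoff − δ), cutoff − 1]` (default margin
  `δ = 3` — "close to but below" quantified, configurable to stress
  specificity as δ grows) and allocates it uniformly over all score
  compositions via exact sequential sampling from composition counts.
  Sheets default to verbal so each domain's target range is a single fixed
  set; every output fails the diagnostic algorithm in all three domains.

All generators are pure functions of (configuration, seed).

## Problem sizes

The default study conditions are used throughout: 966-subject cohorts for
training and 10-fold cross-validation, 20 generator seeds for the
planted-recovery rate, 1000 sheets per control simulator (10 000 where a
distributional shape is tested). These sizes are the package's chosen
experiment design; the oracle-equivalence tests for the learner run on
exhaustively enumerable instances (≤ 12 records, ≤ 3 items, ≤ 2 rounds)
against an independent brute-force implementation.

## Known limitations

The package classifies classic autism versus non-spectrum only — no
Asperger/PDD-NOS subtyping, no age-of-onset criterion, and no probability
calibration of scores. The shipped domain mapping is synthetic; any
conclusion about the real instrument requires the canonical mapping as
configuration. The published seven-item subset is shipped as a constant
for questionnaire-shortening use, but the original fitted tree's
thresholds and node values are not public, so scoring models are always
trained fresh.
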