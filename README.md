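# adirshort

Item reduction for the Autism Diagnostic Interview–Revised (ADI-R) with
alternating decision trees.

The ADI-R is a 93-item caregiver interview used in the behavioural
diagnosis of autism; a full administration takes hours. Retrospective
analyses of item-level answer repositories have shown that a boosted
alternating decision tree (ADTree) trained on complete answer sheets can
reproduce the instrument's case/control classification from a handful of
items, suggesting a drastically shortened screening questionnaire.
`adirshort` is a self-contained R implementation of that analysis for
biostatisticians studying instrument shortening: the ADI-R data model and
its domain-cutoff diagnostic algorithm, a from-scratch ADTree learner with
signed confidence scores, baseline learners, cross-validated evaluation,
and synthetic cohort generators (the real repositories are
access-restricted) including the two control simulators used for
specificity experiments under heavy class imbalance.

## The model

An ADTree alternates *prediction nodes*, each carrying a real additive
contribution `a`, with *splitter nodes*, each testing one item score
against a threshold. A sheet's score is the sum of the contributions of
every prediction node it reaches (the root always; a splitter's child iff
its parent prediction node is reached and the condition holds; parallel
paths all contribute). The classification is the sign of the score —
negative = autism, positive = non-spectrum — and its amplitude `|F(x)|` is
a confidence measure; scores inside a configurable band (default 0.5) are
flagged low-confidence.

Training is boosting over base rules (precondition `c1` = the path to an
existing prediction node, condition `c2` = one threshold test). With
`W+(c)`, `W-(c)` the weights of non-spectrum/autism records satisfying
`c`, each round adds the splitter minimising

    Z(c1,c2) = 2[ sqrt(W+(c1&c2) W-(c1&c2)) + sqrt(W+(c1&!c2) W-(c1&!c2)) ] + W(!c1)

with child values `a = 1/2 log((W+ + e)/(W- + e))` (smoothing `e = 1`) and
weight update `w_i <- w_i exp(-y_i r_t(x_i))`. Defaults: 10 rounds,
exhaustive all-path search, deterministic tie-breaking.

Around the learner, the package implements the instrument layer (raw codes
0–3 with 3→2, exception codes 7/8/9→0; exclusion of items answered mostly
with exception codes; the domain-cutoff algorithm: autism iff social ≥ 10,
communication ≥ 8 verbal / 7 nonverbal, restricted-repetitive ≥ 3), and
evaluation (confusion metrics with autism as positive class, stratified
k-fold CV, classifier comparison, score-vs-age profiles).

## Worked example

```r
library(adirshort)

cohort   <- generate_cohort(cohort_config(), seed = 1)   # 891 cases, 75 controls
retained <- setdiff(item_cols(cohort), identify_excluded_items(cohort))
rec      <- recode_cohort(filter_by_age(cohort, 5, 17), retained = retained)

model <- fit_adtree(rec, iterations = 10)
model
#> ADTree model: 10 splitter(s), root value -1.2314
#> Items used (7 distinct): ageabn x1, compsl5 x1, conver5 x1, gaze5 x1,
#>   grplay5 x2, peerpl5 x1, play5 x3

kfold_cv(rec, adtree_learner(iterations = 10), k = 10, seed = 1)
#> 10-fold CV of ADTree on 966 records
#>   FPR 0.040  TPR 1.000  accuracy 99.69%

classify_score(predict_score(model, rec[c(1, 966), ]))
#> # A tibble: 2 x 5
#>    score diagnosis    label confidence low_confidence
#> 1 -10.7  autism          -1      10.7  FALSE
#> 2   5.63 non_spectrum     1       5.63 FALSE
```

The fitted tree uses exactly the seven planted informative items (the
published seven-item subset ships as `published_subset`), three of them
more than once; every case is recovered (TPR 1.000) and 3 of the 75
controls are misclassified (FPR 0.040). The two example subjects are
classified with high confidence on the correct side of zero.

The two specificity experiments are one call each:
`resample_controls(build_control_pool(cohort), n = 1000, seed = ...)`
draws artificial controls item-wise from the observed control pool, and
`simulate_near_cutoff_controls(near_cutoff_config(n = 1000), seed = ...)`
generates behaviourally borderline sheets whose three domain totals fall
just below the diagnostic cutoffs. Screening either set with the fitted
model measures specificity beyond the 75 observed controls.

A file-based pipeline (`cmd_simulate()`, `cmd_train()`, `cmd_evaluate()`,
`cmd_screen()`) wraps these steps with provenance sidecars, and
`inst/cli/adirshort.R` exposes them as a command line.

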