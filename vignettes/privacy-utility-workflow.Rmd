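---
title: "Comparing anonymization and synthetization for a claims cohort: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing anonymization and synthetization for a claims cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privcohort)
```

## The problem

A data holder wants to share a small, high-dimensional health-claims cohort
(one row per patient: demographics, comorbidity flags, study dates, rare
time-to-event outcomes) without exposing the individuals in it. Two protection
routes dominate practice: **anonymization**, which transforms the original
records until formal privacy models hold, and **synthetization**, which fits a
generative model and releases entirely new records. `privcohort` implements
both routes at desk scale and scores them on three axes:

1. **Fidelity** — how closely the protected data reproduce the structure of
   the original (univariate prevalences, pairwise correlations, multivariate
   support overlap).
2. **Utility** — whether the downstream study result survives: inverse
   probability of treatment weighted (IPTW) Cox hazard ratios for all-cause
   mortality and major bleeding, comparing direct oral anticoagulants (DOAC)
   against vitamin K antagonists (VKA) in a venous-thromboembolism (VTE)
   population.
3. **Privacy risk** — empirical attacks: linkage, singling-out, attribute
   inference (each normalized against a control attack), and shadow-model
   membership inference.

Protection and attack are both evaluated in two adversary scenarios: a
*context-dependent* (lower-risk) scenario in which the attacker only holds
the attributes flagged by threat modeling, and a *context-independent*
(higher-risk) scenario in which every attribute may serve as auxiliary
knowledge.

## The synthetic study cohort

The real cohort underlying this design cannot be shared, so the package
starts from a seedable generator (`generate_cohort()`) whose defaults *are*
the study conditions: 1727 records and 39 attributes — 3 demographic, 20
binary comorbidity flags, 9 study-information attributes and 7 outcome
attributes — with a 71.5% DOAC share. Eight comorbidity flags carry the names
the underlying study reports (arterial hypertension, varicose
veins/post-thrombotic syndrome, stroke, moderate/severe liver disease,
obesity, myocardial infarction, oral contraception, tamoxifen); the remaining
twelve are documented stand-ins, since the full attribute list is not public.
The pseudonymized patient id sits among the study-information attributes —
claims extracts always carry one, and it supplies the single direct
identifier that the threat model expects.

Design of the generator:

* **Correlated binary flags.** A latent Gaussian vector with a fixed
  positive-definite correlation matrix is thresholded at per-group normal
  quantiles. This gives exact control of per-group prevalences and of the
  latent correlation structure, and it is trivially seedable. The default
  prevalences are calibrated to an elderly VTE population (hypertension
  near-ubiquitous; obesity deliberately near zero — a handful of expected
  cases — so that rare-category safeguards are exercised downstream).
* **Outcomes.** Exponential event times with per-group rates, right-censored
  by an exponential dropout time (mean one year) and a 1080-day
  administrative horizon; bleeding and hospitalization are additionally
  truncated at death. The default death and bleeding rates give event counts
  in the tens with fewer events in the (smaller) VKA arm, and a group rate
  ratio of 1.25, so the utility stage has a recoverable ground truth.
* **Dates.** All dates are anchored on a first-VTE diagnosis date drawn
  uniformly from a four-year window; derived dates are stored redundantly as
  calendar dates *and* integer day offsets (offset 0 = the anchor), matching
  how such extracts are shipped and exercising the anonymizer's offset
  handling.

What the generator does **not** emulate: claims-code-level detail (ICD/ATC
lists), longitudinal multi-row structure, non-exponential hazards, and
covariate-dependent treatment effects. Passing tests on this cohort therefore
demonstrate that the machinery is correct and calibrated, not that any
particular real dataset is safe to release.

## Threat model

Attributes are classified into four mutually exclusive classes. Direct
identifiers are flagged as such; every other attribute is rated 1-3 on
replicability (stability over time), availability (how plausibly an external
party holds it) and distinguishability (how strongly it isolates a person).
The three ratings are summed and compared against a threshold (`>=`, default
6); attributes at or above it are indirect identifiers, remaining harm-laden
attributes are sensitive, the rest insensitive. The bundled profile set is
calibrated so the default schema classifies into 1 direct / 10 indirect / 5
sensitive / 23 insensitive; both the ratings and the threshold are plain data
(YAML-overridable) because they are expert judgments, not estimable
quantities.

## Anonymization

`anonymize()` enforces *k*-anonymity (default k = 2) and equal-distance
*t*-closeness (default t = 0.5) using generalization, microaggregation and
suppression:

* **Hierarchies.** Age generalizes to 5- then 10-year intervals, day offsets
  and event times to 30-, 90- then 360-day intervals; intervals are
  represented by their midpoint so data types survive. Binary flags have
  exactly two levels (identity, suppressed), which makes "suppress this flag
  everywhere" identical to attribute suppression. Birth quarter and the
  first-VTE date are not lattice dimensions: they are microaggregated to the
  equivalence-class mean date after the search, which leaves every class
  internally identical on those columns. Other dates are converted to
  offsets before the search and reconstructed afterwards from the
  microaggregated anchor plus the generalized offset midpoint.
* **Equal-distance t-closeness.** With uniform ground distances the
  earth-mover distance between a class's sensitive-value distribution and
  the table distribution reduces to the total-variation distance
  `0.5 * sum |P_class - P_table|`; that reduction is implemented directly and
  documented so alternative distance choices can be compared.
* **Objective.** Granularity loss: per cell, the fraction of the attribute's
  domain covered by the generalized value (interval width over domain range;
  `(covered-1)/(domain-1)` for categories; 1 for a suppressed cell), averaged
  over all protected cells. Microaggregated cells count 0 — the metric prices
  generalization and suppression, not aggregation; this convention is
  declared normative here.
* **Search.** Equivalence classes smaller than *k*, and classes violating
  *t*-closeness for any sensitive attribute (iterated to a fixed point), are
  suppressed whole; the record-suppression budget defaults to 100% —
  full-protection configurations of small high-dimensional cohorts routinely
  lose upwards of a third of the records, so a tight default budget would
  make them infeasible rather than merely lossy. Lattices with at
  most `exhaustive_limit` nodes (default 4000) are searched exactly by
  breadth-first enumeration with a generalization-only lower bound for
  pruning — the bound is valid because a suppressed cell costs at least as
  much as any generalization. Larger lattices (the context-independent
  configuration spans ~30 dimensions) use best-improvement coordinate search
  started from the fully generalized top node, which is always feasible
  (a single class, no record suppression) and descends monotonically. The
  greedy path returns a local optimum; correctness of the machinery is
  anchored by an independent brute-force oracle on all small instances in the
  test suite. Per-cell suppression is not searched separately: record and
  attribute suppression between them cover the behaviours the comparison
  needs, and `suppressed_cells` counts the cells those two routes remove.

One consequence worth knowing: under the granularity objective the greedy
search may suppress a cheap binary column (including the treatment column)
when keeping it would fragment many equivalence classes. That is the
objective speaking — the context-independent configuration then reports
non-estimable hazard ratios, the extreme of the pattern that protecting
everything costs the most utility.

## Synthetization

The generator is an autoregressive chain of smoothed conditional frequency
tables over discretized attributes, fitted in schema order (demographics,
comorbidities, study information, outcomes) — a causal-ish ordering that is
configurable by reordering columns. It implements the three safeguards the
protection route depends on:

1. **No 1:1 mapping.** Sampling is ancestral from fitted tables only; the
   model stores no training rows.
2. **Overfit control.** Parent sets grow greedily, at most `max_parents`
   (default 3) per attribute, and a candidate parent is kept only if it
   improves the holdout log-likelihood by at least `min_improvement`
   (default 2 nats), averaged over `holdout_splits` (default 3) random
   20% holdout splits. The margin exists because the *best* of ~30 spurious
   candidates gains a fraction of a nat by chance; averaging over splits
   exists because a single split's gain estimate is noisy enough to reject
   genuine dependencies. Conditional probabilities shrink toward the
   attribute's marginal with pseudo-count `smoothing * n_categories`, so
   unseen parent configurations fall back to the marginal.
3. **Outlier protection.** Numeric attributes are clipped to the 1st/99th
   percentile before binning into 10 quantile bins (samples are drawn
   uniformly within a bin, hence always inside the clip bounds); categories
   with fewer than 5 training occurrences are pooled. For binary flags the
   pooled label decodes back to the majority value, so a flag with fewer
   than 5 positive cases — the default cohort's obesity flag — vanishes from
   the synthetic output entirely.

A known limitation follows from the chain order: the treatment column can
condition on at most `max_parents` of the twenty comorbidity flags, so
group-conditional prevalences of the remaining flags are recovered only
through inter-flag correlation. At the default settings the residual bias is
within sampling error of the training estimates (tested), but a schema with
many strongly treatment-dependent attributes would need a larger
`max_parents` or a reordered chain.

## Fidelity metrics

* **Normalized prevalence.** Within each treatment arm, each flag's
  prevalence in the protected data is expressed as a percentage of its
  original prevalence (baseline 100), on within-dataset relative
  distributions so differing record counts do not distort the comparison;
  suppressed flags and zero-prevalence originals are excluded and flagged.
* **Correlation distance.** Mean absolute difference between the pairwise
  Pearson correlation matrices (binary flags enter as 0/1, i.e.
  point-biserial); pairs undefined in either dataset (zero variance,
  suppression) are excluded and counted.
* **Integrated alpha-precision / beta-recall / authenticity.** Computed in
  min-max normalized space fitted on the original data, missing values
  imputed with the original column median (so a fully suppressed column
  becomes a constant — a caveat for heavily anonymized data, as the
  motivating study notes). The support estimator is deliberately simple:
  distance-from-center quantile balls. The precision curve at level
  `a` is the share of protected records within the original's `a`-ball;
  recall swaps the roles; both are integrated against the diagonal on a
  20-point grid (trapezoid), `1 - 2 * integral(|curve - level|)`, clamped to
  [0, 1], so a distribution-matched release scores near 1 and a disjoint one
  near 0. Authenticity is the share of protected records whose nearest
  original neighbor is farther away than that original's own nearest
  neighbor among the originals — an exact copy scores 0. The one-class
  embedding of the metric's original formulation is out of scope; the
  simplification is the package's declared estimator and is what the
  identity/extreme-case tests pin down.

## Privacy attacks

All Anonymeter-style attacks report a main attack (targets drawn from the
records that produced the release), a naive baseline (random guessing), and a
control attack (same procedure, targets from a held-out control split), and
normalize `R = (r_main - r_control) / (1 - r_control)`. Risk is computed per
repetition and then averaged (10 repetitions by default, mean and SD
reported); an estimate is flagged invalid when the main attack does not beat
the baseline. Negative risks are reported as-is and read as "no effective
advantage".

* **Linkage** splits the auxiliary attributes into two halves and links a
  target when its nearest released neighbors under the two halves intersect
  (Gower-style distance: range-normalized absolute difference for numerics,
  0/1 mismatch for categoricals; ties break by record order).
* **Singling-out** derives predicates from the release only — unique values
  and min/max thresholds (univariate), or 2-4-attribute conjunctions seeded
  by a random released record (multivariate, capped at 100 queries) — keeps
  those isolating exactly one released record, and succeeds when a predicate
  also isolates exactly one attacked record. Because isolation probability
  scales with the attacked set's size, the pipeline attacks equally sized
  train and control subsets.
* **Attribute inference** predicts a secret attribute as the nearest released
  neighbor's value on the auxiliary attributes (exact match for categories,
  5% of range for numerics); the baseline guesses from the release's
  marginal.
* **Membership inference** follows the shadow-model design: reference
  samples from an attacker pool are protected with and without the target,
  a random forest is trained on attribute-wise marginal features (histogram
  counts for numerics, category frequencies for categoricals, bins fitted
  once on the pool) and evaluated on fresh labeled releases; risk is
  TPR − FPR aggregated over runs. For anonymizers the protection runs
  directly on each reference sample; for synthesizers a generator is refit
  per sample. The default design (samples of 500, 10+10 replicates, 30 runs)
  gives each pool record at least a 95% chance of entering some reference
  draw; the analysis script runs a reduced design (samples of 100, 5+5
  replicates, 5 runs) so the stage stays in the minutes range, and the test
  suite uses finer histograms (30 bins) when it needs a deliberately sharp
  attacker to expose an identity release.

## Utility analysis

A single harmonization step (shared schema, type casting, recomputation of
whichever date/offset representation protection discarded) is applied to all
datasets. The propensity model is a logistic regression of treatment on the
twenty flags plus age and gender; weights are stabilized ATE weights
(`P(T=1)/e` and `P(T=0)/(1-e)`), untruncated by default with a configurable
truncation quantile. Covariates that are constant, fully suppressed, or that
separate the arms perfectly (rare flags in small cohorts) are dropped with a
warning. Hazard ratios come from a weighted Cox partial likelihood with
treatment as the sole covariate and a robust sandwich variance for the 95%
CI — required for honest intervals under weighting. A zero-event arm is
reported as not estimable (`NA`), never as a numeric artifact. Balance is
reported as standardized mean differences before and after weighting
(pooled-SD denominator, weighted moments after).

## Numerical choices and degenerate inputs

Seeds thread through every stage (generator, splits, search, fitting,
attacks); identical configuration and seed give byte-identical CSV output.
Distance ties break by record index. Generalized event times of zero are
floored at half a day before Cox fitting. Empty quasi-identifier sets make
k-anonymity vacuously true (with a warning); a domain of size one contributes
zero granularity loss; all-constant data make the support metrics an explicit
error rather than a silent 0/0.

## Problem sizes used in the checks

The packaged checks run the full machinery at reduced scale so the suite
stays in the minutes range on one CPU: guarantee soundness over 100 simulated
cohorts of 120 records; exact-search/oracle equivalence on all instances with
at most 8 records and 3 protected attributes; attack calibration on a
750-record cohort split three ways with 10 repetitions; membership inference
at the reduced design above; Cox coverage over 100 replicates of n = 5000.
The analysis scripts under `analysis/` run the same stages at the full
1727-record study scale.

## Known limitations

* The greedy lattice search is heuristic above the exact-search cap; only
  small instances carry an optimality guarantee.
* The support metrics use center-distance balls, not a learned embedding;
  absolute values are comparable within this package, not across
  implementations of the metric family.
* The synthesizer is a discretized frequency chain, not a neural generator;
  it reproduces the safeguards and the marginal/low-order structure, not
  arbitrary high-order dependencies.
* Empirical attack scores are estimates under specific attacker designs;
  they bound nothing. A release that scores low here can still be vulnerable
  to attacks outside the four families implemented.
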