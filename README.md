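# privcohort

Privacy-preserving data sharing for small, high-dimensional health-claims
cohorts: `privcohort` compares the two standard protection routes —
**anonymization** (transforming the original records until formal privacy
models hold) and **synthetization** (releasing records drawn from a fitted
generative model) — on a common footing of **fidelity**, **study-level
utility** and **empirical privacy risk**, each evaluated under a
context-dependent (threat-modeled) and a context-independent (worst-case)
adversary.

It is written for biostatisticians and data stewards who must decide how to
release a per-patient claims extract (demographics, comorbidity flags, study
dates, rare time-to-event outcomes) and want the trade-off quantified rather
than asserted.

## What is inside

* **Cohort simulation** — a seedable generator for a 1727-record, 39-attribute
  anticoagulation-safety cohort (DOAC vs VKA after venous thromboembolism):
  correlated binary comorbidities via a latent Gaussian threshold model,
  exponential outcome/censoring times with tens of events, anchored dates.
* **Threat modeling** — replicability/availability/distinguishability ratings
  summed against a threshold, classifying attributes into direct / indirect /
  sensitive / insensitive (default profiles yield the 1/10/5 split).
* **Anonymization** — *k*-anonymity (k = 2) with equal-distance *t*-closeness
  (t = 0.5; earth-mover distance under uniform ground distances, i.e.
  total-variation distance `0.5 Σ_v |P_class(v) − P_table(v)|`) via
  generalization hierarchies, date microaggregation and suppression,
  minimizing a granularity loss over a transformation lattice (exact
  breadth-first search with lower-bound pruning on small lattices, greedy
  coordinate search on large ones).
* **Synthetization** — an autoregressive chain of smoothed conditional
  frequency tables over discretized attributes with rare-category pooling,
  extreme-value clipping and holdout early stopping on parent growth.
* **Fidelity** — group-wise normalized prevalences (baseline 100), Pearson
  correlation distance, and integrated α-precision / β-recall / authenticity
  in min-max normalized space.
* **Utility** — stabilized IPTW from a logistic propensity model, covariate
  balance (standardized mean differences), and weighted Cox hazard ratios
  with robust 95% CIs; a zero-event arm reports `NA`.
* **Privacy attacks** — linkage, univariate/multivariate singling-out and
  attribute inference with main/baseline/control normalization
  `R = (r_main − r_control) / (1 − r_control)`, plus shadow-model membership
  inference (`R = TPR − FPR`) against both protection routes.

## Worked example

```r
library(privcohort)

cohort <- generate_cohort(cohort_config(seed = 1))   # 1727 x 39 cohort
splits <- split_cohort(cohort, c(0.5, 0.25, 0.25), seed = 1)

cl <- classify_attributes(default_profiles(), default_threshold(),
                          default_schema())
cl
#> threat_classification (threshold >= 6 ): direct=1, indirect=10,
#>   insensitive=23, sensitive=5

anon <- anonymize(splits$train,
                  scenario_anon_config(cl, "context-dependent"),
                  default_hierarchies())
anon
#> anon_result: k=2 t=0.5 | loss=0.2323 | suppressed records=35 |
#>   suppressed attributes=2 | nodes evaluated=38

model <- synth_fit(splits$train, synth_config(seed = 1), default_schema())
synth <- synth_sample(model, nrow(splits$train), seed = 2)
fidelity_report(harmonize_cohort(splits$train), harmonize_cohort(synth),
                "treatment_group")
#> fidelity_report: corr distance=0.0427 IPa=0.9749 IRb=0.9746
#>   authenticity=0.6489

run_utility(anon$table)
#>              outcome events_exposed events_comparator       hr    ci_low ...
#> all_cause_mortality              28                 8 1.941250 0.8179813
#>      major_bleeding              17                 5 1.449667 0.5162713

round(risk_score(0.960, 0.926), 2)   # normalized attack risk
#> [1] 0.46
```

Reading the numbers: the threat model finds 1 direct, 10 indirect and 5
sensitive attributes; the context-dependent anonymization meets k = 2 and
t = 0.5 at a granularity loss of 0.23 while suppressing 35 of 863 training
records; the synthetic release keeps the correlation structure within 0.043
on average and sits almost entirely inside the original's support
(IPα ≈ 0.97) while 65% of its records are not near-copies; the anonymized
data still support the study's weighted Cox analysis (mortality HR 1.94,
95% CI 0.82–4.61); and a main attack succeeding 96.0% of the time against a
92.6% control success normalizes to a risk of 0.46 — the excess success as a
share of the remaining headroom.

## The analysis workflow

The full three-way comparison is organized as numbered drivers over the
package:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort + train/control/pool split
Rscript analysis/02_threat_model.R         # attribute classification
Rscript analysis/03_protect.R              # both anonymizations + synthesis
Rscript analysis/04_fidelity.R             # population/prevalence/correlation/support tables
Rscript analysis/05_utility.R              # IPTW Cox hazard ratios + balance
Rscript analysis/06_privacy_attacks.R      # linkage / singling-out / inference risks
Rscript analysis/07_membership_inference.R # shadow-model MIA (reduced scale)
```

Each stage prints what it found and writes its tables under `results/`
(CSV/JSON). Stages 1–5 run in seconds to a couple of minutes, stage 6 takes a
few minutes, and stage 7 (shadow-model membership inference) takes tens of
minutes on one CPU even at its reduced design.

## Scope

The vendor-neutral generator stands in for neural tabular synthesizers: it
reproduces the safeguards such tools advertise (broken record mapping,
overfit control, rare-category and extreme-value protection), not any
specific architecture. Attack scores are empirical estimates under the
implemented attacker designs, not guarantees. See the methods vignette
(`vignettes/privacy-utility-workflow.Rmd`) for the model, the design
decisions and the known limitations.
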