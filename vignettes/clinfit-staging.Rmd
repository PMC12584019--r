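---
title: "Functional staging of ClinFIT total scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional staging of ClinFIT total scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinstage)
```

## The problem

The ClinFIT instrument rates 30 ICF-derived categories on 0–10 scales, so
its total raw score spans 0–300 with higher values indicating greater
functional limitation. A raw total is hard to act on clinically; staging —
partitioning the scale into ordered bands such as light / moderate / high
rehabilitation intensity — makes it usable for triage and resource
planning. `clinstage` derives such stage boundaries empirically, using an
ordinal measure of delivered rehabilitation intensity as the reference:
the Therapy Disciplines (TD) domain of the Rehabilitation Complexity
Scale v2, which counts therapy disciplines involved in a patient's care
(TD0 none, TD1 one, TD2 two–three, TD3 four or more). TD reflects
provision of services, not assessed need — staging models built on it
inherit that interpretation.

## The stepwise procedure

`run_stepwise()` walks the TD levels from the highest level present down
to 1. At level \(L\):

1. The remaining sample is dichotomized **cumulatively**: positives are
   patients with TD \(\ge L\), negatives TD \(< L\). The cumulative
   reading (rather than level-vs-adjacent-level only) is the one
   consistent with the remaining-sample arithmetic of published staging
   tables — after the top step on \(n\) patients excludes its
   \(tp + fp\) predicted positives, the next step's four cells must total
   \(n - (tp + fp)\), which holds only if missed higher-level patients
   remain positives downstream.
2. Every integer cutoff \(c \in \{0, \dots, 300\}\) is scored by the
   Youden index \(J(c) = Se(c) + Sp(c) - 1\) with the prediction rule
   *positive ⇔ score ≥ c*; the maximizer is taken, ties broken toward the
   smallest cutoff. The full integer grid (not observed-score midpoints)
   is used because ClinFIT totals are integer sums and every integer is a
   legitimate clinical threshold.
3. All remaining patients with score ≥ the chosen cutoff — the
   *predicted* positives, not the true-label positives — are excluded,
   and the procedure moves to level \(L - 1\). Steps whose smaller class
   has fewer than `min_class_size` members (default 2) are recorded as
   skipped and cause no exclusion; the default is deliberately permissive
   because real high-intensity classes can be as small as two patients,
   and such steps are flagged *exploratory* (positive class < 10) rather
   than suppressed.

After the sequential pass, retention rules prune the candidates: a cutoff
is dropped when its comparison had AUC < `min_auc` (default 0.6) or
Youden < `min_youden` (default 0.3); then, while any two adjacent
survivors lie closer than `min_separation` points (default 15, i.e. 5% of
the scale), the member with the lower Youden index is dropped — the merge
loop terminates because each iteration removes one cutoff. When the
criteria tie, the lower cutoff is dropped; the choice of discarding the
weaker discriminator is ours, as no convention exists. The \(K\)
surviving cutoffs define \(K + 1\) stages with bands
\([0, c_1), [c_1, c_2), \dots, [c_K, 300]\); `assign_stage()` maps any
score to its band. For the two-cutoff model (135, 192) this yields
light < 135, moderate 135–191, high ≥ 192.

Two boundary conventions circulate in descriptions of such models
(“≤ 135 is light” vs “≥ 192 is high”); they disagree by one point at the
lower boundary. We fix *predicted positive ⇔ score ≥ cutoff* throughout
because it is the only convention that reproduces published stage counts
exactly (e.g. 83/82/105 on a 270-patient cohort under cutoffs 135/192).

A provisionally retained cutoff still causes exclusion for subsequent
steps even if the retention filter later removes it. This mirrors the
sequential narrative of the original analysis and keeps the audit trail
interpretable; `reevaluate_after_drop = TRUE` instead re-runs the
sequential pass with dropped candidates banned from the grid until the
retained set is stable. Manual judgment calls — forcing a cutoff at a
step, excluding specific candidate values — are supported only as
explicit `forced_cutoffs` / `excluded_candidates` arguments and are
always marked in the audit, never applied silently.

## ROC core

`roc_auc()` uses the Mann–Whitney formulation (probability that a random
positive outscores a random negative, ties counted ½), computed from
midranks; it equals the trapezoidal area under the all-thresholds
empirical ROC curve and is checked in the tests against an \(O(n^2)\)
pair-counting oracle and against `pROC`. `optimal_cutoff_youden()` is
checked against a scalar exhaustive search over all 301 cutoffs.
Metrics with an empty class (no positives or no negatives) raise errors
rather than returning sentinels: subgroup steps can legitimately run out
of positives and must be detected, not averaged over. Metrics are
reported rounded half away from zero at 3 decimals (1 decimal for
means/SDs/percentages); internal arithmetic is never rounded.

## The synthetic cohort generator

No patient-level data ship with the package, so `simulate_cohort()`
generates cohorts with the statistical structure the procedure assumes,
and the analysis pipeline is validated by *parameter recovery*: plant
thresholds, simulate, re-derive, compare.

The generative model, chosen as the simplest one matching the reference
cohort's printed moments:

* admission score ~ Normal(165.3, 59.4), rounded and clipped to
  \[0, 300\] (only mean/SD are known, so no heavier-tailed family is
  assumed);
* latent TD level = number of planted thresholds \(t_1 < t_2 < t_3\) at
  or below the score; observed TD = latent ± 1 with probability
  `td_noise` (symmetric, since no referral error model is documented),
  clipped to 0–3;
* discharge = admission − Normal(67.8, 57.5) improvement, rounded and
  clipped — the improvement moments imply a paired effect size
  \(d \approx 67.8/57.5 = 1.18\);
* demographics (54.1% male; age Normal(62.9, 14.3) floored at 18;
  diagnoses 33.0/21.1/23.3/22.6% stroke/MSK/cancer/other) are drawn
  independently of the scores, as no joint structure is documented.

Default planted thresholds are (142, 198, 260): the quantiles of the
configured admission distribution that reproduce the reference TD
marginals 34.4/36.3/23.7/5.6%. Default `td_noise` is 0.05, a modest
level of referral-recording error. Both defaults are stated here once
and are not tuned elsewhere; validation scenarios that plant other
thresholds (e.g. 135/160/192) pass them explicitly.

What the generator does *not* emulate: correlation between demographics
and scores, floor/ceiling clustering of real ClinFIT items, site effects,
and any dependence of improvement on admission severity (score clipping
induces a mild one mechanically: the realized effect size is ≈ 1.19
rather than 1.179 at very large n). Passing recovery tests therefore
show the procedure recovers thresholds *when the latent-band model
holds*; they cannot show the model holds in any real population. The
within-TD-level score distributions of real cohorts are unknown; the
latent-band + noise model is one admissible choice and is labelled as
such.

`cohort_from_confusion_fixture()` is the complementary validation tool:
it builds a cohort whose forced stepwise run reproduces a printed set of
TP/FP/TN/FN cells *exactly*. Scores are placed mid-band (robust to
off-by-one convention changes) and TD labels are minimal (true positives
at the dichotomy's upper level, false positives one level below), with
missed positives carried into later steps' cells. Only the cells and
stage counts are controlled — a fixture's TD marginals and AUCs are not
those of the original data (three distinct score values cannot reproduce
a continuous-data AUC), which is why printed AUC values are not
acceptance quantities. One published subgroup ("other" diagnoses)
involved a manual threshold substitution and its printed steps do not
satisfy the remaining-sample recursion; `reference_fixtures()` therefore
carries that stratum as two standalone one-step fixtures.

## Paired pre/post statistics

`paired_change()` runs the classical paired t-test (via `stats::t.test`)
on admission − discharge, so positive differences mean improvement.
Cohen's d uses the paired-design variant \(d_z\) = mean difference / SD
of differences, which satisfies \(t = d\sqrt{n}\) exactly and is the
variant consistent with reported effect sizes near 1.18 given the
printed score moments; this is an assumption, as the variant is rarely
named in applied reports. The default 95% CI is the normal approximation
\(d \pm 1.96\sqrt{1/n + d^2/(2n)}\); `ci_method = "noncentral"` inverts
the noncentral t distribution instead. Effect bands follow the
0.2/0.5/0.8 small/medium/large convention on \(|d|\). Zero-variance
differences are an explicit error (t undefined), and patients missing a
discharge score are excluded and counted.

## Subgroup analyses

`run_subgroups()` re-runs the procedure independently per stratum of a
marginal plan (sex; age below/at-or-above 65, the boundary inclusive in
the older band; diagnosis group) with identical criteria. Strata are
never cross-classified — crossing explodes sparsity and no reference
results exist for it. Sparse strata degrade gracefully to 1-stage models
with warnings. `collate_cutoffs()` assembles the cross-stratum
comparison with an audit appendix of skipped and dropped candidates.

## Problem sizes and numerical choices

The validation suite uses fixture cohorts of 270 patients, synthetic
cohorts of up to 6 000, oracle instances of up to 120 observations, and
100-seed recovery sweeps at n = 5 000 with 10% TD noise — sizes at which
the recovery behaviour is stable while the whole suite runs in well
under a minute per module. Recovery under noise is judged within ±5
points of the planted thresholds; noise-free recovery is exact because,
with dense integer scores, the unique Youden-maximal cutoff under a
perfect step function is the planted threshold itself. All randomness
flows through explicit seeds (`withr::with_seed`), so every cohort is
reproducible from its parameter set.

## Known limitations

* The TD reference measures delivered services; staging models express
  provision, not need.
* Cutoff uncertainty (bootstrap CIs) and external validation are out of
  scope, as is any smoothed or cost-weighted ROC variant.
* The generator's independence assumptions make subgroup cutoffs
  identical in expectation across strata; it cannot emulate genuinely
  heterogeneous subgroup thresholds.
* ClinFIT is modelled at total-score level only; item-level structure is
  not simulated.
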