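---
title: "Trial-level SART thresholding: method, generator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level SART thresholding: method, generator and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sartvis)
```

## The task and its raw data

The Sustained Attention to Response Task (SART) shows the digits 1–9 in a
fixed repeating order, 300 ms per digit with an 800 ms gap. The
participant presses a key for every digit except 3, for which the press
must be withheld. One pass through the nine digits is a **cycle**; the
administration repeats it 23 times, giving 207 **presentations** and, in
a flawless run, 184 recorded reaction times plus 23 correct withholds.
Two kinds of mistakes exist: **omissions** (a GO digit with no press) and
**commissions** (the NO-GO digit pressed). Both signal lapsing attention.

Conventional analyses reduce the 207-point record to a mean and SD of RT
and a total mistake count. The premise of this package is that the
*within-task distribution* of mistakes carries clinically relevant
information that those averages destroy: one catastrophic cycle among 22
clean ones and eleven isolated slips produce the same total, but mean
very different things.

A note on vocabulary: the word "trial" is used in the field both for a
single digit presentation and for a 9-digit cycle. This package never
uses it; the API speaks of *presentations* (207) and *cycles* (23).
Spots, thresholds and bad performances are all per-cycle concepts.

## Per-cycle metrics and plottability

`cycle_metrics()` computes, for each cycle: omission, commission and
total mistake counts, the error fraction (denominator fixed at 9, the
presentations per cycle), and the mean RT over the *correct actions*
(GO presses with a recorded RT) of that cycle. Commission RTs are
generated by the hardware but never used.

A cycle is **plottable** when its mean correct-action RT exists: at
least one correct press, and no press with a lost RT. A cycle with no
presses at all (8 omissions; withholding on the 3 is correct, so never 9)
has no RT anchor and receives no spot. Consequently the largest mistake
count a plottable cycle can carry is 8 — one correct press must remain.

## The spot-size threshold

The multimodal visualisation draws one spot per plottable cycle, placed
vertically at its mean correct-action RT, with participants ordered
horizontally by age (integer ranks, because the cohort's age
distribution is far from uniform and positioning by raw age would crush
most of the plot into the 50–65 range). Spot colour runs from light
brown (0 mistakes) to black (8). Spot **area** is proportional to
`error_fraction^size_power`, with `size_power = 2` by default — that is,
the marker *radius* grows linearly with the percentage of errors, which
is how marker size is specified in most plotting systems (an "area"
argument in points², with the drawn radius its square root).

A **bad performance** ("big spot") is a cycle whose spot size exceeds
`mean + 2 * SD` of the sizes of all plottable cycles pooled across the
dataset. `sart_threshold()` converts this cutoff into the smallest
integer mistake count k (strict inequality) whose spot exceeds it. On
cohorts generated by the default configuration this lands on **4
mistakes out of 9**, stably across seeds at n = 5000 (the acceptance
suite checks 10 seeds).

The exponent matters, and the choice is deliberate. A moment-bound
argument shows why the rule cannot operate on the error-fraction scale
directly for data of this shape: the cohort moments being emulated
(total mistakes ≈ 11 per 207 presentations, mean bad-performance count
≈ 0.3 with at most ~1.3% of cycles at 4+ mistakes) cap the pooled SD of
per-cycle error fractions near 0.13, so `mean + 2*SD` stays below 1/3
and the implied integer threshold could never exceed 3 whatever the
generative details. Squaring stretches the upper tail of the size
distribution (a spot with half the digits wrong has 16× the area of one
with one-eighth wrong, not 4×), which both matches how a drawn bubble
chart is perceived and makes the 2-SD rule single out genuinely
catastrophic cycles. `size_power = 1` is available for the linear
reading, and `fixed_sart_threshold(4)` pins the reference value when
comparing datasets, which is also the recommended route for small
samples where the pooled SD is noisy.

Unplottable cycles are excluded from the cutoff computation (they are
absent from the graph that defines it) but, by default, a cycle whose
mistakes reach the threshold still counts as a bad performance even when
unplottable — a cycle with no presses at all is plainly a bad
performance. `bad_perf_plottable_only = TRUE` restores the stricter
visualisation-bound reading. Under either convention the decomposition
`total_mistakes = mistakes_in_good_performances + mistakes in bad
cycles` holds exactly, and the tests assert it participant by
participant.

## The synthetic cohort generator

Real trial-level SART data of this kind come from restricted cohort
studies, so the package ships a generator whose outputs have the
statistical structure the analysis assumes. Its defaults are the study
conditions; they were frozen against the descriptive moments above and
are not tuning knobs.

Errors arise from three processes, each acting on the log-odds scale
through age (per year over 60) and a standard-normal latent attention
deficit:

* **baseline errors** — independent GO omissions (2.4%) and NO-GO
  commissions (13%);
* **attention bursts** (`lapse_cycle_rate`, 0.3% per cycle before age
  and deficit effects) — a run of 2–3 consecutive GO digits goes
  unanswered, producing the 2–3-mistake cycles that thicken the size
  distribution without crossing the threshold;
* **deep lapses** (`deep_lapse_cycle_rate`, 0.062%) — engagement
  collapses for a whole cycle: each GO digit is omitted with
  probability 0.78 and the NO-GO is pressed with probability 0.5,
  yielding 6–8 mistakes. These rare cycles carry the upper tail that
  the 2-SD rule detects.

The deficit loading on the lapse rates (2.3) is large by design: it
concentrates bad performances in a small subgroup, reproducing the
heavy-tailed, emphatically non-normal feature distributions that rule
out linear models on real data (`normality_screen()` rejects normality
for all three candidate predictors on any sizeable simulated cohort).
The age loading (0.095/yr) makes the proportion of participants with at
least one bad performance rise monotonically across the 50–64, 65–74 and
75+ bands, the qualitative gradient reported in ageing cohorts.

RTs of presses are lognormal: participant location `log(368)` ± 0.225
(log scale) plus 1 ms/yr above age 60; each participant has their own
within-task log-SD (median 0.185, dispersion 0.4). The dispersion term
keeps the mean-RT and SD-RT features only moderately rank-correlated
(ρ ≈ 0.5), as observed in real cohorts — with a common within-SD the two
features would be nearly collinear and the adjusted models'
collinearity screen would rightly fail.

One calibration compromise is worth stating plainly. Robust recovery of
the threshold of 4 requires roughly 0.27 deep-lapse cycles per
participant; together with the burst tail this puts the generated
bad-performance mean near 0.45 (SD ≈ 1.7), above the ≈ 0.3 (1.1) of the
emulated descriptives, while total mistakes (≈ 11.3, SD ≈ 13), RT
moments, and the remaining descriptives sit on target. The generator
prioritises the threshold geometry — the quantity the method is about —
over the second moment of one derived feature; tightening both at once
is not achievable under this (or, by the bound above, any
fraction-linear) size mapping.

Two-wave outcomes are drawn from explicit logistic links on the
participant's bad-performance count (the generator applies its own
threshold of 4) and age, with intercepts setting realistic incidences.
Default effects use odds ratios reported for fully adjusted models on
real data (1.29 for TUG decline, 1.114 for new falls, 1.15 for gait
speed decline, 1.067 for MMSE decline), so end-to-end runs resemble the
published magnitudes; because the truth is known, the regression
machinery can be validated by parameter recovery (see below). Wave-3
continuous values are then generated consistently with the drawn flags,
with mean TUG increments of 0.871 s (no bad performances) and 1.512 s
(at least one) between waves, preserving the ordering of the two group
slopes. About 20% of participants (rising mildly with age) miss wave 3
entirely; a further 0.8% have degraded streams (cycles with no presses,
or a press with a lost RT), emulating the small unplottable fraction of
real recordings.

What the generator does **not** emulate: survey sampling weights and the
healthy-participant selection of real cohort studies, practice or
time-on-task trends within the 4-minute session, post-NO-GO slowing and
other sequential effects, and realistic cross-correlations among the
clinical covariates beyond their age trends. Passing tests therefore
demonstrate that the pipeline measures what it claims on data with the
assumed structure — not that the published epidemiological estimates
would be reproduced on a real cohort.

Reproducibility: a configuration with a `seed` yields bit-identical
cohorts; generation is fully vectorised under a single seed rather than
split into per-participant substreams.

## Outcomes, models and inference conventions

The four binary outcomes are transitions between waves: TUG crossing
12 s (from below), gait speed crossing 100 cm/s (from above), a first
fall, and an MMSE drop of ≥ 2 points. `derive_outcomes()` flags them per
participant (NA where inputs are missing). Because each outcome is a
transition from a normal baseline, the default analysis population
*excludes* participants already past the cut-off at wave 1 rather than
coding them 0 (`baseline_impaired = "keep"` exposes the other reading;
on the generated data the choice moves sample sizes, not conclusions,
since the generator only draws decline events from unimpaired
baselines).

The model suite fits, for exactly one of the three candidate predictors
(bad performances, total mistakes, mistakes in good performances):
model 1 (predictor alone), model 2 (+ mean RT, SD RT), model 3
(+ age, sex, education), model 4 (+ anxiety, depression,
antihypertensives, diabetes, smoking, drinking problem, IPAQ), and
model 4a (+ baseline gait speed). Conventions, chosen where the
originating analyses leave room:

* **Wald inference** on the log-odds scale (`exp(beta ± 1.96·SE)`), the
  default of the major GUI statistics packages; CIs and p-values are
  exactly consistent with the stored estimates and the tests check the
  identity to 6 decimals.
* **Complete-case** analysis; no imputation.
* **Collinearity screen**: all pairwise Spearman correlations among the
  independents; the pass limit defaults to 0.7 (reported observed maxima
  in comparable analyses are ≈ 0.42, well clear), configurable and
  always reported.
* **Separation and rank deficiency fail loudly**, naming the column; no
  automatic penalisation. On small cohorts (a few hundred) the sparse
  binary covariates can separate in model 4 — that is a property of the
  data size, and the intended behaviour is the diagnostic error.
* **Nonparametrics**: paired comparisons use the signed-rank test
  (zeros dropped; exact only for ≤ 25 tie-free pairs, otherwise the
  normal approximation with continuity correction); independent groups
  use the Mann-Whitney U with the same exactness rule. Normality
  screening pairs the Lilliefors variant of the Kolmogorov-Smirnov test
  with Shapiro-Wilk (deterministically thinned to 5000 observations,
  its implementation limit).
* **No multiplicity correction** across the outcomes × predictors grid;
  each model is read at α = 0.05, matching the per-model reporting the
  suite mirrors.
* The per-group "slope" of TUG between two waves is simply the group
  mean of `TUG3 − TUG1` per wave interval, in seconds.

## Validation design and problem sizes

The test suite validates each layer against an independent route:

* mistake counting against a presentation-by-presentation loop
  (≥ 1000 cycles), the threshold rule against explicit-sum
  recomputation (1000 random size sets), and logistic odds ratios
  against the closed-form 2×2 cross-ratio (1000 random tables, 1e-6);
* parameter recovery: with a true bad-performance OR of 1.30 on TUG
  decline, 200 cohorts of n = 4000 give a mean model-1 OR within
  [1.25, 1.35] and 95% Wald coverage within [0.90, 0.98];
* null calibration: with the effect set to zero, 500 replicates of
  n = 1500 give predictor p-values indistinguishable from uniform
  (Kolmogorov-Smirnov at α = 0.01), and both nonparametric tests hold
  5% size within [0.03, 0.07] over 1000 replicates;
* threshold recovery: 10 default-configuration cohorts of n = 5000 must
  yield a mistake threshold of 4 in at least 8.

These sizes were chosen so the full suite completes in a few minutes
while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* The size-mapping exponent is a modelling choice documented above, not
  a recoverable quantity; analyses comparing against a dataset whose
  threshold was derived under a different drawing convention should pin
  the integer threshold rather than recompute it.
* The generator's covariates influence outcomes only through age and
  the latent deficit; adjusted models on synthetic data therefore shift
  estimates less between models 1 and 4 than real confounding would.
* Rendering is a presentation layer: layout logic (ranks, strata
  blocks, overlay scaling, big-spot flags) is contract and tested;
  marker geometry, palette endpoints and the overlay offset above the
  spot cloud are defaults, not contract.
* Attrition is missing-at-random given age; informative dropout is out
  of scope.
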