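# sartvis

Trial-level analysis of the Sustained Attention to Response Task (SART):
per-cycle feature extraction, a 2-SD spot-size rule for flagging *bad
performances*, an age-ordered multimodal visualisation of whole cohorts,
and a logistic-regression suite validating the extracted features as
predictors of four-year mobility and cognitive decline.

## The problem

The SART presents the digits 1–9 in a fixed repeating order (300 ms per
digit, 800 ms gap); the participant presses a key for every digit except
3. One pass through the nine digits is a *cycle*; an administration
repeats it 23 times — 207 presentations, 184 expected presses, 23
expected withholds. Large ageing studies administer it to thousands of
participants, then typically reduce each 4-minute record to a mean RT,
an SD of RT and a total mistake count.

Those averages hide the structure that matters clinically: a participant
with one catastrophic cycle and 22 clean ones looks identical, in
totals, to one with a dozen scattered slips. `sartvis` works on the raw
stream instead. For each cycle it computes the mistake decomposition
(omissions on GO digits + commission on the NO-GO) and the mean RT of
the correct actions, then draws each cycle as a spot — position = mean
RT, area ∝ (error fraction)², colour from light brown (0 mistakes) to
black (8) — with participants ordered by age along the x axis and
overlay curves for total mistakes, MMSE×3 and TUG×3.

The central statistic is the **bad-performance threshold**. Pooling the
spot sizes of all plottable cycles across the cohort (a cycle with no
correct action, or with a lost RT, has no spot), a cycle is a *bad
performance* when its size exceeds

```
cutoff = mean(size) + 2 · SD(size),   size = (n_mistakes / 9)^2
```

converted to the smallest integer mistake count whose spot exceeds the
cutoff — **4 of 9** under the calibrated default conditions. Per
participant this yields the candidate predictors `bad_performances`
(cycles at or above the threshold), `total_mistakes` and
`mistakes_in_good_performances`, which a suite of incrementally adjusted
binary logistic models (predictor alone; + RT features; + demographics;
+ clinical covariates; + baseline gait speed) compares as predictors of
four decline outcomes: TUG crossing 12 s, gait speed dropping below
100 cm/s, becoming a new faller, and an MMSE drop of ≥ 2 points.

Because the trial-level records of real ageing cohorts are
access-restricted, the package includes a calibrated synthetic-cohort
generator (raw streams + two-wave clinical tables) with known outcome
effect sizes, so the entire pipeline — including parameter recovery and
null calibration of the model suite — is testable end to end. See the
vignette (`vignettes/sart-thresholding.Rmd`) for the generative model
and every documented convention.

## Worked example

```r
library(sartvis)

cohort <- simulate_cohort(sart_config(n_participants = 1500, seed = 4))
fx <- extract_sart_features(cohort$streams)
fx$threshold
#> <sart_threshold> bad performance = >= 4 mistakes per cycle
#>   spot size mean 0.0136, sd 0.0576, cutoff 0.1287 (power 2)
#>   609 big spots across 221 participants
```

The 2-SD rule recovers the threshold of 4 mistakes per cycle; 221 of
1500 participants have at least one bad performance. Merging features
with the two-wave table and fitting the suite for TUG decline:

```r
tab <- merge_waves(cohort$cohort, fx$features)
#> merged longitudinal sample: 1196 of 1500 baseline participants
run_model_suite(tab, "bad_performances", "tug_decline")
#> <sart_model_suite> predictor bad_performances, outcome tug_decline
#>   model 1   OR 1.272 (1.161-1.395) p=2.663e-07  n=1159
#>   model 2   OR 1.277 (1.164-1.401) p=2.157e-07  n=1159
#>   model 3   OR 1.217 (1.103-1.343) p=9.423e-05  n=1159
#>   model 4   OR 1.218 (1.099-1.351) p=0.0001798  n=1159
#>   model 4a  OR 1.218 (1.098-1.350) p=0.0001874  n=1159
```

Each additional bad performance multiplies the odds of crossing the
12-second TUG cut-off by ≈ 1.22–1.28, and the effect survives full
covariate adjustment — the generator draws this outcome with a true OR
of 1.29 per bad performance, so the fits recover the planted effect.
The two bad-performance groups also separate on the raw TUG change:

```r
cmp <- compare_predictors(tab, "tug_decline")
round(cmp$group_slopes, 3)
#>  good   bad
#> 1.037 1.928
```

Rendering the visualisations:

```r
model <- build_plot_model(fx$metrics, fx$features, cohort$cohort,
                          fx$threshold, strata = "tug_w1",
                          strata_cut = 12)
render_sart_full(model, "sart_full.png")
render_sart_thresholded(model, "sart_big_spots.png")
```

A command-line front end over the same functions lives in
`inst/scripts/sart-pipeline.R` (subcommands `simulate`, `features`,
`plot`, `analyze`, `report`).

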