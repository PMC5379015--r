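# kinectcpt

Scoring engine for motion-tracked continuous performance tests (CPTs).

In a CPT a stream of letters is presented and the examinee responds to
every letter except the forbidden **X-stimulus**, for which the
response must be withheld. In the variant this package scores, the
response is a raise of the dominant hand recorded by a depth camera as
a ~30 Hz stream of 3-D hand-joint positions, instead of a key press.
Motion tracking yields, per trial:

* **RT** — reaction time, from stimulus onset to the moment the hand
  *starts* to rise (first sustained vertical-velocity crossing);
* **CT** — completion time, from movement onset until the hand returns
  to the rest position;
* **commission index** — for an X trial, the ratio of the hand-path
  length during the X window to the larger path length of the two
  neighbouring trial windows:

  $$CI_i = \frac{L(w_i)}{\max\{L(w_{i-1}),\ L(w_{i+1})\}}$$

  where $L(w)$ is the summed 3-D Euclidean path length over window
  $w$. Near 0 means clean inhibition; near 1, a full reaction to the
  forbidden stimulus; intermediate values expose *inhibited
  commissions* — movements begun and aborted, invisible to a keyboard.

A participant is summarised by median RT, median CT and median
commission index (48, 48 and 12 observations on a compliant
60-stimulus session), and those predictors are correlated with the
three factor scores of the SWAN rating scale (18 items scored 0–100;
items 1–9 inattention, 10–15 hyperactivity, 16–18 impulsivity), with
two-sided p-values from the t transform on n − 2 degrees of freedom.

The package covers the whole pipeline: stimulus-schedule generation and
validation (60-stimulus/3-minute and 360-stimulus presets), trajectory
IO/gap handling/segmentation, movement-onset detection, per-trial
scoring and event classification (omission, partial omission, multiple
reaction, premature reaction, commission, inhibited commission, correct
inhibition), participant summaries, SWAN factor scoring, the
correlation report, and a latent-trait cohort simulator with
minimum-jerk hand kinematics so everything is testable without
hardware. See the methods vignette
(`vignettes/kinect-cpt-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(kinectcpt)

# the 3-minute design: 60 letters, 12 of them X, ISIs of 2/3/5 s
sched <- cpt_schedule("revised-60", seed = 7)

# one simulated participant with high impulsivity, scored end to end
sim <- simulate_participant(
  sched,
  trait_profile(inattention = 70, hyperactivity = 60, impulsivity = 80),
  sim_config(seed = 7)
)
results <- score_session(sim$trajectory, sched)
table(results$event_class)
#>        full_reaction             omission     partial_omission
#>                   43                    4                    0
#>    multiple_reaction   premature_reaction           commission
#>                    1                    0                   12
#> inhibited_commission   correct_inhibition        invalid_trial
#>                    0                    0                    0

summarize_participant(results)[, 1:6]
#>   median_rt_s median_ct_s median_commission_index n_rt_obs n_ct_obs n_ci_obs
#> 1         0.5   0.7333333               0.7373093       44       44       12
```

This impulsive profile reacts fast (median RT 0.50 s), omits four
non-X trials, and fails to inhibit all twelve X-stimuli (median
commission index 0.74, all twelve classed as commissions).

A simulated 30-participant cohort, correlated against SWAN factor
scores:

```r
cohort <- simulate_cohort(30, sched, cfg = sim_config(seed = 7), seed = 7)
correlate_traits(cohort, score_swan(cohort))
#> CPT predictor vs SWAN factor correlations (pearson, n = 30)
#>
#> | Explanatory variables | Inattention | Hyperactivity | Impulsivity |
#> |---|---|---|---|
#> | RT | .25 (P=.19) | -.63 (P=.00) | -.36 (P=.05) |
#> | Commission | .10 (P=.60) | .14 (P=.45) | .93 (P=.00) |
```

The signs follow the programmed generative links: impulsive and
hyperactive profiles respond faster (negative RT correlations) and
impulsive profiles move more on X trials (positive commission
correlation). Use `tidy()` / `glance()` on the report for tibbles,
`autoplot()` for a tile map, and `render_report(..., "markdown")` for
the table above.

A full reproducible run (schedule → simulated cohort → scoring → SWAN →
report, with a checksummed manifest) is:

```r
run_pipeline(pipeline_config(out_dir = "cpt-run", n_participants = 30, seed = 1))
```

or from a shell via the bundled CLI:

```sh
Rscript inst/cli/cpt.R run --n 30 --seed 1 --out cpt-run
```

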