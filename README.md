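# kinescreen

Movement phenotyping for children's room-scale motion tracking, with
symptom-score inference.

When a child wears a head-mounted display and two hand controllers, their
spontaneous movement — pacing, fidgeting, stillness — is recorded as
time-stamped 3D positions. kinescreen turns those logs into quantitative
behavioral markers and relates them to standard symptom questionnaires, for
researchers studying hyperactivity, inattention, irritability and
aggression with objective movement data.

The pipeline has four stages:

1. **Tracking** — read/validate three-device logs (`t,device,x,y,z` CSV or
   JSON-lines) on a uniform grid (default 0.5 s over 300 s), with linear
   interpolation of short dropouts.
2. **Features** — seven kinematic variables per session, from per-step
   Euclidean displacements `d_k = ‖p_{k+1} − p_k‖`:
   average speed (mean of `d_k/Δt` across head and hands), acceleration
   intensity (mean `|v_{k+1} − v_k|/Δt`), total distance (Σ `d_k`),
   area occupied (convex hull of the head's floor-plane track), mean
   hand-to-head distance, movement-bout frequency (onsets of steps whose
   max-device displacement exceeds `threshold_1`, per minute), and time
   spent still (steps below `threshold_2`).
3. **Scales** — item-sum scoring of an 18-item ADHD rating scale
   (hyperactivity + inattention), the 7-item Affective Reactivity Index
   (6-item symptom total) and the 23-item Reactive-Proactive Aggression
   Questionnaire, for parent and child informants — eleven measures.
4. **Inference** — Pearson correlation screen of all 7 × 11 pairs
   (`t = r√(n−2)/√(1−r²)`, n−2 df), then backward stepwise OLS per outcome
   (removal `p > .10`, re-entry `p < .05`) with post-selection variance
   inflation factors (`VIF_j = 1/(1−R²_j)`, flagged at 5).

A latent-trait simulator generates full synthetic cohorts — trajectories
from a still/moving bout process plus ordered-categorical item responses,
both driven by one per-child trait — so everything is testable and
calibratable without clinical data. See the methods vignette
(`vignettes/movement-phenotyping.Rmd`) for models, parameter choices and
limitations.

## Worked example

```r
library(kinescreen)

cohort   <- simulate_cohort(cohort_config(n = 45, seed = 2026))
features <- extract_features(cohort$sessions)
scores   <- score_scales(cohort$items)

features
#> # A tibble: 45 × 8
#>   subject_id average_speed acceleration total_distance area_occupied
#>   <chr>              <dbl>        <dbl>          <dbl>         <dbl>
#> 1 S001              0.213        0.0812          192.           7.57
#> 2 S002              0.217        0.121           195.           8.14
#> 3 S003              0.0505       0.0422           45.4          1.41
#> # ℹ 42 more rows ...
```

Subject S003 barely moves (0.05 m/s, 45 m in five minutes, 1.4 m² of floor
used); S001 and S002 cover four times the distance over 8 m². Running the
inference:

```r
inference <- run_inference(features, scores)
inference
#> <vr_inference> 45 subjects, 11 measures, 77 correlation tests (55 significant at alpha=0.05)
#>   stepwise models: 11 of 11 non-empty

inference$models$adhd_hyperactivity
#> Backward stepwise model for adhd_hyperactivity
#>   R^2 = 0.497, n = 45
#>           term estimate   p.value vif
#>  area_occupied    1.339 6.453e-08   1
```

In this simulated cohort, hyperactivity is best explained by a single
spatial predictor: each additional m² of floor-plane area occupied adds
about 1.3 points of parent-rated hyperactivity, explaining half the score
variance; a VIF of 1 says the retained model is free of collinearity. The
screen view shows the strongest marginal associations, e.g. average speed
against parent-reported aggression (r = 0.77):

```r
dplyr::filter(tibble::as_tibble(inference$screen), significant) |> head(3)
#> # A tibble: 3 × 7
#>   feature       measure                 n     r        p significant computable
#> 1 average_speed rpq_total_parent       45 0.765 9.64e-10 TRUE        TRUE
#> 2 average_speed rpq_reactive_parent    45 0.739 6.68e- 9 TRUE        TRUE
#> 3 average_speed adhd_total             45 0.738 7.51e- 9 TRUE        TRUE
```

`tidy()`/`glance()` summarize fits, `autoplot()` draws sessions, screens and
models, and `synthesize_cohort()` / `analyze_cohort()` run the same pipeline
against directories of files, writing `descriptives.csv`,
`correlations.csv`, `models.csv`/`models.json`, a selection `trace.log` and
a `run_manifest.json` that records version, config hash, seed, thresholds
and subject accounting. `inst/scripts/kinescreen.R` wraps the three stages
(`synth`, `features`, `analyze`) for shell use.

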