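---
title: "Movement phenotyping from room-scale tracking: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement phenotyping from room-scale tracking: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinescreen)
```

## The problem

Head-mounted displays and hand controllers record a child's position many
times a second while they move freely around a virtual room. Those traces
carry information about hyperactivity, inattention, irritability and
aggression that questionnaires measure only indirectly, through an
informant's memory. kinescreen turns raw three-device position logs into
seven interpretable kinematic variables, scores the standard symptom
instruments from item-level responses, and links the two with the classical
screening-then-selection analysis used in small clinical cohorts: a Pearson
correlation screen over every feature-measure pair followed by backward
stepwise linear regression per outcome with variance-inflation-factor (VIF)
diagnostics.

Because clinical tracking data of this kind are rarely shareable, the
package also ships a latent-trait cohort simulator. Every stage of the
pipeline is exercised, calibrated and tested against synthetic cohorts whose
generating truth is known.

## Data model

A *session* is one child's trial: three position series (head, left hand,
right hand) on a shared uniform time grid. Coordinates are meters in a y-up
frame; the floor plane is (x, z). The grid has `floor(duration/dt) + 1`
points with `t = 0` the first scheduled sample; the defaults, `dt = 0.5` s
over 300 s, give 601 samples per device. Raw log rows are snapped to the
nearest grid time (ties toward the earlier point; the last row wins within a
cell). Interior gaps of at most `max_gap = 2` consecutive missing samples
are filled by per-coordinate linear interpolation; longer gaps or missing
boundary samples fail validation, and the pipeline excludes such subjects
with a logged reason (or aborts under `strict = TRUE`). The gap policy is
this package's convention: with 0.5 s sampling, interpolating up to one
second of dropout is innocuous for the session-level aggregates computed
here, while anything longer starts to bias the stillness and bout variables.

Tracking logs are CSV (`t,device,x,y,z`) or JSON-lines with the same keys.
Writing uses `%.17g`, so write-then-read reproduces a session bit-exactly;
the reader converts numerals with R's exactly-rounded parser for the same
reason.

## The seven kinematic variables

All variables are built from per-step Euclidean displacements
`d_k = ||p_{k+1} - p_k||` (forward differences on the grid), per device.

* **average_speed** (m/s): mean over the three devices of the mean step
  speed `d_k / dt`. Devices are weighted equally so that hand and head
  movement both count.
* **acceleration** (m/s²): mean over devices of `|v_{k+1} - v_k| / dt` with
  `v_k = d_k/dt`, i.e. the magnitude of speed change — a non-negative
  intensity measure, zero for constant-speed motion of any direction.
* **total_distance** (m): sum over devices of the summed displacements.
  Note the identity `total_distance = 3 * average_speed * (L-1) * dt` when
  all tracks have equal length, which matters for model selection (below).
* **area_occupied** (m²): area of the 2D convex hull of the head's
  floor-plane projection (shoelace formula on `grDevices::chull`); zero for
  fewer than `hull_min_points = 3` distinct points or collinear points. The
  head is used as the proxy for body position; a hull is the standard
  occupancy summary.
* **hand_head_distance** (m): per-sample mean of the two hand-to-head
  distances, averaged over the session.
* **movement_frequency** (events/min): a step is *moving* when the largest
  displacement across the three devices exceeds `threshold_1`; an event is a
  transition from non-moving (or session start) into movement. Counting bout
  onsets, not moving samples, keeps this variable distinct from
  (1 − stillness).
* **time_spent_still** (s): `dt` times the number of steps whose largest
  across-device displacement is at most `threshold_2`.

`threshold_1 = 0.05` m and `threshold_2 = 0.02` m per 0.5-s step are package
defaults (0.10 and 0.04 m/s expressed as speeds): small enough that
deliberate locomotion always registers, large enough that tracking jitter of
a few millimetres does not. Both are mandatory configuration entries echoed
into every run manifest, because the frequency/duration variables are
meaningless without them. The max-over-devices rule means any limb movement
breaks stillness.

## Instrument scoring

Three instruments are scored as plain item sums, with subscale membership
held as configuration (`scale_maps()`) rather than code:

* the 18-item ADHD rating scale (items 0–3), parent-rated, with the
  standard alternation of inattention (odd positions) and hyperactivity
  (even positions) as the default map — 0–27 per subscale, 0–54 total;
* the 7-item Affective Reactivity Index (items 0–2), parent and child
  informants; the irritability total sums the first six symptom items
  (0–12), excluding the impairment item, which matches how the published
  6-item symptom total is used — `ari_items_in_total = 7` includes it;
* the 23-item Reactive-Proactive Aggression Questionnaire (items 0–2), both
  informants, split 11 reactive / 12 proactive per the published instrument.

Eleven measures result: three ADHD scores, two ARI totals, six RPQ scores.
`score_descriptives()` reports the sample mean and n−1 SD per measure.

## Inference

`correlation_screen()` computes Pearson r with two-sided p-values from the
t distribution on n−2 degrees of freedom for all 7 × 11 pairs, flags
`p < alpha` (default 0.05), and reports pairs with fewer than three complete
cases or zero variance as non-computable instead of dropping them. No
multiplicity correction is applied — this is a screen, and the number of
tests is attached to the result.

`backward_stepwise()` starts from the model with all predictors and
alternates removal (drop the predictor with the largest p above
`p_remove = 0.10`) with re-entry (add the excluded predictor with the
smallest add-one p below `p_enter = 0.05`), until stable. This reading —
backward elimination with re-entry — is the common SPSS-style hybrid in
which both an entry and a removal criterion are meaningful; `p_enter = 0`
recovers pure backward elimination. Determinism is guaranteed by fixed
tie-breaking (column order) and a step limit. Empty final models are a valid
outcome, flagged and rendered as a dash row in the model table. Every
decision is logged in a trace so the selection path can be audited.

Three degenerate-design rules:

* if `n` is too small for the full model, selection starts from the largest
  fittable model, taking predictors by descending marginal |r| (trace action
  `trim`);
* exactly collinear predictors cannot coexist in one fit, so the later
  column of an aliased pair is set aside at the start (trace action
  `alias`) while remaining eligible for re-entry. This arises by
  construction on clean synthetic sessions, where total distance is exactly
  proportional to average speed; on real data with dropouts the two merely
  correlate strongly and instead produce large preliminary VIFs;
* `vif()` returns 1 for a single predictor by convention and `Inf` under
  perfect collinearity.

Multicollinearity is assessed *after* selection: VIFs
(`1 / (1 - R²_j)` from regressing predictor j on the rest) are reported for
the retained set and flagged at `vif_flag = 5`; the full-model VIFs computed
before selection are kept in the fit for transparency. Plain (not adjusted)
R² is reported, matching how such models are usually summarized in this
literature.

## The cohort simulator

One scalar latent trait `h ~ N(0, trait_sd²)` per child — hyperkinesis, in
the package's shorthand — drives both movement and symptoms. This
single-trait structure is deliberately minimal: it is the simplest generator
consistent with one or two kinematic variables explaining each outcome, and
it makes planted effects easy to reason about.

**Trajectories.** A two-state (still/moving) Markov bout process runs on the
grid: per-step hazards `still→moving` and `moving→still` start at 0.08 and
0.10 (mean bouts of ~6 s and ~5 s, about 45% of time in motion at `h = 0`)
and shift with `h` on the logit scale (`bout_loading = 0.5`), so restless
children start more and stop fewer bouts. While moving, the head walks
toward uniformly drawn waypoints in a 4 m × 3 m room at speed
`speed_base * exp(speed_loading * h)` (0.15 m/s, loading 0.4); positions are
clamped to the room, which bounds the occupied area by the room area — a
tested invariant. Hands ride at a per-subject arm length (0.45 ± 0.04 m)
in directions that diffuse only while the body travels, and all devices
receive 5 mm Gaussian tracking jitter. Two subject-level residuals
independent of `h` — a log-speed residual (SD 0.3) and a bout-hazard logit
residual (SD 0.4) — represent movement style unrelated to symptoms; without
them the feature-trait correlation saturates near 0.95 and every
feature-score correlation lands implausibly high.

**Items.** Each item is drawn from an ordered-categorical model: a latent
value `item_loading * h + item_difficulty` plus standard logistic noise is
cut at equally spaced thresholds into the item's range. Loadings default to
0.9 per instrument. Difficulties (−0.9 ADHD, −1.0 ARI, −0.45/−2.9 RPQ
reactive/proactive) were set once so that the synthetic score means sit near
the values typically reported for mixed clinical/community child cohorts on
these instruments; proactive aggression needs its own, much lower location
because it is rarely endorsed. Participant-reported items get 1.5× logistic
noise, so parent reports track the trait more tightly — mirroring the common
finding that externalizing symptoms are better observed by parents.

Under the defaults, loaded feature-measure pairs correlate at roughly
0.3–0.65 in 45-child cohorts, the hand-to-head distance behaves as a null
feature, and movement frequency is nearly uncorrelated with symptoms
marginally (its onset rate is a ratio of the two hazards, which move in
opposite directions) — so the generator produces both strong, weak and null
relationships for the screen to sort out.

**Calibration.** `calibrate_cohort_config()` rescales the two movement
loadings by a common factor λ to hit a target population feature-score
correlation: it simulates calibration cohorts over a λ grid, smooths with a
quadratic fit through the origin (r(0) = 0 by construction), and inverts.
The tests use it to plant ρ\* = 0.5 between average speed and hyperactivity
and verify recovery across replicate cohorts.

**What the simulator does not emulate.** Bout dynamics are piecewise-linear
waypoint walks, not biomechanics; there is no object interaction, no
avatar-driven behaviour, no age or sex structure, and a single trait rather
than separable hyperactivity/irritability/aggression dimensions. Passing
tests therefore demonstrate that the pipeline's estimators and selection
procedure behave correctly when their assumptions hold — not that the
specific defaults match any real cohort's kinematics, for which no public
trajectory summaries exist to anchor them.

## Numerical and testing choices

* All randomness flows through explicit integer seeds; a cohort is
  byte-reproducible from its config, and `synth → analyze` twice yields
  byte-identical report files.
* Feature implementations are vectorized one-pass computations, tested
  against naive-loop oracles (including an independently hand-written
  monotone-chain hull) to 1e−9 relative tolerance on random sessions.
* Pearson p-values are checked against the exact 2-df closed form
  (r = 0.8, p = 0.2 on a four-point fixture) and the covariance formula to
  1e−12; OLS against the normal equations to 1e−8; VIF against its k = 2
  closed form (sample correlation 0.9 → 5.263) and `car::vif`.
* Operating characteristics are verified by simulation at moderate sizes
  chosen to keep the default suite fast while leaving Monte-Carlo error
  well inside the asserted margins: stepwise recovery of a planted
  predictor (partial R² ≈ 0.33, n = 500, 100 replicates, ≥95% retention),
  screen false-positive rate under an all-loadings-zero generator
  (13 cohorts of n = 400, ~1000 tests, 99% binomial band around 0.05), and
  effect recovery after calibration to ρ\* = 0.5 (100 cohorts of n = 400,
  sample r within ±0.1 in ≥95%).
* The all-noise behaviour of stepwise selection is recorded rather than
  asserted (empty final models in roughly half the replicates at these
  settings): the type-I behaviour of p-threshold stepwise has no clean
  reference value.

## Known limitations

Selection inference is classical: the reported coefficient p-values and R²
are conditional on the selected model and carry the usual post-selection
optimism; the package reports the selection trace rather than attempting
corrections the original analysis did not use. The screen is unadjusted by
design. The simulator's defaults are plausibility choices, not fits to data.
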