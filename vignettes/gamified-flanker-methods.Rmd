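---
title: "Methods: an adaptive, gamified flanker assessment and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an adaptive, gamified flanker assessment and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankgame)
```

## The assessment

The flanker task asks a child to press the button matching the direction of
a central target (a fish, in child-friendly versions) while ignoring
flanking distractors that point the same way (congruent) or the opposite
way (incongruent). The *conflict effect* — slower and less accurate
responding on incongruent trials — is the task's signature measure of
inhibitory control, and its preservation is the key psychometric question
when the task is redesigned.

`flankgame` implements two administrations of the same 50-trial design
(8 practice + 42 test trials, 67:33 congruent:incongruent, 450 ms
inter-trial interval):

* **Traditional**: every test trial has a fixed 1700 ms response deadline.
  A response in the wrong direction is a *commission* error; no response
  within the deadline is an *omission*. Both count as errors.
* **Gamified**: the same trial structure wrapped in reward/penalty
  feedback (a treasure jar that gains one item per correct response and
  loses one, floor zero, per error) and an adaptive response window. The
  42 test trials are partitioned into 14 hidden levels of 3 trials,
  aligned with the staircase rule below.

## The staircase controller

Difficulty adaptation is a one-up deadline staircase on the response
window: after `streak_target = 3` consecutive correct responses the window
shrinks by `step_ms = 500`; any error or timeout resets the streak and
leaves the window where it is ("stagnation"), so the task converges toward
the tightest deadline a child can sustain. Parameters, all in
`staircase_config()`:

| parameter | default | units | why |
|---|---|---|---|
| `start_window_ms` | 8000 | ms | Opening window. Must exceed the traditional 1700 ms cap, since preschool mean RTs under no time pressure run to ~2000 ms; 8000 ms makes early timeouts essentially impossible while leaving 14 possible decrements (to 1000 ms) within the test block. Every simulated report records the value used. |
| `step_ms` | 500 | ms | The published decrement size. |
| `streak_target` | 3 | trials | Consecutive correct responses per decrement; also the hidden-level size. |
| `floor_ms` | 500 | ms | Guard against non-physical windows under unusual configurations; never reached at the defaults. |
| `mode` | `"streak"` | — | Whether the streak counter rolls across level boundaries (default) or decrements are decided only at 3-trial block boundaries (`"block"`). The two differ only when an error splits a level; the rolling reading matches a consecutive-correct rule, and we expose the block reading without asserting which the original implementation used. |

Two consequences worth noting: the window trajectory is monotone
non-increasing with every change exactly −500 ms, and 42 straight correct
responses end at `8000 − 14 × 500 = 1000` ms.

The practice block uses the fixed 1700 ms window in both conditions; the
staircase engages only in the test block. "Clearing" practice is defined
here as ≥ 6 of 8 correct; a failed block is re-presented (same eight
trials) up to twice, after which the session proceeds regardless. Repeated
practice passes are logged with a repeat counter and never enter test
metrics. A response arriving after the deadline is coerced to an omission
— the deadline defines omission — rather than scored by its direction.

## Trial scheduling

The 67:33 ratio over 42 trials is realized as exactly 28 congruent / 14
incongruent by largest-remainder rounding; left/right targets are split
50:50 within each congruency class (odd counts give the extra trial to
LEFT). The order is shuffled under the config seed subject to a run-length
constraint — at most 3 consecutive trials of the same congruency or the
same target direction — enforced by rejection-resampling, staged as:
resample the congruency order until its constraint holds, then resample
the within-class direction assignment until the direction constraint
holds. (A joint resample of the full shuffle satisfies both constraints
only about 5 times in 10^5 draws at the 28:14 split; the staged version
needs ~1,200 + ~20 cheap draws.) Congruency order is randomized globally,
not within levels. Schedules are bit-for-bit reproducible from
`(config, seed)`.

## The synthetic respondent model

No child data ship with the package; a generative respondent model stands
in for them. It is deliberately simple — chosen for closed-form means and
easy truncation, and making no claim of psychological validity beyond the
features it is calibrated to reproduce. Per trial:

1. with probability `lapse` the child ignores the trial (omission);
2. otherwise `RT = t0 + exp(mu + delta_incong·[incongruent] + sigma·z)`,
   `z ~ N(0,1)` — a shifted lognormal with a multiplicative congruency
   slowdown;
3. an RT beyond the allotted window is an omission; a timely response is
   wrong with probability `err_cong` or `err_incong`.

In the gamified condition a log-scale `slow_gamified` is added to `mu`:
with an 8000 ms opening window there is no time pressure, and children
(especially older ones, who attend to the narrative) respond more slowly
— which is also what makes multiplicative congruency penalties produce the
much larger gamified conflict-RT gap observed with generous windows.

The `"paper2024"` preset fixes one parameter row per age (3/4/5). The
rows were tuned once — by lognormal tail arithmetic, then one confirming
simulation — so that a mixed-age cohort (default 30/30/40%, i.e. 6/6/8 at
n = 20) run through the *actual engine* reproduces the feasibility-study
profile, and then frozen as constants:

* under the fixed 1700 ms deadline, 3-year-olds average ≈ 23 omissions of
  42 test trials (4-year-olds ≈ 5, 5-year-olds ≈ 2), dragging their
  accuracy toward floor;
* under the staircase the same 3-year-olds average < 2 omissions — the
  "rescue" that motivates adaptive deadlines;
* cohort congruent accuracy in the traditional condition lands near 68–69%;
* gamified RT means land near 1650 (congruent) and 2050 ms (incongruent),
  a conflict-RT gap of ≈ 400 ms.

Child-level heterogeneity: a latent ability score mixes a standardized age
gradient (loading 0.75) with an individual component; the individual part
shifts `mu` (−0.25 log units per SD) and both error logits (−0.70 per SD),
and the congruency penalty itself varies between children (SD 0.12).
Synthetic verbal and matrix-reasoning covariates are WPPSI-style scaled
scores (mean 10, SD 3) loading 0.85 on the same ability, which places
metric–covariate correlations in the 0.6–0.85 band at n = 1000 (they are
*not* asserted at n = 20, where sampling noise dominates). Enjoyment is a
per-child latent (mean ≈ 3, SD ≈ 2.2) discretized to the 1–5 pictorial
scale, shifted upward (mean +2.0) for the gamified condition; the
forced-choice preference is multinomial 0.80/0.15/0.05
(gamified/traditional/no answer). All randomness flows through one seed
with per-child sub-streams, so enlarging a cohort never perturbs existing
children.

What the model does *not* emulate — and what passing tests therefore do
not show about real children: sequential effects (post-error slowing,
fatigue, learning within the session), RT–accuracy trade-off strategies,
any causal effect of the reward feedback on performance, and the
between-child stability of *conflict scores*. On the last point: with only
14 incongruent trials, binomial trial noise in a session's conflict score
is large relative to plausible between-child spread, so simulated
cross-condition conflict-score correlations stay near 0.1–0.2 even though
the observed study reported 0.635 (RT); the model reproduces
cross-condition correlations of the component metrics (≈ 0.67 for
incongruent accuracy, ≈ 0.75 for incongruent RT) but not of their
differences. Gamified congruent accuracy sits near 82% rather than 88%:
the commission-rate parameters are shared between conditions, and raising
gamified accuracy further would push traditional accuracy above its
calibration band. We prioritized the omission structure and the
traditional accuracy band, which carry the feasibility argument.

## The statistics battery

`run_study_analysis()` reproduces a within-subject feasibility analysis:
per-condition congruent-vs-incongruent paired t tests (accuracy and
correct-trial RT, signed so positive = conflict effect), cross-condition
Pearson correlations with Fisher-z 95% intervals, gamified-vs-traditional
paired tests on conflict scores, covariate correlations, a 2×2 mixed
ANOVA on enjoyment (order between, condition within, partial η²), and a
chi-square test of preference × order. Conventions, fixed once:

* two-sided tests, α = 0.05, exact-t critical values (t₀.₉₇₅(19) = 2.093);
* paired Cohen's d is mean difference / SD of differences (≡ t/√n); the
  pooled-SD variant is out of scope;
* RT means use correct trials only (commission RTs index a different
  process and omissions have none); `rt_include_commissions` exists as a
  sensitivity flag, and this is declared as our default, not asserted as
  the original study's;
* percentages are carried 0–100; everything is computed at full precision
  and rounded (half away from zero, 2 decimals) only when rendered;
* no multiple-testing correction (none was applied in the study design
  this mirrors); reports state the number of tests run.

Degenerate inputs are defined rather than left to chance: identical paired
samples return t = 0, d = 0, CI [0, 0]; a congruency class with no correct
trials yields an absent (NA) RT mean, never a silent zero, and RT-based
paired comparisons then drop that child pairwise, reporting the n used;
single-session cells report an absent SD; empty age × condition cells are
absent, not zero.

## Problem sizes and reproducibility

The shipped checks run the engine end-to-end at sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances while finishing in a
few minutes on one core: 200 children per cell for the omission-rescue
contrast, 500 children for cohort accuracy calibration, 100 seeded n = 20
cohorts for conflict-effect sign stability, 10^4 random outcome sequences
for the staircase endpoint oracle, and 500 replicates at n = 1000 for
Fisher-interval coverage. `scripts/acceptance.R --seed S --out f.json`
recomputes every headline quantity from scratch under a single seed.

## Known limitations

The respondent model is a test fixture, not a cognitive model; its age
presets encode one internally consistent scenario, not population norms.
The staircase never re-widens the window (the published rule is stagnation,
not reversal), so it measures a descent limit rather than an equilibrium
threshold. The chi-square of preference × order is validated against
oracles but cannot be checked against the original statistic, whose full
contingency table was never printed. Printed summaries are reproduced only
where internally consistent: one published conflict-accuracy SD is
inconsistent with its own SE (SD 11.71 with SE 3.28 at n = 20 implies
SD ≈ 14.67), and we do not chase such residues.
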