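---
title: "Reward-related quality of life from experience sampling data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-related quality of life from experience sampling data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqol)
```

## The problem

The Experience Sampling Method (ESM) collects short self-report
questionnaires ("beeps") at semi-random moments in daily life, typically 10
times a day over 6 days. Each beep records momentary mood on 7-point Likert
items and the current context: who the person is with, what they are doing,
and where they are. Aggregate momentary quality-of-life scores summarize how
a person felt, but say nothing about *which situations* are worth seeking
out or avoiding — the information a clinician and patient need to steer
daily-life choices.

The reward-related quality of life statistic (rQoL) fills that gap at the
moment level. The intuition: reward efficiency is high when a person spends
their frequent, habitual contexts in a better-than-usual mood, and reserves
worse-than-usual moods for contexts they rarely occupy. Both halves of the
statistic come from the person's own data, so the score is inherently
person-referenced.

## The statistic

For subject $i$ at moment $j$:

$$\mathrm{rQoL}_{ij} = z\mathrm{PA}_{ij}\,\bigl(cp(BS_{ij})_i - c\bigr)$$

* **Positive affect** $\mathrm{PA}_{ij}$ is the arithmetic mean of the four
  mood items *cheerful*, *satisfied*, *relaxed*, *enthusiastic* (1–7). The
  mean keeps the score on the item scale; it is the standard ESM aggregation
  for a small homogeneous item set.
* **Centering.** $z\mathrm{PA}_{ij} = \mathrm{PA}_{ij} - \overline{\mathrm{PA}}_i$
  subtracts the subject's own mean, so positive values mean
  better-than-usual mood. `center_pa()` centers only by default; a
  divide-by-SD variant sits behind `standardize = TRUE` because some users
  expect a z-score, but the reward function as defined uses plain centering
  and that is what `compute_rqol()` does.
* **Behavior settings.** The context of a beep is encoded as a categorical
  *behavior setting* at one of three granularities: activity only
  (`W`, 6 cells), persons × activity (`WW`, 36 cells) or persons ×
  activity × location (`WWW`, 216 cells). The raw questionnaire offers
  8 person and 8 activity options; these are collapsed to 6 each
  (partner → resident family, colleagues → acquaintances,
  resting + nothing, household/groceries + hygiene) so that per-subject
  frequency distributions have a workable number of cells. The pre-collapse
  cross including a 3-block time-of-day indicator has
  $3 \times 8 \times 8 \times 6 = 1152$ cells (`context_space(FALSE)`),
  which is far too fine for per-person frequency work — the reason the
  collapsed spaces exist. Time of day is not part of any setting key.
* **Cumulative proportion** $cp$. Within the analysis unit, the occurrence
  proportions of the occupied settings are sorted in ascending order and
  cumulated; a moment's $cp$ is the cumulative mass at its setting. Rare
  settings therefore get small $cp$, and the most frequent setting always
  reaches 1. The cut point $c$ (default 0.5) splits the large set of
  infrequent situations from the small set of frequent ones; 0.5 is the
  value found sensitive enough for meaningful detection, and
  `compute_rqol(cutoff =)` exposes it for exploration (0.2–0.5 are the
  plausible alternatives).

Sign structure: rQoL is positive when a frequent setting ($cp > c$) carries
above-average affect, or a rare setting carries below-average affect. With
Likert affect, $|z\mathrm{PA}| \le 6$, so $|\mathrm{rQoL}| \le 3$ at $c = 0.5$.

**Ordering and ties.** The cumulation direction is a genuine design choice:
cumulating in ascending-frequency order is the only direction under which
"frequent setting + good mood" scores positively, which is the stated
meaning of the statistic. Settings tied on frequency all receive the
cumulative value at the end of their tied block; otherwise an arbitrary rank
order among ties would change scores. A corollary worth knowing: if *every*
occupied setting is tied (e.g. each occurs once), every moment has $cp = 1$.

**Analysis unit.** For real subjects, centering and the frequency table use
the subject's full valid-beep series. Inside resampling experiments each
resampled set *is* the virtual subject, so both are recomputed within the
replicate. `compute_rqol(unit = "subject")` / `unit = "pool"` select the two
behaviors explicitly.

## Validity and inclusion

A beep is **valid** only when the whole questionnaire was completed: the
completion flag, all four affect items, the momentary-QoL item and all three
context fields. Subjects enter analysis with at least `min_valid = 20` valid
beeps — one third of the 60-beep protocol (`inclusion_threshold()`); the
threshold is a parameter because protocols differ in length. Invalid beeps
are kept (flagged) on load and dropped only at filtering, so compliance can
still be reported.

Multi-checked context cells are reduced to one category per domain by a
fixed precedence order (e.g. partner > resident family > … > nobody;
active options outrank passive ones). This is a package convention — the
setting definitions presuppose a single category per domain, and no
canonical reduction rule exists.

## Monte Carlo experiments

`resample_spec()` fixes the design: a grid of sample sizes (default 20 to
10,000), 1000 replicates per size, a master seed, and the replacement rule.
Under `"auto"`, draws are without replacement up to the pool size and with
replacement beyond it; `"always"` is a pure bootstrap. The bootstrap is the
better emulation of virtual-subject resampling from a pooled seed dataset
(a without-replacement draw of nearly the whole pool mechanically captures
almost every setting, flattening the saturation curve), and it is what the
shape checks in the test suite use; `"auto"` remains the default because a
subsample is the natural reading of "drawing N beeps" at small N.

Four experiments characterize the statistic:

1. **Unique-setting saturation** (`experiment_unique_settings`): the number
   of distinct settings in a replicate, versus N. The mean curve has three
   phases — steep rise at small N, slower growth, then a plateau at the
   pool's occupied-setting count. Richer definitions saturate later (`WWW`
   needs thousands of beeps; `W` saturates near 100).
2. **rQoL spread** (`experiment_rqol_spread`): mean, SD, min and max of
   rQoL within each replicate. Replicate means sit at the neutral point 0
   when affect is independent of context; the min–max range widens with N
   up to roughly 500 beeps for `WWW`/`WW` and is essentially saturated by 60
   for `W`.
3. **Subject percentiles** (`experiment_subject_percentiles`): subjects are
   ranked by occupied-`WWW`-setting count (contextual variability) and the
   5th/50th/95th percentile subjects (nearest rank — interpolation would
   select nonexistent subjects) are resampled from their own beeps at
   N = 20…100. Low-variability subjects give flat, reliable curves at small
   N; high-variability subjects need larger samples.
4. **PA–rQoL correlation** (`experiment_pa_rqol_correlation`): Pearson r
   between PA and rQoL within each replicate. Correlations are weak on
   average with a replicate spread that narrows as N grows — the evidence
   that rQoL is not merely positive affect re-scaled.

Summary rows report `mean`, `sd`, `sem`, `min`, `max` over replicates. The
`sem` column follows the convention $\mathrm{SD}/\sqrt{N}$ with $N$ the
*sample size*, matching how such tables are conventionally printed for this
statistic. For comparing a replicate mean against a theoretical value, the
correct Monte Carlo error is instead $\mathrm{SD}/\sqrt{\mathrm{replicates}}$,
and that is what the package's tests use.

Replicate RNG streams are derived by hashing (experiment, size, replicate)
with the master seed, so results are byte-identical on rerun and extending
the size grid does not perturb existing replicates. A replicate whose
statistic fails (e.g. a zero-variance correlation) is skipped with a
warning; more than 10% failures at any size aborts the experiment.

## The synthetic generator

`generate_dataset()` emulates the statistical profile of a 23-subject
severe-mental-illness ESM seed sample, so that every experiment runs
without clinical data:

* **Beeps per subject**: truncated normal, mean 48, SD 9, range 20–60
  (the protocol maximum), plus a `missing_rate` (default 0.1) share of
  invalid beeps with partially blanked answers.
* **Contexts**: each subject receives a support of `WWW` cells drawn from a
  shared Zipf popularity ranking over the 216 cells (exponent 1.0), so
  frequent cells — being home, resting, with resident family — recur across
  subjects. Within a subject, cells follow a Zipf distribution with
  exponent 0.6. The subject's *target occupied count* is drawn
  log-uniformly from `subject_variability_range` (default 5–28) and the
  support size is solved from the occupancy identity
  $E[\mathrm{occupied}] = \sum_k\bigl(1-(1-p_k)^n\bigr)$. Under the default
  configuration the pooled data occupy ≈110–130 of the 216 cells and
  subject-level occupied counts span roughly 5 to 28 — a skewed frequency
  distribution with a small set of frequent situations, as observed in
  restricted daily lives.
* **Affect**: a latent subject mean (normal around 4.0) plus within-subject
  noise; the four items add independent noise (SD 0.9) and are rounded and
  clipped to 1..7. The latent SDs are set about 5% above the observed
  targets (overall SD 1.41, between-subject SD 0.99) because rounding and
  clipping shrink observed dispersion; the inflation factors were fixed by
  one-off calibration. The momentary-QoL item loads on the same latent
  affect with noise sized to give a moderate PA correlation (~0.3).
* **Reward effect**: with `reward_effect` $e \ne 0$, the latent affect of a
  beep is shifted by $e\,(cp - 0.5)$ of its `WWW` setting (cp computed from
  the subject's own realized beeps). `generate_null_dataset()` forces
  $e = 0$; `generate_reward_dataset()` is the positive control. The
  regression of $z\mathrm{PA}$ on within-person centered $(cp - 0.5)$
  (`estimate_reward_effect()`) recovers $e$ with roughly 5–10% attenuation
  from the Likert rounding/clipping, comfortably within 20%. The predictor
  is centered within person because between-subject differences in mean cp
  would otherwise bias the pooled slope.

What the generator does **not** emulate: diurnal cycles and temporal
autocorrelation of affect, device-specific missingness patterns, and any
semantic coupling between affect and *particular* contexts beyond the
frequency-rank mechanism. Passing tests on synthetic data therefore show
that the statistic and its sampling behavior are implemented correctly
under the stated generative assumptions — not that real diary data satisfy
those assumptions.

## Null behavior and Monte Carlo error

Under affect–context independence, each replicate's mean rQoL estimates the
within-replicate covariance of centered affect with cp, whose expectation is
0. One subtlety matters for testing: all replicates drawn from the *same*
pool share that pool's finite-sample affect–context covariance, of order
$1/\sqrt{\mathrm{pool\ size}}$ (~0.01 here), which does not shrink as
replicates accumulate. The package's null-neutrality test therefore spreads
its 1000 replicates over 10 independently generated pools and computes the
Monte Carlo standard error across pool-level averages — the correct error
for the full generative pipeline. A single-pool average is still reported by
`scripts/acceptance.R` (its magnitude stays ~0.01, i.e. 0.00 at printed
precision).

## Numerical choices and degenerate inputs

* Frequency tables use exact integer tallies; proportions are `count/n`, so
  `sum(proportion) == 1` to within 1e-12 and the final cumulative value is
  exactly 1.
* Empty inputs error early (`frequency_table`, `center_pa`,
  `compute_rqol`); an empty *filtered* dataset is legal output of
  `filter_subjects` and is rejected only when scoring is requested.
* `cutoff` must lie strictly inside (0, 1); 0 or 1 would make one sign of
  the score unreachable.
* Correlations require length ≥ 3 and nonzero variance in both series;
  degenerate replicates are skipped, degenerate pools abort.
* Seeds are kept below $2^{31}$ throughout; the substream hash is plain
  integer arithmetic, stable across platforms.

## Problem sizes used in the shipped checks

The test suite runs the full experiment designs scaled to what a thorough
desk check needs: the null-neutrality check uses 10 pools × 100 replicates
at N = 100; parameter recovery uses 100 seeds per effect size at ~1100
beeps per dataset; the shape check uses 150 replicates over sizes 20 to
10,000 on a single calibrated pool. These sizes were chosen as the smallest
designs whose Monte Carlo error is clearly below the effects being
asserted.

## Known limitations

* The cumulation order among tied frequencies and the treatment of the tie
  block are conventions; other software may rank ties arbitrarily and will
  then disagree on cp for tied settings.
* The negative-affect variant of the reward function is not implemented;
  the natural extension point is passing a different affect column to
  `compute_rqol()`.
* `sem = sd/sqrt(N)` is a printing convention, not the Monte Carlo error of
  the replicate mean; use `sd/sqrt(replicates)` for inference about means.
* The generator's Table-style targets constrain only summary statistics;
  the true cell-level frequency distribution of any real sample is
  unpublished, so agreement is at the profile level, not cell by cell.

## A worked example

```{r example}
set.seed(1)
data <- generate_dataset(synthetic_config(seed = 42))
valid <- filter_subjects(data, min_valid = 20)
scored <- compute_rqol(valid, definition = "WWW", cutoff = 0.5)
dplyr::glimpse(scored[1:3, ])

spec <- resample_spec(sizes = c(20, 100, 500), replicates = 200, seed = 7)
valid$pa <- compute_pa(valid)
experiment_unique_settings(valid, "WWW", spec)
```
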