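---
title: "Scoring and inference for the Attention Network Test: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and inference for the Attention Network Test: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnets)
```

## The task and its scores

The child Attention Network Test (ANT) is a flanker task with a cue
manipulation. On every trial a fixation cross is shown for a uniformly
jittered 400–1400 ms, one of four cues appears for 100 ms (no cue, a central
asterisk, a double asterisk above and below fixation, or a spatially valid
asterisk at the upcoming target location), and after a fixed 400 ms
stimulus-onset asynchrony a target fish appears above or below fixation,
alone (neutral) or flanked by four fish pointing the same way (congruent) or
the opposite way (incongruent). The response window is 1700 ms. A standard
session is 24 practice trials with feedback followed by 3 blocks of 96 test
trials; `ant_schedule()` generates such sessions with *exact* cell balance in
every test block over the 48 cells of the cue × flanker × target-location ×
target-direction factorial, which guarantees estimable condition medians for
every participant.

Three attention networks are isolated by Donders subtraction on
per-participant, per-condition summaries (median RT over retained correct
trials; proportion of errors, PE, over retained trials):

* **alerting** = no-cue − double-cue,
* **orienting** = central-cue − spatial-cue,
* **executive control** = incongruent − congruent.

The subtractions are applied to both the speed and the accuracy summaries.
The signs follow the field's convention that each score is the benefit (or,
for executive control, the cost) experienced by the participant: positive
alerting and orienting mean the cue helped, positive executive control is
the conflict cost. Some verbal descriptions of the scoring invert the
operands ("subtracting the no-cue condition from the double-cue condition"
would be double − no-cue); the published per-group means those descriptions
accompany are only consistent with the convention used here, so the package
follows the convention and not the phrasing.

## Trial exclusion

RTs below 200 ms or above 1700 ms are extreme values; the inequalities are
strict, so a trial at exactly 200 or 1700 ms is retained. Response timeouts
carry no RT, are scored incorrect, and are excluded. Practice trials
(`block == 0`) never enter any analysis. The default `exclusion_scope =
"both"` removes extreme trials from both the RT and the PE computations; the
alternative reading, in which the bounds only apply to RT medians, is kept
available as `"rt_only"` because published method sections rarely separate
the two. The per-participant *overall* RT is the median over all retained
correct test trials (not the mean of condition medians); both definitions
are computable from `summarize_conditions()` output, and the direct median
was chosen because it is the natural statistic on the trial population and
does not re-weight rare cells.

## The composite score and its standardisation scope

Speed and accuracy are integrated per network in the balanced-integration
style: the RT difference and the PE difference are z-scored and the two
z-scores averaged; higher composites mean worse performance. The one
genuinely open design choice is the *scope* of the z-scoring:

* z-scoring each network separately over participants forces every
  network's mean composite to zero, so group means must straddle zero within
  each network;
* z-scoring the *stacked* difference scores — pooled over participants and
  all three networks, separately for the RT measure and the PE measure —
  preserves the ordering of the networks: conflict costs (~85–95 ms) sit far
  above the pooled mean of all difference scores and keep positive
  composites, while alerting and orienting benefits sit below it and come
  out negative.

Published per-group composite tables for this task show exactly the second
pattern (both groups positive on executive control, negative on alerting and
orienting), so the pooled-stack scope is the default (`z_scope = "pooled"`),
with `"per_network"` available as a switch. Standardisation moments are
always computed on the combined sample, never per group, so group contrasts
remain interpretable. PE differences are standardised on the raw
percentage-point scale; the arcsine-square-root transform is applied only to
the overall PE before the group comparison, where it stabilises the variance
of small proportions (`arcsin_transform()` uses the `asin(sqrt(p))` variant:
at an overall PE around 2.6% it gives ≈ 0.16, the magnitude reported for
transformed error scores on this task, while the `2·asin(sqrt(p))` variant
would double it).

## Split-half reliability

`split_half_reliability()` estimates the reliability of each network score
by the permutation method: each participant's retained test trials are split
into two random halves, the network score is recomputed on each half from
scratch, the half scores are correlated across participants (Pearson — the
Spearman–Brown step presupposes a Pearson correlation), the correlation is
corrected to full length by `2r/(1+r)`, and the whole procedure is repeated
(1000 times by default). The reported coefficient is the mean of the
corrected correlations.

Two details are under-determined by the usual verbal description and are
resolved as follows:

* **Split mode.** An unrestricted random split of all trials can leave a
  half without any trial in a needed condition. The default split is
  therefore stratified within each cue × flanker cell (the odd trial of an
  odd-sized cell lands on a random side), which guarantees both halves
  contain every condition; `split = "unrestricted"` is available.
* **Interval.** The 95% interval is the normal standard-error interval
  `mean ± 1.96·sd/√n` over the permutation values. Published intervals for
  this statistic are far too narrow to be percentile intervals of the
  permutation distribution and match the standard-error construction;
  `ci = "percentile"` is available.

For the composite measure, the stacked half differences are standardised
within each half before averaging, so each half's composite is computed
exactly as it would be on a full dataset.

## The inference layer

`mixed_anova()` implements the split-plot (one between × one within factor)
repeated-measures ANOVA from first principles: the between-subject stratum
is decomposed into group and subjects-within-group, the within-subject
stratum into the within effect, the interaction, and the residual, by
sequential orthogonal projections. Sphericity is assessed with Mauchly's W
computed on the pooled within-group covariance of orthonormalised contrasts
(groups centred separately, pooled df = N − g), with the standard
second-order chi-square series for the p-value; the Greenhouse–Geisser
epsilon from the same contrast covariance rescales the degrees of freedom of
within effects (the F statistic itself is unchanged). Effect sizes are
generalized eta squared, `SS_effect / (SS_effect + SS_subjects +
SS_residual)`, whose denominator carries all subject-related variance and is
comparable across designs. The implementation is validated in the test suite
against `stats::aov()` error strata and `stats::mauchly.test()` on small
toys; those functions are used only as oracles, never as the implementation.

Post hoc machinery:

* `group_contrast()` compares the groups on the per-subject average; with
  two groups this equals the Tukey HSD comparison of group means, with the
  standard error taken from the subjects-within-group mean square and
  df = N − g.
* `cellwise_posthoc()` compares the groups within each within-factor level.
  A cell-mean contrast mixes both error strata, so its variance combines the
  two mean squares as `(MS_subj + (k−1)·MS_error)/k` and its df comes from
  Satterthwaite interpolation between the strata (for 108 subjects and 3
  networks this lands between the stratum dfs, around 315–318 when the mean
  squares are comparable). P-values are Holm-adjusted across the within
  levels; a studentized-range ("tukey") adjustment over all g·k cell means
  is available, because the label "Tukey HSD with Holm correction" that
  circulates for this procedure is internally redundant — the pooled-error
  contrasts with Holm adjustment are what it operationally means.
* Overall speed and accuracy are compared with Welch t tests
  (`welch_t()`), Holm-adjusted as a two-test family, with pooled-SD Cohen's
  d. Two-sided p-values are the default. One published pair of overall
  statistics for this task (p = .302 for a t of 0.52 at ~105 df, p = .002
  for a t of 3.13) is only arithmetically consistent with *one-sided* tests
  Holm-adjusted over the pair; `tails = "one"` reproduces that recipe and
  the choice is surfaced rather than hidden.
* `cooks_screen()` computes Cook's distances from the hat matrix of a
  least-squares fit and flags observations above the median of
  F(k+1, n−k−1) — for one predictor and 108 observations a cutoff of about
  0.70.

Holm adjustment is always applied within a declared family (the RT+PE pair;
the three post hoc contrasts), never globally across all tests. Skewness and
kurtosis are the moment estimators g1 and excess g2 by default
(`bias_correct = TRUE` gives the adjusted G forms); which variant produced
any given published table is usually unstated, so both are provided.

## The synthetic cohort

`simulate_cohort()` generates trial-level data with the statistical
structure the analysis assumes, so every stage is testable without external
data. Reaction times are ex-Gaussian — the standard right-skewed family for
RT data, chosen because its two noise parameters (Gaussian sd, exponential
tail) control skew independently of location — with a location shifted by
the design cell: any cue removes the participant's alerting benefit, a
spatial cue additionally removes the orienting benefit, incongruent flankers
add the conflict cost. Neutral trials sit at the congruent baseline; since
neutral trials enter no subtraction score, this choice is inert for all
headline outputs. Errors are Bernoulli from a logistic model with an
incongruency term on the log-odds. Anticipations (probability 0.005 per
trial) replace the RT with a uniform draw on [80, 199] ms; lapses
(probability 0.002) produce a response timeout, which is scored incorrect —
together they plant the ~0.7% out-of-range rate the exclusion stage is
meant to catch. RTs and errors are conditionally independent given the
design cell: there is no speed–accuracy trade-off term in the generator,
which is a documented limitation (real data couple the two), and one reason
the generator's composites are cleaner than real ones.

Participant heterogeneity is Gaussian around group-level means. The default
calibration targets the magnitudes of published child ANT cohorts of this
design (two groups of 54, 288 test trials): overall median RT ≈ 634 ms (SD
≈ 80 across participants, from a 78 ms between-participant SD of the
ex-Gaussian location), alerting ≈ 30 ms, orienting ≈ 43 ms, executive cost
≈ 83.7 ms in the reference ("gifted") group with a +10.5 ms group effect in
the comparison group, overall error proportion ≈ 2.5% vs ≈ 4.5% (a +0.62
baseline log-odds group effect), and errors concentrated in incongruent
trials (+1.35 log-odds). Two calibration details matter and were set
numerically: the location anchor (562 ms) absorbs the ex-Gaussian
tail and the mixture of condition shifts so that the realised overall median
lands at its target; and because the error model is logistic with a 0.8
between-participant SD on the log-odds, the population mean error rate is
inflated relative to the logit of the mean (Jensen's inequality), so the
baseline log-odds is set ≈ 0.32 below the naive value. The between-
participant SDs of the three effect benefits (13, 5, 28 ms) were chosen so
that the *reliability ordering* of the three networks reproduces the
qualitative pattern reported for this task — executive control by far the
most reliable, orienting near zero — which is a direct consequence of
difference scores with small true-variance-to-noise ratios.

What the generator does **not** emulate: sequential effects (post-error
slowing, block fatigue), speed–accuracy trade-offs, age or IQ covariates,
cue-dependent error rates (the alerting and orienting PE effects are
centred on zero), and any cognitive-process structure (no drift-diffusion
parameters). Tests passing on this generator therefore show that the
*pipeline arithmetic* is right and that the analysis behaves correctly on
data with the assumed structure — not that the assumptions hold in any real
dataset.

## Numerical and degenerate-input choices

* Medians of even-sized samples are the midpoint of the two central order
  statistics.
* A participant cell with no retained correct trial yields an `NA` median
  and a warning; downstream scores propagate `NA` and `run_ant_pipeline()`
  drops incomplete participants from the ANOVA with a warning.
* Zero pooled SD in standardisation, constant samples in `welch_t()`, zero
  margins in the chi-square, and rank-deficient designs in `cooks_screen()`
  are hard errors, not silent NaNs.
* `spearman_brown()` is monotone on (−1, 1]; a half correlation of −1 is
  undefined and surfaces as `-Inf`, which the permutation mean then exposes
  rather than hides.
* Sample Greenhouse–Geisser epsilon is bounded in [1/(k−1), 1] by
  construction; with a 2-level within factor it is exactly 1 and Mauchly's
  test is vacuous.
* All randomness flows from one user seed through named substreams
  (responders, cohort, splits), so each stage is independently reproducible
  and a fixed seed makes pipeline outputs byte-identical.

## Problem sizes used in the shipped checks

The packaged tests exercise the study-scale design (two groups of 54, 288
trials) where the claim under test concerns that scale: 200 simulated
cohorts for sign recovery of the planted executive group effect, 500
null-configuration cohorts for the empirical type-I error of the
group × network interaction, and three cohorts at 200 permutations each for
the reliability ordering. Toy problems for the ANOVA oracle comparisons use
8–10 participants, where brute-force projection algebra is exact and fast.
The acceptance script simulates one full cohort and runs the complete
pipeline with 1000 split-half permutations.
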