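---
title: "Models and methods behind ymazepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ymazepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ymazepop)
```

`ymazepop` re-implements, as a tested and reusable pipeline, the behavioral
and neural-population analyses used in virtual-reality Y-maze navigation
experiments: selectivity statistics with permutation nulls, subsampled
population decoding, noise-correlation analysis, and hierarchical bootstrap
inference — together with a synthetic-data generator that emulates the
task's structure and the statistical structure of cortical population
activity, so the entire chain runs and is validated without experimental
data. This vignette documents the models, the parameters that matter, the
numerical conventions, and the design decisions taken where the methods
left details open.

## The behavioral task and its simulator

In all task variants, a grating cue on the maze walls instructs a rewarded
side: under Rule A, horizontal maps to left and vertical to right; Rule B
reverses the mapping. The *simple* and *delay* tasks keep Rule A
throughout. The *switching* task reverses the rule unsignaled within a
session whenever three criteria hold jointly, evaluated once after each
completed trial: at least 75 trials since the previous switch or session
start, at least 85% correct over the last 30 trials, and a correct
immediately preceding trial. Because the criterion is checked once per
trial boundary, at most one switch can occur between consecutive trials.
The *run-to-target* task carries no informative wall cue: the rewarded arm
is marked directly, so every trial is treated as visually guided.

Trials are marked *guided* with probability `guided_fraction`; guided
trials are always answered correctly (the reward side is explicitly
marked). *Bias correction* emulates the training-stage procedure: if the
agent made the same choice on five consecutive trials irrespective of
correctness, the next trial's correct side is forced to the opposite side
and flagged. We interpret "the next trial" minimally: the override lasts
exactly one trial, and the same-choice counter restarts from the trial
after the forced one (the forced trial's own choice is not counted). Cue
identity is otherwise drawn i.i.d. uniform; how cues were randomized in the
real task is not documented, and independent uniform draws are the simplest
assumption consistent with long-run balance. Whether bias correction could
trigger on guided trials is likewise unstated; we count guided-trial
choices in the run, since the subject does make a motor choice on them.

The agent is deliberately not a belief-updating model. It chooses the
correct side with probability `p_correct`; after each rule switch its
effective accuracy ramps linearly from chance (0.5) back to `p_correct`
over `post_switch_relearn_trials` trials, which reproduces the
drop-and-recovery dynamics around unsignaled switches without modeling
inference about the hidden rule. With probability `lapse_rate` the choice
is uniform. `side_bias` in [-1, 1] adds `side_bias / 2` to the probability
of a left choice before clipping to [0, 1]; at `p_correct = 0.5`,
`side_bias = 1` yields an agent that always chooses left, the extreme the
signed-choice-bias statistic maps to exactly 1. An optional laser schedule
marks trials with an inhibition target and decrements effective accuracy
per cortical target, so inhibition effects of known size can be planted and
recovered.

Session fraction correct therefore has expectation
`g + (1 - g) p_correct` for guided fraction `g` at asymptote, and the
switch times are a deterministic function of the realized choice sequence
— both properties are verified in the tests, the latter against an
independent replay of the three criteria.

## The synthetic population generator

The generator emits deconvolved-like, spatially binned activity
(`neurons x trials x bins`) directly; calcium indicator dynamics,
deconvolution, and image-domain processing are out of scope. Its
structure mirrors what the downstream analyses assume:

* **Spatial sequences.** Each neuron has a Gaussian tuning bump (sd
  `tuning_width_bins`, default 3 bins) at a preferred bin drawn uniformly,
  so the population tiles the maze as a sequence of transiently active
  cells. Amplitude is `peak_rate` (default 1) over `baseline_rate`
  (default 0.05).
* **Trial-type selectivity.** A fraction `fraction_selective` (default
  0.4) of neurons has its bump amplitude increased by
  `selectivity_strength` on trials of a preferred label level. The label
  the boost keys on is configurable (`trial_type`, i.e. the cue-choice
  combination, or `cue` or `choice` alone); the cue/choice modes exist so
  that cue-, choice-, and single-trial-type cells can be planted for the
  four-trial-type categorization.
* **Shared noise.** On trial `t`, a standard-normal latent `z_t` enters
  every neuron scaled by its loading, plus private Gaussian noise of sd
  `private_noise_sd`. For unit loadings `lambda`, the expected pairwise
  noise correlation is `lambda^2 / (lambda^2 + sigma^2)` before clipping;
  the defaults (`lambda = 0.23`, `sigma = 1`) target a mean pairwise
  correlation near 0.05, a typical cortical value. Loadings can be uniform
  (`global`), per-area (independent latents per area), or *signal-aligned*
  (signed by each neuron's selectivity direction), the latter producing
  information-limiting correlations along the discriminant axis — the
  configuration under which disrupting correlations *improves* decoding.
* **Nonnegativity.** Activity is clipped at zero, as deconvolved event
  rates are nonnegative. Clipping biases the closed-form correlation
  slightly, so the generator exposes `clip = FALSE` and the closed-form
  checks run on the unclipped variant.

All randomness in a generator call flows from one seed; identical seeds
give bit-identical output. Ground truth (selectivity flags, preferred
types and bins, loadings, the closed-form correlation) is returned for
parameter-recovery tests.

## Preprocessing conventions

**dF/F.** `compute_dff()` implements
`(F_corr - P8(F_corr)) / P8(F)` with `F_corr = F - 0.7 F_neuropil` and
`P8` the 8th percentile in a 60-s sliding window. The window is centered
and truncated at the trace edges, and the percentile uses linear
interpolation (R's default type 7); neither choice is dictated by the
method's description, so they are fixed here and documented to make
results bit-reproducible. The statistic is invariant to a common positive
rescaling of both channels. Nonpositive raw baselines are rejected with a
diagnostic rather than silently producing unstable ratios.

**Spatial binning.** Deconvolved activity is summed over the frames whose
position falls in each half-open 5-cm bin `[lo, hi)` (0-based positions in
cm along the long axis; events on an edge belong to the right-hand bin).
Whether the original analyses summed or averaged within bins is not
stated; summation conserves total event counts (a tested invariant) and an
occupancy-normalized mode is available by flag. Frames outside the maze
extent are dropped with a reported count.

**High-performance trial filter.** Only correct trials from periods with
at least 80% correct within a 10-trial window are analyzed, which excludes
post-switch relearning epochs. The window's anchoring is not specified in
the method's description; the default here is the symmetric *any-window*
rule (a trial qualifies if any 10-trial window containing it passes, with
windows truncated at both session edges), with `trailing` and `centered`
anchors available by flag. The implementation is validated exactly against
a brute-force double-loop oracle, and selection is monotone in the
threshold.

**Trial subsampling.** To match trial counts across conditions, trials are
subsampled uniformly without replacement to 30 per trial type (two-type
analyses) or 15 per type across the four cue-choice types (60 trials
overall), deterministically given a seed.

## Selectivity statistics

Per neuron and spatial bin, the auROC compares activity distributions
between the two trial types under the Mann–Whitney convention (ties count
half) — computed from average ranks, which makes it exactly equal to the
exhaustive pair-count and lets a whole shuffle batch be evaluated as one
matrix product against precomputed trial ranks. Selectivity is
`2 |auROC - 0.5|`, invariant to which class is called positive.

Significance uses 100 label shuffles and the add-one estimator
`p = (1 + #{shuffle >= observed}) / (1 + n_shuffles)`, so p is never zero
and `p < 0.01` with 100 shuffles means precisely "the observed selectivity
beats every shuffle". Under the null, the flag rate per neuron-bin is
therefore 1/101, just under the nominal 0.01 — a calibration verified on
the null generator over tens of thousands of neuron-bins. By default one
permutation per shuffle is applied jointly to all neurons (cheaper, and
conservative for population summaries because it preserves cross-neuron
structure within a shuffle); independent per-neuron permutations are
available by flag and are used where independence across neurons matters,
as in the calibration measurement. Whether the original test shuffled per
neuron or population-wide is unstated.

Segment summaries average per-neuron quantities over the bins whose
centers fall in each maze segment — first stem half (15–75 cm), second
stem half (75–150 cm), arms (150–220 cm) — and the fraction of selective
neurons is computed per bin and then averaged over the segment's bins.

For the four-trial-type analysis, a neuron is selective within a rule if
it has at least three consecutive significant bins for the left-vs-right
comparison; the rule's preferred choice is the majority sign of
`auROC - 0.5` over the significant run. Neurons selective in one rule only
are `single_trial_type`; in both rules to the same choice, `choice`; to
opposite choices, `cue` (the cue-choice mapping reverses across rules);
and neurons with runs of conflicting direction within a rule are
`complex` — the treatment of within-rule conflicts is our reading of
"selective to opposite choices at different positions", since no finer
aggregation rule is documented.

## Population decoding and noise correlations

Trial-type decoding fits a linear maximum-margin classifier (linear SVM,
`cost = 1`; accuracy on separable synthetic data is insensitive to this
value, and it is exposed in the interface) per spatial bin on a uniform
random subsample of neurons, z-scored using training-fold statistics only
— whether the original z-scoring was fold-wise or session-wide is
unstated, and the leakage-free choice is the defensible default. Stratified
10-fold cross-validation yields held-out accuracy, averaged over folds,
bins, and repetitions (40 repetitions for populations of 5 or 10 neurons,
20 for 25–200, by default). Accuracy is averaged over all maze bins;
restricting to a bin subset is a parameter, which the orchestration layer
also uses to keep runtimes moderate.

Choice decoding from running uses a binomial GLM per spatial bin with four
predictors — pitch, roll, and yaw treadmill velocities and lateral maze
position — under the same stratified cross-validation; sessions can be
filtered on stem-average accuracy (e.g. the 85–95% band) by thresholding
this output.

Noise correlations are Pearson correlations of trial-to-trial responses
computed separately per trial type and averaged across types. "Spatially
binned data" admits two readings: the default computes the correlation per
bin across trials and averages over bins, avoiding conflation of spatial
tuning with trial-to-trial covariance; a concatenate-bins mode is provided
by flag. Area-pair means are unweighted means over qualifying pairs
(self-pairs excluded); pairs with zero variance in every usable slice are
skipped and counted. Disruption shuffles each neuron's trial order
independently within trial type, which provably leaves all single-neuron,
label-conditional statistics unchanged (tested bit-exactly for per-type
means and auROC) while destroying shared variability; the decoding impact
is measured with matched subsamples and folds for the intact and disrupted
data.

## Hierarchical bootstrap

Statistics are summarized as the mean with SEM equal to the standard
deviation of 1000 bootstrap means. Resampling is hierarchical: groups
(sessions, pooled across mice — a mouse level can be added as an extra
grouping column) are drawn with replacement, then units within each drawn
group (trials, or neurons), each resample keeping the original group
sizes — the standard convention; the source methods do not state the
within-group resample size. Two distributions are compared by doubling the
smaller one-sided overlap probability; the one-sided probability is floored
at `1/n_boot`, so the smallest reportable two-tailed p is `2/n_boot`
(claims like "p < 0.001" therefore require at least 2000 resamples). When
both distributions are completely tied the p is 1, not the floor. When two
conditions share sessions, resampling is independent by default, with a
paired comparison available by passing equal-length bootstrap vectors
drawn under a common seed. Bonferroni adjustment is `min(1, m p)`.

## The end-to-end experiment

`run_experiment()` simulates two cohorts that differ only in generator
parameters — by default a "simple-only" cohort and a
"switching-experience" cohort with higher `selectivity_strength` (0.8 vs
0.3) and lower shared-noise loading (0.15 vs 0.35) — and runs the full
chain on each session, emitting tidy CSVs and a manifest. Cohort contrasts
(selectivity via sessions-then-neurons bootstrap, mean correlation via a
session-level bootstrap) come out in the planted direction: the
higher-selectivity/lower-noise cohort shows higher mean selectivity,
larger selective fractions, higher decoding accuracy at every population
size, and lower mean pairwise correlations. Every stage's seed derives
from the root seed through named substreams, so adding a stage never
perturbs earlier stages and reruns are byte-identical.

This package's interface is the set of exported functions plus
`run_experiment()`; no shell entry point is shipped, as the intended users
drive analyses from R scripts in which configuration objects are more
expressive than command-line flags.

## Problem sizes and test design

The validation suite chooses problem sizes so that every statistical check
has adequate power while remaining desk-scale: chance-level behavior is
checked on 12,000 simulated trials (binomial SE ≈ 0.005); permutation-test
calibration on 40,000 neuron-bins from a 2000-neuron null population with
neither built-in selectivity nor a shared latent — the shared latent makes
a neuron's bins co-fluctuate, which would cluster the significance flags
and invalidate the binomial Monte-Carlo error (SE ≈ 0.0005 around the
theoretical 1/101) that the check relies on; parameter recovery
on 20 replicate cohort pairs of 60 neurons, 12 bins, and 30 trials per
type, with decoding at sizes 5/10/25 and 10 repetitions; the bootstrap
closed form on 50 replicates of 200 i.i.d. normal observations. auROC and
the trial filter are checked exactly against brute-force oracles on 1000
random instances each.

## What passing tests do and do not show

The generator emulates the statistical skeleton the analyses assume —
transient spatial tuning, additive trial-type gain, a low-rank shared
noise source, nonnegativity — not real calcium physiology: no indicator
kinetics or deconvolution artifacts, no slow drift or behavioral
covariates entangled with position, no heavy-tailed event statistics, and
rule switches leave the generator's tuning itself unchanged. Parameter
recovery on these synthetics validates the *estimators* (that the pipeline
recovers planted differences in selectivity, decodability, and
correlation, and stays calibrated under the null); it cannot certify how
large such effects are in real recordings. Known limitations: the sliding
percentile is O(n·w) and meant for session-length traces; the SVM step
refits per bin, fold, and repetition, so exhaustive size grids on
thousands of neurons are compute-heavy; and the hierarchical bootstrap
treats sessions as exchangeable across mice by default.
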