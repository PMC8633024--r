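---
title: "Models and methods behind reciprosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reciprosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reciprosim)
```

## The paradigm

`reciprosim` simulates and analyses a joint length-reproduction paradigm in
which a human participant interacts with an algorithmic partner framed either
as a computer or as a humanoid robot. A session always runs three tasks in a
fixed order:

1. **Perceptual inference** (66 solo trials): the participant reproduces the
   distance between two flashed disks (11 lengths, 8–16 cm in 0.8 cm steps,
   each shown 6 times).
2. **Social influence** (66 decision trials): after estimating, the
   participant sees the partner's estimate of the same stimulus and places a
   final decision anywhere between the two responses. The *influence index*
   `i = a / d` — the adjustment toward the partner `a` over the distance `d`
   between the two estimates — measures the weight given to the partner
   (0 = keep own answer, 1 = adopt the partner's).
3. **Reciprocal social influence** (176 trials): decision turns (participant
   decides) strictly alternate with observation turns (partner decides). The
   partner's own influence level is manipulated across a Susceptible and an
   Unsusceptible block (66 trials each), joined by a 22-trial transition ramp
   and closed by a 22-trial final block (11 observation turns in a row, then
   11 decision turns) announced as the end of the experiment.

Everything the partner does is fully specified and therefore *not* free:
estimates are Gaussian around the true length (SD 1.52 cm, with a bounded
resampling rule that keeps half of the draws closer than 0.5 cm to the
participant away from them), and observation-turn influence comes from fixed
mixtures of uniform distributions over quarters of [0, 1]
(Susceptible: 0.45/0.35/0.15/0.05 from the top quarter down; Unsusceptible:
0.80/0.15/0.05 from the bottom quarter up), with an exact 2-2-3-4 interval
ramp in the transition block and inheritance of the last main condition in
the final block.

## The synthetic participant

The human side of the paradigm is *not* fully specified by the experimental
protocol, so the package ships a generative model — the synthetic-data
module — whose structure is the minimal one producing the phenomena the
analyses assume.

### Central-tendency observer

A percept of a length `s` is `p ~ Normal(s, w·s)` with Weber fraction `w`
(scalar variability). The estimate combines the percept with a prior centered
on the running mean `m` of the percept history:

    estimate = λ·m + (1 − λ)·p + ε_motor,   λ = (w·s)² / ((w·s)² + σ_prior²)

with `m` updated toward each percept by an exponential moving average
(rate 0.15) and initialized at the first percept. Because `λ` grows with
`s`, long stimuli are pulled toward the prior more strongly than short
stimuli are pushed up, which yields the three required phenomena at once: a
response slope below 1 (central tendency), a slope that flattens as noise
grows, and a session mean below the 12 cm design mean (underestimation).

**Calibration.** The observer's free parameters were set by
`calibrate()` — a seeded grid search over `(w, σ_prior)` that simulates
25-participant solo-task cohorts and minimizes the squared
tolerance-standardized distance to the target mean relative estimation error
0.20 and mean regression index 0.46. The frozen result is `w = 0.38`,
`σ_prior = 4.6` cm, with motor noise fixed at 0.8 cm. A practical note: the
grid objective must be evaluated with enough simulated participants
(150 here) that Monte-Carlo noise does not drive the pick; and the stage-two
(policy) simulator warms the prior up with a 66-trial solo block first,
because the real pipeline enters the joint tasks with a converged prior and
a fresh prior biases distances upward and influence downward.

The calibrated Weber fraction (0.38) is larger than classic values for
suprathreshold visual length discrimination; it is what the target error
level of 0.20 for briefly flashed, memory-reproduced distances implies under
this model, and it absorbs all non-sensory trial-to-trial variability (memory
decay, touch placement) that the model does not represent separately.

### Influence policy

On decision turns the participant's influence is logit-linear:

    logit(i) = β₀(group) + β_d·(|own − other| / s) + shift(condition)
               + final_block·shift_F + Normal(0, σ_policy)

squashed through the logistic function, which keeps `i` in (0, 1) by
construction and makes each reported effect a single parameter: egocentric
discounting is `β₀ < 0`, the decline of influence with inter-agent distance
is `β_d < 0` (−3.0 for the Computer policy, −2.0 for the Robot policy,
mirroring the stronger distance effect under the computer framing),
and the condition effects are additive logit shifts. Baselines were
calibrated to the reference group means (Computer 0.26, Robot 0.35), giving
`β₀ = −0.65` and `−0.30`. Condition shifts follow the reference qualitative
pattern: positive in both reciprocal conditions for the Computer group
(≈ +0.03/+0.04 on the influence scale), near zero for the Robot group, and a
negative final-block shift that is larger for the Robot group.

### Learning, ratings, heterogeneity

* **Perceptual learning** across tasks is emulated phenomenologically as a
  multiplicative modifier on the Weber fraction per group × condition
  (Computer: 0.90 in both main conditions — performance improves; Robot:
  1.10 in the Susceptible condition — performance deteriorates, 1.02
  Unsusceptible). No mechanistic learning rule is claimed, because the
  protocol specifies none; the modifiers only reproduce the direction and
  rough size (±0.02) of the reference error changes.
* **Ratings** (1–10, self and partner) are deterministic in the model:
  the partner rating drops by 1.75 points per unit of the partner's observed
  mean influence in the current condition. Integer quantization plus a
  per-participant anchor jitter supplies the residual variance for the
  rating model.
* **Heterogeneity**: per participant, the Weber fraction and prior SD are
  log-normal around the calibrated center (log-SDs 0.18 and 0.15) and the
  policy baseline is normal on the logit scale (SD 0.75, which reproduces
  the reference between-subject influence SD of ≈ 0.13–0.16). Each participant
  runs on an independent random substream derived from the master seed, so
  cohort growth never perturbs existing participants.

## What the generator does and does not establish

The synthetic cohort reproduces: the stimulus design and schedule exactly;
the partner's distributions exactly; central tendency, underestimation,
scalar variability; group-level mean error/influence/regression index at the
calibrated targets; the distance–influence decline; condition and
final-block shifts of the reference sign and approximate size; and
rating–influence coupling. It does **not** reproduce: the absolute size of
the underestimation (≈ −0.3 cm here vs. ≈ −1 cm in the reference setting — the minimal
observer under-predicts it once error and regression index are pinned), any
mechanistic account of learning or motivation, reaction times, or
participant-level idiosyncrasies beyond the three heterogeneity parameters.
A green calibration test therefore certifies the generator's stated world,
not a reanalysis of the original human data, which is out of reach of a
synthetic pipeline by construction.

## Statistical machinery

All tests are two-tailed and report a z statistic with the rank-biserial
style effect sizes `r = z/√N` and `η² = z²/N` (`N` = observations entering
the test):

* **Wilcoxon signed-rank / rank-sum**: z always comes from the tie-corrected
  normal approximation (so effect sizes are always defined); the p value is
  exact — full enumeration of sign assignments or group assignments — below
  10 non-zero differences (signed-rank) or for pooled samples of at most 12
  (rank-sum), and normal-based above. Enumeration agrees with the
  brute-force oracles and with base R's exact tests on tieless data.
* **Spearman**: average ranks for ties; exact permutation p for n ≤ 7, else
  the t approximation. Constant input is flagged, not silently zeroed.
* **Mixed models**: the six trial-level contrasts are linear mixed models
  with a participant random intercept, fitted by maximum likelihood
  (`lme4`), with Wald z and normal p values. Treatment contrasts use
  Computer / Baseline reference levels so coefficient names read as the
  reported contrasts ("Susceptible − Baseline", "Robot − Computer"
  interactions); the Susceptible − Unsusceptible comparison is a Wald
  contrast on the fitted coefficients. Singular fits are reported through a
  warning and an attribute, never silently. Parameter recovery and the
  nominal 5% type-I rate of the Wald z are verified by simulation in the
  test suite.

## Numerical choices and degenerate inputs

* Influence is undefined when the two estimates coincide (`d < 1e−6` cm);
  such trials are flagged invalid and excluded from influence analyses. The
  partner's resampling rule makes them rare by design.
* A final decision outside the segment between the two estimates (beyond a
  1e−9 tolerance) is a data-integrity error, not a clippable value.
* The distance-binning display statistic uses nine half-open bins of 0.05
  per-stimulus SDs with an open-ended ninth bin (the top edge is not part of
  the procedure's definition); a constant influence series z-scores to 0
  with a warning; empty bins are reported missing, never as zero.
* The agent's resample-until-far loop is bounded at 1000 iterations and the
  agent's estimates are clipped to the physical screen with a warning —
  both unreachable in practice at SD 1.52 cm, present only as guards.
* "In half of the instances" (the resampling rule) is read as an independent
  Bernoulli(0.5) decision per offending draw — the simplest stationary
  interpretation.
* Decision turns lead the alternation in the reciprocal task; the protocol
  does not fix which turn type comes first, and any fixed choice preserves
  every count. The 22-trial transition block continues the same alternation,
  its 11 observation turns carrying the influence ramp.
* The three sub-blocks of the social-influence task differ only by pauses;
  no functional difference is modeled.
* Configurations serialize as JSON rather than YAML; JSON round-trips are
  exact and need no extra dependency.

## Known limitations

The generator is a stated world: its defaults encode the reference group
statistics once and are not re-tuned per run. Cohort means of 25 simulated
participants inherit the realistic between-subject spread, so any single
seed can land 1–2 Monte-Carlo standard errors away from a target; the
calibration centers the expectation, not each realization. The rating model
is linear and deterministic; the final-block motivational account is
represented only as an additive shift; and the Computer/Robot differences
are injected through the policy parameters, not derived from any model of
belief about the partner.
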