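---
title: "Modelling explore-exploit decisions in the Horizon Task with a drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling explore-exploit decisions in the Horizon Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(horizonDDM)
library(dplyr)
```

## The task and the scientific question

The Horizon Task is a two-armed bandit game built to separate two strategies
people use when trading off exploration against exploitation. Each game
starts with four *instructed* trials that force a fixed sampling pattern:
either one draw from one bandit and three from the other (the unequal, `[1 3]`
condition) or two from each (the equal, `[2 2]` condition). The participant
then makes either one free choice (horizon 1) or six (horizon 6). Rewards are
Gaussian with an 8-point SD around each bandit's generative mean; one mean is
40 or 60 points and the other is offset by plus or minus 4, 8, 12 or 20.

Because only the horizon differs between conditions, changes in behaviour
with horizon isolate the *prospective* value of information:

* **directed exploration** — an information bonus that grows with horizon,
  measured as the increased preference for the less-sampled option;
* **random exploration** — decision noise that grows with horizon, measured
  as the increased rate of choosing the lower-valued option.

Choice probabilities alone cannot say *how* decision noise is controlled.
In a sequential-sampling account, choices become more random either because
the evidence itself is less reliable (a lower signal-to-noise ratio, SNR) or
because less evidence is required before committing (a lower decision
threshold). These two mechanisms make identical predictions for choices but
different predictions for response times — which is why this package models
both.

## Models

### Logistic bias-noise-bonus choice model

On the first free choice, with `dR` the observed mean reward difference
(left minus right), `dI` the information difference (+1 when left is the
once-sampled option, -1 when right is, 0 in the equal condition):

    p(left) = logistic( (dR + A * dI + b) / (2 * sigma) )

`A` is the information bonus in points, `b` a spatial bias towards the left
side, and `sigma` the decision noise in points. The typeset form of this
model is ambiguous about whether the denominator is `sigma` or `2 * sigma`;
this package adopts `2 * sigma` throughout and applies the same convention to
the DDM noise mapping below, so the two scales are directly comparable.
`sigma` is estimated separately for the unequal and equal conditions (the
two are reported separately in the literature), while `A` and `b` are shared;
`A` is identified only by unequal-condition trials since `dI = 0` otherwise.
Fitting is bounded maximum likelihood (`sigma` in (0.1, 100], `A` and `b` in
[-40, 40]) with dispersed restarts; estimates landing on a bound (complete
separation) are flagged rather than raised as errors.

### Response-time regression

    RT = b0 + bR * alpha * dR + bI * alpha * dI

with `alpha` the choice sign (+1 left, -1 right). `b0` is the baseline
response time, `bR` captures the speed-up with (signed) reward difference —
decisions are faster when the chosen option is clearly better — and `bI` the
corresponding effect of information. Ordinary least squares; a rank-deficient
design (e.g. all equal-condition rows) is an error naming the collinear
column.

### The linked drift-diffusion model

The first free choice is modelled as a two-boundary Wiener process. Evidence
`X(t)` for "left is better" accumulates with drift `mu` and unit diffusion
noise (`c = 1` fixes the scale degeneracy between drift, threshold and
noise); a response is given when `X` first crosses `+beta` (left) or `-beta`
(right); the starting point is `X0 = alpha_bias * beta`; the observed RT
adds a non-decision time `T0`. Task variables enter through the linking
functions

    mu         = c0_mu + cR_mu * dR + cI_mu * dI
    alpha_bias = 2 * logistic(c0_a + cR_a * dR + cI_a * dI) - 1
    beta       = c0_beta

With noise fixed at 1, `cR_mu` is the "SNR reward" (evidence per point of
reward difference) and `cI_mu` the "SNR information". The 7 linking
coefficients plus `T0` give 8 free parameters per horizon condition — 16 for
the baseline model. *Yoked* variants share the threshold, the SNR reward, or
both across horizons (15, 15 and 14 parameters), and are the natural
comparison set for asking whether the extra per-horizon flexibility is
needed. `dR` enters in raw points (no normalisation).

The likelihood of a (choice, RT) pair is the defective first-passage-time
density at the crossed boundary. Left choices map to the upper boundary.

### The DDM-to-softmax noise mapping and the threshold counterfactual

For a zero-bias diffusion the choice marginal is
`p(left) = logistic(2 * beta * mu)`, so a reward-driven drift implies the
logistic model's noise

    sigma_DDM = 1 / (4 * beta * cR_mu)

under the same `2 * sigma` convention. Participants whose fitted `cR_mu` is
not positive have no meaningful noise equivalent and are excluded (and
counted) from the noise-mapping analysis, mirroring the exclusion rule used
with the deposited data. `temperature_counterfactual()` asks the group-level
question directly: replacing one group's average threshold with another's
changes `sigma_DDM` by `100 * (beta_original / beta_replacement - 1)` percent
— e.g. giving older adults the (lower) younger-adult threshold *raises*
their implied decision noise, quantifying how much the higher threshold
compensates for a lower SNR. Under this closed-form mapping the percent
change depends only on the threshold ratio; a simulation-based variant
including bias terms was considered and rejected because the bias terms
average to approximately zero at the group level.

## Numerics

**First-passage densities.** The density is evaluated with the standard
small-time and large-time series expansions of the Wiener first-passage
problem in the (separation `a = 2 beta`, relative start `w`) parametrisation,
choosing the cheaper series whose truncation error is below `tol` (default
`1e-7`) at each evaluation; the upper-boundary density uses the reflection
`(mu, alpha_bias) -> (-mu, -alpha_bias)`. Unit tests verify normalisation,
agreement of the integrated density with the analytic absorption probability,
continuity across the series switchover, and closed-form moments.

**Analytic gradients.** The log-density derivatives with respect to drift,
separation, start and non-decision time have closed forms (the series are
differentiated term by term, with one extra term retained); the negative
log-likelihood gradient in the 8 linking coefficients follows by the chain
rule and is validated against central finite differences. Optimisation uses
`nlminb` (a bounded quasi-Newton method) with this gradient.

**Fitting.** Bounded multi-start maximum likelihood: 10 dispersed
(low-discrepancy Halton) start points by default plus one central start;
coefficient bounds are `c0_mu, cI_mu` in [-10, 10], `cR_mu` in [-1, 1] per
point, bias coefficients in [-5, 5], `beta` in (0.05, 10], and `T0` in
[0, 0.95 * min RT]. Observations with `rt <= T0`, where the density is zero,
contribute a finite per-observation log-density floor of -50 rather than
`-Inf`, keeping the objective optimizable; the `T0` upper bound prevents the
floor from being abused. Fits are deterministic given data and options (the
start points are deterministic).

**Simulator.** `simulate_wiener()` uses Euler-Maruyama paths at `dt = 1e-3` s
(maximum duration 20 s, censored paths excluded with a warning). Because
drift and diffusion are constant, the grid-point transition is exact; the
only discretisation error is an intra-step crossing-and-return, which is
handled with the Brownian-bridge crossing probability
`exp(-2 (b - x0)(b - x1) / dt)` per step and boundary. Without this
correction the mean decision time carries the classic O(sqrt(dt)) overshoot
bias (about 0.02 s at `dt = 1e-3`), large enough to fail a 3-standard-error
comparison against the closed-form mean at 100,000 paths; with it the
residual bias is below 2 ms.

## The synthetic cohort generator

`simulate_cohort()` produces trial-level data with the full statistical
structure the analyses assume: counterbalanced schedules (exact horizon by
information crossing; anchor mean, offset magnitude, offset sign and side
balanced within cells), Gaussian integer-rounded rewards, first free choices
and RTs drawn from the linked diffusion, and a ground-truth coefficient
table. Seeded runs are bitwise reproducible.

Two illustrative parameter regimes are built in. **They are not published
estimates** — no parameter means are printed in the source literature — they
are package defaults chosen once to reproduce the qualitative aging pattern
of Horizon-Task DDM fits: relative to the young-like regime, the old-like
regime has a higher threshold and longer non-decision time in both horizons,
a lower SNR information in both horizons, and a lower SNR reward in
horizon 1; within the young-like regime, threshold and SNR reward fall from
horizon 1 to 6 while SNR information rises. The means were calibrated with
the closed-form mean decision time so that implied first-free-choice RTs land
in the published group ranges (young roughly 0.7-1.1 s, old roughly
1.1-1.8 s): an earlier draft with larger thresholds produced multi-second
decisions unlike any printed RT curve, and — a useful cautionary note — left
non-decision time weakly identified, because a diffuse RT distribution has no
sharp left edge for `T0` to anchor on. Between-participant variation is
truncated Gaussian within the fitting bounds (`T0` floored at 0.1 s).

What the generator does **not** emulate: sequential learning across games,
within-session fatigue or practice drift (block effects must be injected
explicitly, as the block-fit tests do), RT contaminants (fast guesses,
attentional lapses), and any demographic structure. Later horizon-6 free
choices (trials 2-6) are outside the model of interest and are filled by a
documented placeholder — greedy on the observed running mean with a 10%
lapse rate — purely so accuracy-by-trial curves can be exercised; instructed
trials get placeholder motor RTs (`T0` plus a small gamma latency), faster
than the modelled first free choice as in the real task. A green test on
synthetic data therefore establishes internal consistency of the pipeline
(simulate, fit, recover, predict), not correctness of the scientific claims
on any real dataset.

## Analysis pipeline choices

**Curves.** Choice and RT curves bin the reward-difference axis with edges
placed between the design offsets (±4, 8, 12, 20). The unequal condition is
summarised as p(choose the more informative option) against
`R(high info) - R(low info)`; the equal condition as p(left) against
`dR`. Standard errors are across-participant s.e.m. by default (matching the
field's figures) or pooled binomial/SD.

**Parameter recovery.** `parameter_recovery()` simulates, refits, and
reports per-coefficient Pearson correlations and biases. Recovery cohorts
should span the parameter range of the cohort under study — the package's
recovery checks simulate half young-like, half old-like participants,
mirroring a recovery study run with "the same parameters as the real data"
on a two-group cohort.

**Leave-one-out model comparison.** The granularity is leave-one-*game*-out
within participant: each first free choice is held out in turn, the model is
refitted on the remaining games, and the held-out observation is scored by
its joint choice + RT log density (scoring the joint density, not choices
alone, was an open design point; the joint density is what the model claims
to explain). Two implementation details matter:

* *Warm starts.* Fold refits start from the full-data optimum instead of
  re-running the multi-start search, which makes the procedure tractable at
  cohort scale. The fold optimiser must still be run close to convergence:
  stopping too early leaves the fold at the full-data optimum, which
  *contains* the held-out observation's influence, silently erasing the
  out-of-sample penalty for extra parameters and mis-ranking nested models.
  The fold iteration cap and tolerance are exposed in `ddm_fit_options()`.
* *The `T0` support constraint.* `T0`'s upper bound is a fraction of the
  smallest observed RT. If a fold recomputed that bound from the remaining
  games, holding out the fastest game could let `T0` exceed the held-out RT,
  flooring its log density at -50 and injecting tens of nats of noise into
  the comparison. Fold refits therefore inherit the participant-level bound
  computed from all games.

Per participant, the best model maximises the summed held-out log-likelihood;
exact ties are broken by parsimony (fewest free parameters) and then by the
declared spec order, and flagged. Folds in which any model fails are dropped
symmetrically across models.

**Noise correlation.** The DDM-implied `sigma_DDM` is compared with the
logistic `sigma` across participant-by-horizon pairs, with negative-drift
participants excluded and counted. The unequal-condition `sigma` is the
primary comparison (which `sigma` entered the original analysis is not
stated; the equal-condition correlation is also reported).

## Data format

The canonical on-disk unit of exchange is a UTF-8 CSV with columns
`participant_id, age_group, game_id, block, horizon, info_condition,
trial_index, is_instructed, choice, reward, rt, gen_mean_left,
gen_mean_right`; `rt` is in seconds at millisecond precision, instructed
trials are exactly `trial_index` 1-4, test games carry block labels 1-4 and
practice games block 0 (practice is excluded from every analysis). Behavioural
data deposited elsewhere — including the study's OSF repository, whose file
layout is not described in the text — must be mapped onto this schema by the
user: one row per trial, sides relabelled to `left`/`right`, rewards in
points, RTs converted to seconds, and the generative means attached from the
session's game definitions. `read_horizon_data()` validates structure and
invariants and names offending rows. Task configuration objects are plain R
lists (`horizon_config()`); serialise them with `jsonlite` if a file format
is needed (YAML support is deliberately not a dependency).

## A small worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_config(4, age_regime("young"), seed = 7))
feats <- first_choice_features(cohort$data)
fit <- fit_ddm(
  feats[feats$participant_id == "young_001", ],
  model_spec("baseline")
)
fit
# compare the implied decision noise with a logistic refit
ddm_noise(fit$coefficients[["6"]])
fit_logistic(feats[feats$participant_id == "young_001", ], horizon = 6)$params
```

## Known limitations

* The pure DDM only: no across-trial variability in drift, start point or
  non-decision time, and no collapsing bounds. Later horizon-6 choices are
  not modelled (no reinforcement-learning update rule).
* Per-participant maximum likelihood, not hierarchical estimation; with 64
  games per horizon, weakly-identified coefficients (notably the bias terms,
  and `T0` when decisions are slow and diffuse) carry substantial estimation
  error, and group comparisons should use the emitted tidy tables with an
  appropriate inferential model (deliberately out of scope here).
* Group-level inferential statistics (mixed models, post-hoc tests) are not
  reimplemented.
* Whether the original task clipped displayed rewards is unknown; rewards
  are rounded to integers and unclipped by default (`horizon_config()`
  exposes an optional clipping range).
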