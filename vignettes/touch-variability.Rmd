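---
title: "Decoding explore/exploit states and touch variability in restless bandit sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding explore/exploit states and touch variability in restless bandit sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchbandit)
```

## The scientific problem

In a two-arm spatial restless bandit task, a mouse chooses between two
visually identical response apertures on a touchscreen. Each arm pays off
with a probability that drifts independently over trials, so the animal must
keep re-learning which side is better. Behaviour in such tasks alternates
between *exploration* (sampling both options to track their values) and
*exploitation* (committing to the currently better option). Because a choice
is registered anywhere inside a large 240 × 240 px aperture, the touch
coordinates themselves carry information beyond the left/right choice: how
tightly successive nosepokes cluster, how far they sit from the screen
midline, and how bout-to-bout touch clouds move are all candidate motor
signatures of the underlying decision state.

`touchbandit` implements that analysis end to end: the task's probability
walk, a latent-state labeler, an agent model of the choice sequence, the
spatial precision metrics, bout-level geometry, and the mixed-model
machinery that relates the metrics to state, sex and prior reward — plus a
synthetic-cohort generator so every stage is testable without access to
recorded animals.

## The task simulator

Each session is `n_trials = 300` trials. On every trial, each arm
independently has a `step_prob = 0.10` chance of its reward probability
moving by `step_size = 0.10`, up or down with equal probability, bounded to
`[0.20, 0.90]`.

A boundary-crossing step can be handled two ways. *Clamping* pins the value
at the bound, but then a down-step drawn at the lower bound realises no
change at all; at stationarity roughly 1 in 80 drawn steps is silently
absorbed and the realised per-trial change frequency falls measurably below
the nominal 10%. *Reflecting* folds the overshoot back inside, so every
drawn step realises a change of exactly one step size while the walk stays
inside its bounds. Because the task is defined by its per-trial chance of a
probability *change*, reflection is the default (`boundary = "reflect"`);
clamping remains available as a flag. Initial probabilities, when not
supplied, are drawn uniformly from the attainable grid
`{0.2, 0.3, ..., 0.9}`, which keeps every subsequent value on the grid.

One seeded generator drives a session; the stream order (left-arm step
indicator, left direction, right-arm step indicator, right direction, per
trial) is fixed, so walks and rewards are jointly reproducible from a
single seed.

## The explore/exploit labeler

Trials are labeled by a three-state hidden Markov model over the choice
sequence: *explore*, *exploit-left* and *exploit-right*. Two structural
constraints define the model:

* direct transitions between the two exploit states are forbidden — an
  animal must pass through exploration to switch the side it exploits;
* exploit states emit their own side deterministically, while explore emits
  left with probability `explore_emit_left` (0.5 by default, fittable
  behind a flag).

Deterministic exploit emissions are what make the transition constraint
meaningful: any side switch inside an exploit run would otherwise be
absorbed by emission noise. The transition structure is kept minimal: one
shared persistence probability for both exploit states, and explore exits
split equally between the two exploit sides.

Fitting is by Baum–Welch EM restricted to the free parameters (the two
stay probabilities, the initial distribution, optionally the explore
emission). Structural zeros receive no mass at any point, the
log-likelihood is non-decreasing across iterations (asserted in the test
suite on every run), and five jittered restarts from stay probabilities
(0.8, 0.6) guard against local optima. The default fitting unit is one
animal across its sessions — states are a property of the animal's policy,
and per-session fits at 300 trials leave the stay probabilities noisy — but
pooled and per-session fits are a matter of how sequences are passed in.

Hard labels come from the Viterbi path, not from per-trial posterior
maximisation: the Viterbi path is guaranteed to respect the forbidden
transitions, which per-trial MAP labels are not. Posterior `P(explore)` per
trial is reported alongside from the forward–backward recursions. Ties in
the Viterbi backtrack resolve to the lowest state index, making decoding
deterministic.

## The RLCK agent

The choice sequence itself is modelled by a four-parameter
reinforcement-learning choice-kernel (RLCK) agent. Arm values update by the
delta rule, `q <- q + alpha * (reward - q)`, and a choice kernel tracks
recent choices, with the chosen side's trace moving toward 1 and the
unchosen toward 0. The probability of a left choice is

```
P(left) = plogis( beta * (qL - qR) + bias + kappa * (ckL - ckR) )
```

with learning rate `alpha`, decision noise `beta`, side bias `bias` and
stickiness `kappa`. The published description of this model names exactly
four parameters, so the choice-kernel learning rate is tied to `alpha`; the
functional form is isolated in `choice_prob_left()` / `update_agent()` so a
separate kernel rate or a one-trial-back sticky indicator could be swapped
in without touching the fitting machinery. Values start at 0.5
(indifference between Bernoulli arms) and kernel traces at 0.

`fit_rlck()` minimises the summed negative log-likelihood over an animal's
sessions (the agent resets at session boundaries) with bounded L-BFGS-B
from 20 uniform-random restarts; parameters that end on a bound are
flagged, since degenerate behaviour (an animal that always chooses one
side) is explained equally well by extreme bias or stickiness.

## Spatial precision metrics

All analyses work in screen-global pixels (origin top-left, half-open
ranges `[0, 800) × [0, 600)`) and convert distances to millimetres with the
hardware calibration 1 px = 0.29 mm. A reader dialect converts
aperture-local exports (coordinates relative to the touched aperture) by
adding the fixed aperture offsets.

* **Distance from the screen midline** is `|400 - x|` px. Only the x
  coordinate enters: the midline is a vertical line, and the printed
  worked form of this metric uses x alone, so the package does the same.
* **Successive Euclidean distance** is the hypotenuse between consecutive
  touches, restricted to pairs on the same aperture and in the same
  decoded state; pairs spanning a side change, a state change or both are
  excluded and the accounting (counts and percentages by reason) is
  reported. Pairs never span session boundaries.
* **Mahalanobis distance** scores every touch against its group's centroid
  through the group's sample covariance, so no touches are excluded.
  Groups are one aperture side within one animal (pooling sessions),
  split by explore/exploit when requested; groups with singular
  covariance are skipped and flagged rather than scored.
* **Response latency** is summarised per animal and state.
* **Previous-outcome conditioning** attaches the preceding trial's reward
  to each trial (and to each successive pair, via the pair's first trial)
  and drops each session's first trial.

Downstream models use per mouse × session × state means (optionally also
split by previous outcome), so that every animal contributes equally and
random effects are identified by the session-level replication.

## Bouts and contour geometry

A state *episode* is a maximal run of same-state trials; every
explore↔exploit transition starts a new one. Episode counts per session
are reported as the explore and exploit bout numbers — by alternation the
two counts can differ by at most one, which is asserted on every output.
For spatial metrics each episode is additionally partitioned by aperture
side, since an explore episode can touch both sides; centroid shifts are
Euclidean distances between successive bout centroids within one state and
side.

The area and perimeter occupied by a bout are measured from its touch
density: a 2D histogram with automatic (Freedman–Diaconis) bin edges
coarsened by a factor of two (adjacent bins merged), counts normalised to
`[0, 1]`, thresholded, and the occupied region's iso-boundary traced on a
zero-padded grid. The default threshold keeps every occupied bin — the
boundary of the least-dense, outermost contour level — because that is the
outer range of responding the measurement is after; the level is
configurable. Outermost boundaries are identified by containment (a
boundary nested inside another is a child and does not contribute);
when the occupied region is disconnected the top-level components' areas
and perimeters are summed and the component count is reported. Geometry is
computed with the shoelace formula and summed edge lengths, in mm.

Bouts with fewer than 5 touches, or with all touches coincident,
contribute to counts and centroids but are flagged degenerate and carry no
area/perimeter; they are excluded from bout-geometry averages.

## Mixed models and stepwise AIC selection

Metric tables are analysed with linear mixed models fitted by maximum
likelihood (not REML), because the selection procedure compares models
that differ in their fixed effects and only ML AICs are comparable across
those. AIC is `2k - 2 logLik` with `k` counting fixed coefficients plus
variance parameters. Coefficient p-values are Wald tests on the normal
scale from the same ML fit. Factors use treatment coding with reference
levels female, explore and nonrewarded, and the reporting functions print
the coding, since coefficient signs depend on it. A singular random-slope
fit falls back automatically to a random intercept and is flagged.

`stepwise_select()` performs a greedy backward search: children are formed
by deleting one term — fixed interactions before the main effects they
contain (marginality is enforced), main effects only when their current
Wald p-value is above 0.05 (significant main effects are protected), and
random slopes reducible to random intercepts. The search moves to the
lowest-AIC child while that improves on the parent, breaking ties toward
fewer parameters, and never removes the grouping factor. The full trace
(step, dropped term, AIC) is returned.

`fit_model_family()` fits the family of winning models for every analysis
(Euclidean, Mahalanobis, midline distance, their previous-reward variants,
centroid shift, bout area and perimeter, latency, the learning-rate model
of touch distance, and the two bout-count models) over tables built from a
labeled trial set, and emits one tidy report row per coefficient.

## The synthetic cohort generator

The generator exists so that the full pipeline — labeling, metrics, bouts,
models — can be exercised and validated without recorded data. Its
defaults encode the study design it stands in for: 16 animals per sex,
8 sessions each, 300 trials per session. Per session it draws a fresh
probability walk; a latent state chain from the constrained HMM with stay
probabilities (0.9, 0.7); choices consistent with the chain; Bernoulli
rewards from the walk; and touches and response times conditioned on
state, sex and the previous trial's outcome. Ground-truth states and
per-animal parameters are returned alongside the trial table for recovery
testing.

Touches are truncated bivariate Gaussians centred on the chosen aperture.
The planted effect structure, chosen once at magnitudes plausible for
nosepoke data and not revisited, is: exploit SD 5 mm per axis vs explore
9 mm; explore means shifted 10 mm toward the screen midline; male
dispersion scaled by 1.2; dispersion after a rewarded trial scaled by
0.85; a per-animal log-normal dispersion multiplier (SD 0.1 on the log
scale) for individual differences; log-normal response times with exploit
0.25 log-units faster and males 0.2 log-units slower. Truncation (not
resampling) keeps touches inside the aperture mask, which mildly
compresses the largest dispersions — the cost of never producing an
impossible coordinate.

Explore-trial choices are emitted uniformly by default. Exploration in
this task means re-surveying both options, which is also precisely the
labeler's emission assumption; the alternative `explore_policy = "rlck"`
draws explore choices from the agent's softmax policy instead, which makes
exploration sticky and measurably harder to decode (label accuracy drops
from roughly 0.87 to 0.78 on otherwise identical cohorts). That option is
kept as a robustness probe, not as the study condition, and analyses of
labeler misspecification should use it deliberately.

What the generator does **not** model: within-trial reach trajectories,
biomechanics or screen-edge artefacts beyond truncation, session-level
fatigue or satiety drift, and any dependence of the walk on behaviour.
Passing the planted-effect tests therefore shows that the pipeline detects
the statistical structure it targets at the study's size, not that real
touch data satisfy the generative assumptions.

## Numerical choices and problem sizes

* Forward, backward and Viterbi recursions run scaled / in log space; a
  sequence impossible under the parameters has log-likelihood `-Inf`
  rather than an error in the likelihood path.
* EM stops when the absolute log-likelihood change drops below `tol`
  (default `1e-6`) or at `max_iter = 500`; the initial distribution is
  floored at `1e-10` before renormalisation so later decoding never hits
  a hard zero at trial 1.
* The RLCK likelihood floors per-trial probabilities at `1e-300`;
  optimisation uses bounds alpha in [0, 1], beta in [0, 20], bias in
  [-5, 5], kappa in [-10, 10], convergence `factr = 1e4`.
* Viterbi and stepwise-AIC ties break deterministically (lowest state
  index; fewer parameters).
* The test suite validates the simulator at 100 walks × 10,000 trials;
  parameter recovery with 50 replicates (16 × 300-trial sequences for the
  HMM, 8 × 300-trial sessions for the RLCK agent); and planted-effect
  recovery end to end on 25 full-size cohorts plus 40 null cohorts for
  calibration of the sex term's false-positive rate. These sizes are the
  package's chosen validation conditions; the underlying generators scale
  to arbitrary sizes.

## Known limitations

* The RLCK parameterisation ties the choice-kernel learning rate to the
  value learning rate; if the original agent used a free kernel rate, the
  recovered `kappa` absorbs part of the difference.
* Contour area and perimeter depend on the binning rule; quantities are
  comparable within one configuration, and only area/perimeter statistics
  (not boundary coordinates) are contractually meaningful.
* Wald p-values on ML mixed fits are mildly anticonservative for small
  numbers of animals; the calibration test bounds, but does not remove,
  this effect.
* With noisy state labels, inclusion rules that condition on decoded
  states can attenuate covariate effects (label noise leaks into the
  selection); the generator's `"rlck"` explore policy exists to study
  exactly this failure mode.
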