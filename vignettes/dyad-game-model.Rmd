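---
title: "A differential-game model of physically coupled dyadic reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A differential-game model of physically coupled dyadic reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadgame)
```

## The task and the model

Two players each hold a handle; a virtual spring of stiffness $k = 150$ N/m
connects the two handles. Both players reach from the same start to the same
target, 10 cm apart, in about 2 s — but each must pass through their *own*
via-point, unknown to the partner, while keeping the interaction force low.
The via-points lie on opposite sides of the straight path, so the players'
goals partly conflict: the dyad can negotiate a common path through both
via-points (low force), or each player can ignore the other (high force).

The package models the dyad as one linear discrete-time plant with two
inputs,

$$x(t+1) = A\,x(t) + B_1\,[u_1(t) + \eta_1(t)] + B_2\,[u_2(t) + \eta_2(t)],$$

where the 22-dimensional state holds, per player, planar position, velocity
and four muscle-activation states (two cascaded first-order lags per axis,
40 ms each, so a player's block has the eight state variables of standard
optimal-control reaching models), plus a constant goal block carrying the
target and both via-points so that tracking costs stay quadratic in the
state. The spring enters the velocity rows as $-k(p_i - p_{-i})/m$; the
interaction force on player $i$ is $F_i = -k(p_i - p_{-i})$, exactly equal
and opposite between players. Discretization is exact zero-order hold at
$dt = 10$ ms (the recording rate); a forward-Euler option exists for
convergence checks. Motor noise is additive Gaussian only.

Each player's goal is a quadratic cost over the horizon $T = 200$ steps:
a via-point term $w_{vp}\,\lVert p_i - vp_i \rVert^2$ applied at one via
time (0.35 T for player 1, whose via-point is near the start; 0.65 T for
player 2), terminal target and stopping terms, a running separation penalty
$w_f\,\lVert p_1 - p_2 \rVert^2$ (force is proportional to separation, so
this penalizes the interaction force up to the constant $k^2$), and a
control-effort term $u_i^\top R\, u_i$.

## Controllers

`solve_nash()` runs the backward coupled Riccati recursion for
finite-horizon feedback-Nash equilibria of two-player linear-quadratic
games: at each stage both players' first-order conditions form one linear
system in the stacked gains, solved exactly, with a documented failure
signal if the stage system is singular. `verify_nash()` checks the defining
inequality two ways: random unilateral gain perturbations (antithetic
pairs, so a cost gradient along the drawn direction cannot hide), and the
deviating player's *exact* best response to the partner's frozen gains — a
time-varying LQR — whose improvement is zero at a Nash solution and
strictly positive for any corrupted gain sequence.

`solve_no_partner()` is the package's model of non-collaboration: the
player drops the partner's input map and solves a single-player LQR,
treating the partner's force as zero-mean noise (by certainty equivalence
the assumed covariance does not change the gains). The no-partner dyad
shows the characteristic role alternation: each player actively pulls
(negative interaction power, "leader") just before their own via-point and
is dragged (positive power, "follower") near the partner's, because the
partner's via-point is task-irrelevant to them and, by the
minimum-intervention logic of optimal feedback control, not controlled.

## Observer and partner model

Each player estimates the dyad state from their own sensory stream with a
Kalman filter on an augmented state $[x; u_{-i}]$ that also carries the
partner's command, modeled a priori as AR(1):
$u_{-i}(t+1) = A_u u_{-i}(t) + \varepsilon$. Sensory channels per group:
own position (2 mm), own velocity (0.01 m/s), displayed via-point and
target (1 mm), and the interaction force — noisy for the haptic group
(1 N; the spring is weak, the percept unreliable) and much cleaner when
the force vector is displayed (VH, 0.3 N). The partner-visible group
additionally sees the partner cursor (1 mm). These noise levels are
config-overridable defaults; like the original study, the exact values are
not identifiable from first principles and were calibrated once so that
the model reproduces the qualitative group contrasts (H slowest and most
role-bound, PV closest to optimal), after which they were frozen.

Two observer choices deserve comment:

* **Prior strength.** With the command prior decaying at $A_u$ per step,
  a constant true command is recovered with a multiplicative shrinkage bias
  of roughly $(1-A_u)/(1-A_u+\kappa)$, where the innovation gain $\kappa$
  is limited by the two-stage activation lag rather than by sensory noise.
  A fast-decaying prior therefore biases the estimate by tens of percent
  regardless of group. The default $A_u = 0.998$ gives the prior a
  correlation time of several seconds — commands treated as near-constant
  on the movement timescale — keeping the bias near 2%, well below the
  sensory-driven fluctuation. $\Sigma_\varepsilon = (0.5\,\mathrm{N})^2 I$
  per 10 ms step.
* **Retrodiction.** Measurements carry information about *past* inputs, so
  after a trial ends the whole movement's data are used to reconstruct the
  partner's command sequence by fixed-interval (Rauch–Tung–Striebel)
  smoothing. The within-trial control loop uses the causal filtered
  estimate — a player cannot act on future data — but the across-trial
  partner model uses the smoothed series, which removes the causal filter's
  onset transient and tracking lag. Feeding the lagged causal estimate
  instead destabilizes the learning loop (see below).

## Learning through fictitious play

On every connected trial each player solves a best response to the
partner-command trajectory estimated from previous play (`best_response_policy()`):
the command enters the player's internal plant as a drift carried by a
constant dummy state, so the optimal controller has the usual feedback part
plus a feedforward part encoding the predicted partner action. The first
training trial uses a zero estimate and therefore equals the no-partner
policy exactly. Estimates are never updated from disconnected trials
(baseline, catch, after-effect), and after-effect trials reuse the last
training policies.

Because best responses are computed against a frozen input *sequence*, the
fixed point of this iteration is the **open-loop** Nash equilibrium of the
game, not the feedback-Nash solution of the coupled Riccati recursion: at
the feedback equilibrium a player's deviation would change the partner's
realized inputs, which a frozen sequence cannot represent. The two
equilibria are computed by different routes and genuinely differ here
(peak separation ≈ 1.3 cm at the open-loop equilibrium versus ≈ 0.5 mm for
feedback Nash under default weights). `fictitious_play_fixed_point()`
computes the open-loop equilibrium exactly by the coupled costate
recursion ($\Lambda(t) = I + S_1 P_1 + S_2 P_2$ with
$S_i = B_i R_i^{-1} B_i^\top$), and one further best-response round leaves
it unchanged to machine precision — the absorbing-state property of strict
equilibria under fictitious play, verified in the test suite.

**Belief aggregation.** The default aggregates the per-trial smoothed
estimates into their running empirical mean — the classical fictitious-play
belief. Using only the most recent trial's estimate is available as an
option but is not the default: in this plant the estimate-to-best-response
loop then escalates by ~40% per trial and diverges within an epoch,
because the causal estimate's lag turns the marginally stable mutual
best-response map unstable. The empirical-mean belief both damps the
iteration and lets estimate noise average out across trials.

## Calibration of the free parameters

The cost weights are not identifiable from the task description alone; they
were calibrated once, and frozen, against three requirements, in this
order:

1. noiseless Nash trajectories pass within 5 mm of both via-points and stop
   within 5 mm of the target (met by a wide range of settings; defaults
   $w_{vp} = w_{target} = 10^4$, $w_{stop} = 10$, $w_{effort} = 10^{-4}$
   reach ~0.02 mm);
2. the no-partner strategy produces *more* interaction force than the
   learned (open-loop-equilibrium) behavior, so that learning reduces
   force. The no-partner accommodation is reaction-lag-limited (separation
   floor ≈ 1 cm regardless of the force weight), while anticipatory
   coordination is not, so a sufficiently large force weight separates the
   two regimes; $w_f = 30$ gives no-partner ≈ 0.33 N versus ≈ 0.21 N at
   the equilibrium;
3. the stochastic learning loop remains stable: at $w_f \ge 60$ the noisy
   PV loop diverges, and at $w_f = 100$ the deterministic best-response
   map's spectral radius approaches one, so trial-to-trial noise is
   amplified without bound. $w_f = 30$ is comfortably inside the stable
   region.

Mass (1 kg per player), movement duration (2 s = the midpoint of the
instructed 1.85–2.15 s band) and motor noise (0.3 N per axis per step) are
plain defaults, stated in `dyad_params()`.

## What the synthetic data emulate — and what they do not

`make_protocol()` reproduces the session structure exactly: one baseline
epoch, ten training epochs with two randomly placed silent catch trials
each, two after-effect epochs, 12 movements per epoch, 156 in total.
`generate_group_dataset()` simulates five dyads per group and writes raw
trial CSVs (t, p1x, p1y, p2x, p2y, f1x, f1y, f2x, f2y at 100 Hz) plus one
matrix per indicator with one row per dyad and one column per trial — the
layout of the study's deposited indicator tables. `make_fixture_trial()`
builds model-free minimum-jerk trials through both via-points with one
player time-shifted, giving the indicator pipeline a controlled
leader-follower dose-response: the lead $\tau$ forces the sign of the
leadership indices by construction, and their magnitude grows with $\tau$.

The simulations are a model, not a re-creation of the human data. They do
not include signal-dependent motor noise (additive Gaussian only), within-
trial re-planning, adaptation of the internal plant model at coupling
onset, asynchronous movement starts, or any 3-D component (the vertical-
plane task is modeled in its two task-relevant dimensions). Passing tests
therefore show that the *mechanisms* — optimal coupled control, augmented
estimation, fictitious play — reproduce the study's qualitative contrasts,
not that the simulator matches human trajectories sample by sample.

## Indicator pipeline

Positions are smoothed by a 4th-order Savitzky–Golay filter with a 370 ms
window (37 samples at 100 Hz); velocities and accelerations come from the
same local fits. Movement start/end are the first/last crossings of a
2 cm/s speed threshold on the dyad mean speed. The displayed score is
$100 / (1 + e^{h(d_i - d_0)})$ with $d_i = d_{VP_i} + c\,d_{12}$, $c = 0.5$
when connected and $0$ otherwise; the logistic cannot literally reach 0 or
100, so $d_0 = 12.5$ mm (the midpoint of the saturation distances by
symmetry) and $h = 800\ \mathrm{m}^{-1}$ are set so the *rounded* score is
100 at $d_i \le 5$ mm and 0 at $d_i \ge 20$ mm. IF is the mean force
magnitude over the movement; $MD_{ij}$ the minimum distance of player $i$'s
path from via-point $j$; interaction power $P_i = F_i \cdot v_i$; the
leadership index $LI_{ij}$ averages $P_i$ over the 300 ms before via-point
$j$ is crossed by its homologous player, with the crossing operationalized
as that player's point of closest approach (the source texts do not define
"crossing" otherwise). $\Delta LI_1 = LI_{21} - LI_{11}$ and
$\Delta LI_2 = LI_{12} - LI_{22}$ quantify role specialization. Epoch means
exclude catch trials; the early/middle/late summary uses the first, sixth
and tenth training epochs (the customary "epoch 11" label counts the
baseline epoch, which would make "middle = 6" inconsistent, so training
epochs are indexed directly). The inter-player distance $d_{12}$ in the
score is averaged over the movement window. All indicator definitions use
planar components only.

## Problem sizes and numerical choices

Unit tests run on shortened horizons (60–80 steps) where the properties
under test are horizon-independent; the acceptance suite runs the full
configuration: 200-step trials, 156-trial protocols, five seeds per group
for the learning claims, ten seeds for the observer orderings, and 200
random policy deviations per player for the Nash inequality. Riccati and
covariance recursions symmetrize at every step; the stage-wise Nash system
and the innovation covariance are solved directly and failures are
reported with the offending step index. The constant-input recovery check
is asserted on the across-seed mean of the time-averaged estimate, because
a single run's 50-sample average still carries 6–8% sensory-driven
fluctuation around a ~2% bias. Trial-level seeds are drawn once from the
session seed, so whole sessions are bit-reproducible.

## A worked run

```{r, eval = FALSE}
plant <- build_plant()
costs <- list(build_cost(1, plant), build_cost(2, plant))

nash <- solve_nash(plant, costs[[1]], costs[[2]])
verify_nash(plant, costs[[1]], costs[[2]], nash, n_perturb = 200, seed = 1)

prot <- make_protocol("H", seed = 1)
session <- run_protocol(prot, plant, costs, seed = 101)
ind <- session_indicators(session)
aggregate_epochs(ind, prot)$summary
```

## Known limitations

The open-loop/feedback equilibrium distinction means the learned behavior
plateaus at the open-loop equilibrium's force level, above the feedback-
Nash floor, however good the information; human dyads may exploit richer
within-trial strategies. The H group's learning signal is small relative
to trial noise, as in the study, so single-seed learning curves are noisy;
claims about learning direction are Monte-Carlo averages. Group
differences depend on the declared sensory-noise defaults; they are
defensible but not measured quantities.
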