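---
title: "Models and methods behind evacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evacdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evacdyn)
```

`evacdyn` studies a laboratory evacuation paradigm: 50 participants, each
staked 100 points per one-minute run, watch the strike likelihood of an
approaching disaster update every second (displayed at 11 coarse levels)
and decide if and when to claim one of a limited number of shelter beds.
This vignette records the models the package implements, the choices made
where the design was genuinely open, and what the validation does and does
not establish.

## The threat process

The threat moves on an integer grid: forward distance shrinks every second
while the lateral position performs a random walk with steps uniform on
$\{-v,\dots,+v\}$ for a volatility $v \ge 1$. On arrival (forward distance
zero) the run records a Hit if the lateral position lies within the target
half-width $w$, otherwise a Miss. The strike likelihood
$q(t) = P(\mathrm{Hit} \mid \text{state at } t)$ is computed by backward
recursion over the walk, so it is exactly a martingale of the outcome —
this is checked against exhaustive path enumeration at small horizons and
by calibration over $10^4$ simulated trajectories.

Choices made where the specification was open:

* **Forward law.** CertainTime runs advance one step per second and resolve
  at exactly 60 s. VariableTime runs advance 1 or 2 steps with probability
  `p_fast = 0.5` of the double step; with an initial forward distance of 60
  this puts the arrival time in [30, 60] s with mean ≈ 40 s, and no explicit
  conditioning is required.
* **Display truncation.** The displayed level is the *floor* of $q$ to one
  decimal (so a display never overstates the likelihood); exact multiples
  map to themselves. Rounding conventions other than floor would shift
  every displayed level by at most one step and are not otherwise
  distinguishable.
* **Time indexing.** One-second half-open intervals $[t, t+1)$, with $q$
  constant within an interval and the at-home indicator measured at the
  interval start. The evacuation second itself therefore counts in the
  exposure $n$.

## The trajectory pool

The laboratory used 23 fixed trajectories chosen by the experimenters and
reused across runs. `trajectory_pool()` emulates that curation rather than
sampling blindly: a third of the pool slots must end in a Hit after
dwelling at least two seconds at display levels 0.6–0.9, a third must be
near-miss scares (a Miss reaching at least 0.4), and the rest are
unconstrained; volatility (1–4), half-width (1–4) and starting offsets are
cycled so that starting likelihoods span roughly 0.05–0.6. Without this
curation a random pool occasionally contains no informative high-likelihood
exposure at all, which no experimenter would field — and which would leave
the upper half of the rate curve unidentified. Part of the pool uses
half-width smaller than volatility, which keeps intermediate display levels
(0.7–0.9) reachable near arrival instead of jumping straight to 1.0.

## The synthetic experiment

A design of `n_runs` (47 by default, matching the laboratory; 188 = 4 × 47
in the recovery study) crosses shelter capacities {50, 40, 30, 20, 10}
(cycling fastest), the trajectory pool, three loss matrices, and eight
network topologies (ring lattices at distance 1–3 and five fixed-degree-
sequence random graphs, mean degree 4). Each second, every at-home agent
evacuates independently with probability given by the decision law at the
*displayed* likelihood — participants never saw the exact value, so the
display is what can drive behaviour. Evacuees claim beds in uniformly
random within-second order (the ordering is unrecorded in the paradigm);
once the shelter fills, later evacuees remain InTransit. Evacuation is
absorbing.

The loss-matrix values were never published; the package ships three
fixtures obeying the stated orderings — Miss column (0, 20, 30), Hit column
(100, 60, 30), scaled by 1, 1.5, and 0.5 to emulate varying severity. They
affect only scoring and the payoff analysis, not the decision law. Social
information likewise does not feed the decision law (nearly all laboratory
decisions were made while viewing the disaster display); networks are
generated and logged for interface completeness.

## Estimation and fitting

Rates are measured per partition cell by the Beta posterior
$R_k = (m_k+1)/(n_k+2)$, i.e. the conjugate posterior mean under a uniform
prior — taken exactly in this add-one form, with no alternative priors.
Cells never observed ($n_k = 0$) are emitted carrying only the prior,
flagged `unobserved`, and excluded from fitting.

Fits maximize the count-level Bernoulli log-likelihood
$\sum_k m_k \log r_k + (n_k - m_k)\log(1-r_k)$, the maximum-likelihood
objective to which that Beta posterior corresponds. Numerical choices:
rates are clamped to $[10^{-9}, 1-10^{-9}]$ inside logarithms; optimization
is box-constrained local refinement (`nlminb`, relative tolerance $10^{-8}$)
from a lattice of 27 starts over threshold × steepness × rate scale, so
fits are deterministic; the Hill coefficient is bounded to $[0.5, 40]$
because with 11 likelihood levels the model is indistinguishable from a
strict threshold beyond that; thresholds $\theta(B)$ outside $(0,1)$ are
clamped with a quadratic penalty. A fit is flagged degenerate when no
evacuations were observed or a rate parameter is pinned at its lower
bound. The three families are strictly nested (hill ⊂ capacity ⊂
six-parameter), and the test suite asserts the corresponding likelihood
ordering on every fitted data set.

Parameter uncertainty is by run-level bootstrap: whole runs resampled with
replacement, counts re-aggregated, model refit, SD taken over replicates.
Overfitting is gauged by leave-one-out cross-validation at the run level;
per-participant fits use the three-parameter law only (individual data are
too sparse to resolve capacity and urgency effects), and Pearson
correlations between individual parameters and cumulative score are
reported with two-sided p-values and no multiplicity correction, matching
their exploratory role.

## Prediction and payoff

The expected at-home curve follows
$H_{t+1} = H_t\,(1 - r(q_t; B, T(t)))$ from $H_0 = 50$. The recursion
predicts *decisions* and deliberately ignores shelter-capacity truncation
of realized arrivals: capacity caps bed assignment, not departures, so the
at-home count is unaffected. The strict-threshold payoff analysis plays a
solo model player who evacuates the first second the displayed level
strictly exceeds a threshold, ignoring capacity and time pressure; because
the display takes 11 values the payoff curve is piecewise constant with
breakpoints only at those levels, and on the default synthetic experiment
its optimum is strictly interior.

## Validation scale and limitations

The laboratory's raw logs were never deposited, so real-data results are
not reproducible; the package validates itself by parameter recovery. The
reference vector (`evac_model()` defaults: $h = 9.3$, $r_{T1} = 0.07$,
$r_{T2} = 0.37$, $r_{T3} = 0.13$, $\theta_0 = 0.60$, $c = 0.002$) is used
as generating truth; `recovery_study()` generates 20 repetitions of 188
runs × 50 agents and refits, recovering every parameter to within a few
percent on average. Problem sizes used by the test suite — $10^4$
trajectories for martingale calibration, $10^4$-replicate ensembles for the
expectation recursion, 47-run experiments for LOOCV — were chosen as the
smallest giving stable 3-standard-error comparisons.

What passing these tests shows: the generator, estimator, fitter, and
predictor are mutually consistent, the estimator is approximately unbiased
at the laboratory's data scale, and the pipeline is deterministic given a
seed. What it does not show: that real crowds follow a Hill law. The
synthetic generator embodies the fitted model's own assumptions —
independent per-second decisions driven only by $(q, B, T)$, no learning
across runs, no peer imitation, no reaction-time correlation — whereas the
laboratory data show adaptation over repeated trajectories and
capacity-scarcity reactions beyond the linear threshold model. The linear
$\theta(B)$ is a local description for $B \in [10, 50]$; the proportionality
constant is small and correspondingly hard to pin down from a single
synthetic experiment.
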