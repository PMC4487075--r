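---
title: "Modelling reward-rate optimality of the speed–accuracy trade-off in multisensory decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward-rate optimality of the speed-accuracy trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

In a reaction-time heading-discrimination task, observers judge whether
they are moving leftward or rightward of straight ahead from optic flow
(visual), inertial motion (vestibular), or both (combined), with the
visual reliability manipulated through motion coherence and all
conditions interleaved across trials. Because the conditions are
interleaved, any condition-specific setting of decision speed versus
accuracy must be chosen anew on every trial. `msddm` provides the
machinery to ask, on fully synthetic subjects with known ground truth:

1. does a decision-maker's speed–accuracy trade-off (the diffusion-model
   *bound*) earn a reward rate close to the best achievable one, and
2. do the *deviations* from the optimum look like the footprint of
   incomplete gradient-based learning — near-optimal bounds along
   directions where the reward surface is steeply curved, larger errors
   along shallow directions?

## The model

Evidence accumulation is a drift–diffusion process with unit diffusion
variance and time-varying drift. A trial's stimulus follows a
peak-normalized Gaussian-bell velocity profile $v(t)$ (standard
deviation 1/6 of the 2 s stimulus; the edge value is subtracted so the
profile starts and ends exactly at rest) with acceleration $a(t) =
\dot v(t)$. The momentary drift for heading $h$ is

* vestibular: $\mu(t) = k_{vest}\,\sin h\,\hat a(t)$, with $\hat a$ the
  peak-normalized magnitude of the acceleration (the discrimination
  signal scales with motion strength, so the informative component is
  rectified to a constant sign);
* visual: $\mu(t) = k_{vis}(c)\,\sin h\,v(t)$, with one sensitivity per
  coherence $c$;
* combined: $\mu(t) = \sin h\sqrt{k_{vis}(c)^2 v(t)^2 +
  k_{vest}^2 \hat a(t)^2}$ — the unit-variance reduction of
  reliability-weighted optimal cue combination.

The particle starts at `bias * theta` and is absorbed at $\pm\theta$.
Because the diffusion variance is normalized, $\theta$ is a *scaled*
bound (actual bound divided by the diffusion standard deviation); in
the *free* variant there is one $\theta$ per modality-by-coherence cell
($2C+1$ parameters for $C$ coherences), in the *parametric* variant one
actual bound per modality plus a linear coherence-to-standard-deviation
map $\sigma(c) = \sigma_0(1 - s\,c)$. If the particle has not been
absorbed by stimulus offset the choice is forced by the sign of the
accumulated evidence (ties split evenly). Reaction time adds a
per-modality non-decision time with ±50 ms uniform jitter; an optional
lapse mixes in stimulus-independent guesses.

## Numerics

`fpt_solve()` integrates the Fokker–Planck equation with a
Crank–Nicolson scheme (Thomas tridiagonal solves; the first four steps
use implicit Euler à la Rannacher so the delta initial condition does
not excite oscillatory modes). Mass absorbed per step is the loss of
interior probability, split between the two boundaries in proportion to
the diffusive flux (the density one node inside each bound). The
default grids are 1 ms in time and 201 spatial points; the contract is
accuracy, not the scheme: against the constant-drift closed forms
$P(\text{upper}) = 1/(1+e^{-2\mu\theta})$ and
$E[T_D] = (\theta/\mu)\tanh(\mu\theta)$ the solver is accurate to a few
$10^{-3}$ in choice probability and a few ms in mean decision time,
and total probability mass is conserved to well below $10^{-4}$.
`simulate_trials()` is the Monte-Carlo twin: Euler–Maruyama paths with
a Brownian-bridge correction for within-step boundary crossings, which
removes the leading discretization bias in crossing probabilities.

Likelihoods: the defective first-passage density of the chosen boundary
at $t = rt - t_{nd}$, convolved with the uniform non-decision jitter
(implemented exactly as a CDF difference across the jitter window, with
the forced-choice mass entering as a step at stimulus offset).
`fit_subject()` maximizes the summed log-likelihood over transformed
parameters (log for positive quantities, atanh for the bias) with
multi-start BFGS; the first start is a method-of-moments point
(non-decision time from the fastest responses minus 100 ms; per-cell
bound and sensitivity from accuracy and mean RT at the largest heading
via the constant-drift closed forms, corrected for the mean profile
amplitude).

## Reward rate and bound tuning

With per-cell accuracy $p_i$, mean decision time $\bar t_{D,i}$ and
mean reaction time $\bar t_{R,i}$ (marginalized over the design's
headings, equal cell weights $w_i$ by default), the reward rate is

$$f(\theta) = \frac{\sum_i w_i p_i - c \sum_i w_i \bar t_{D,i}}
{\sum_i w_i \bar t_{R,i} + t_{iti}},$$

with reward 1 per correct choice, inter-trial interval
$t_{iti} = 6$ s, and an optional evidence-accumulation cost $c$ (0 by
default; 0.1 and 0.2 reward units/s as variants, entering as a cost on
decision time subtracted from the numerator). `optimize_bounds()`
maximizes $f$ over the bound coordinates only, from 50 random restarts
by default (log-uniform in $[\hat\theta/5,\,5\hat\theta]$, plus the
fitted bounds themselves).

Two implementation choices matter here. First, the drift time courses
do not depend on the bounds, so the objective precomputes them and a
single-coordinate perturbation only re-solves the design cells that
coordinate feeds — finite-difference gradients cost about two function
evaluations rather than fifteen, and Hessians a couple of dozen.
Second, plain fixed-step gradient ascent with backtracking converges
impractically slowly on these surfaces (they are shallow, with
near-degenerate curvature and an exactly flat plateau where the bound
exceeds what the diffusion can reach in 2 s), so each restart runs
L-BFGS-B in log-bound space on the same finite-difference gradient,
box-constrained to $[10^{-4}, 10]$: beyond the reachable range bound
settings are behaviorally equivalent, and without the cap the optimum
is not identifiable along plateau directions.

`random_choice_rr()` is the zero-bound baseline (immediate guesses:
accuracy 1/2, decision time 0). `bound_scaling_curve()` evaluates $f$
along the ray $s\,\theta^*$; `project_to_bound_line()` places fitted
bounds on that ray either by following the iso-reward contour (solving
$f(s\,\theta^*) = f(\hat\theta)$ on the branch selected by the scalar
projection) or by plain vector projection.

## Curvature diagnostics

`reward_rate_hessian()` estimates $H = \nabla^2 f(\hat\theta)$ by
central differences (step $10^{-2}$ in bound units, with a half-step
Richardson consistency check that flags mismatches above 10%),
symmetrizes, and eigen-decomposes. `curvature_distance_analysis()`
projects $\theta^* - \hat\theta$ into the eigenbasis and pairs each
dimension's $|\lambda_i|$ with its $|\Delta'_i|$; eigenvalues are
reported signed but analysed by magnitude, dimensions with
$|\lambda| < 10^{-8}$ are tagged degenerate (untestable), and the
eigenvector matrix is exposed so the alignment of the eigenspace with
the original bound axes can be inspected rather than assumed.
`quadratic_loss_check()` compares the model's actual loss
$f(\theta^*) - f(\hat\theta)$ with the quadratic prediction
$\tfrac12|\Delta^\top H \Delta|$.

`simulate_learning()` implements the bound-update rule
$\theta_n = \theta_{n-1} + \alpha \nabla f(\theta_{n-1})$, and a
stochastic variant that perturbs a single bound per step and accepts
the change iff $f(\theta_n) > f(\theta_{n-1}) + \varepsilon$ with
zero-mean Gaussian $\varepsilon$ — both make faster progress along
steeper directions, which is the premise of the diagnostic.

## The synthetic cohort and what it does (and does not) emulate

The experiment's structure is emulated with a default design of
coherences {0.25, 0.37, 0.70} (only the highest is pinned down by the
task description; the others are plausible and configurable), headings
±{1, 2, 4, 8, 16}°, 2 s stimuli, 6 s inter-trial interval, interleaved
trial order, 100 trials per modality-by-coherence cell (a "recovery"
profile uses 400). The template subject has $k_{vest} = 5$,
$k_{vis}(c) = 4 + 9c$ (reliability grows with coherence; near-chance
performance at ±1°, near-ceiling at ±16°), scaled bounds of order one,
~300 ms non-decision times, and a small start-point bias (0.03).
Cohorts perturb sensitivities and bounds log-normally (sd 0.15) and
non-decision times and bias additively.

Truncated learners (`make_truncated_learner()`) replace a subject's
bounds with the endpoint of a prematurely stopped gradient ascent on
that subject's own reward surface. Two structural facts shaped the
defaults, both visible directly in the surface:

* Because the stimulus starts at rest, a very low bound is crossed by
  noise before any evidence arrives, so $\theta = 0$ (immediate
  guessing) is a genuine local maximum and the surface dips before its
  rising branch. Gradient learning started below that separatrix flows
  *away* from the optimum; the default start is therefore
  $0.6\,\theta^*$ rather than deeper down.
* The eigenvalue spread of $H$ at the optimum is modest under the
  default design (roughly a factor of two), and outside a small
  neighbourhood of $\theta^*$ the surface is visibly non-quadratic. The
  default truncation (5 steps, $\alpha = 0.5/\max|\lambda|$) therefore
  stops inside the locally quadratic neighbourhood, where the
  curvature-versus-distance diagnostic is faithful; the `"deep"` preset
  (2 steps, $\alpha = 0.3/\max|\lambda|$) produces subjects whose
  bounds sit well below the optimum (projections $s \approx 0.8$),
  which is the regime for the bound-line analyses.

The generator emulates the *structure* of such an experiment, not its
idiosyncrasies: no staircase adaptation, no session effects or
learning drift within the analysed trials, no RT contaminants beyond
the lapse mixture, and evidence reliability that follows the assumed
profile exactly. Passing tests on this cohort therefore show that the
pipeline recovers what it assumes, not that real observers satisfy the
assumptions.

## Statistical procedures

`wilcoxon_signed_rank_exact()` reports the signed-rank statistic $W$
(sum of positive ranks) with exact tail probabilities from the full
$2^n$ sign-assignment null — via the standard exact signed-rank
distribution when the absolute differences are untied, and via an exact
dynamic-programming convolution over doubled mid-ranks otherwise
(flagged non-exact in the classical sense). One-tailed means
$P(W \ge w)$ under the "greater" direction; two-tailed doubles the
smaller tail. `bootstrap_rr_ci()` gives seeded percentile intervals of
the empirical reward rate over trial resamples. Heading-0 trials are
credited 0.5 of a correct choice deterministically (identical in
expectation to the fair-coin convention, without injecting randomness
into an estimator).

## Problem sizes

The defaults above are the analysis conditions; the automated checks
run the same code at deliberately chosen sizes: solver oracles on a
12 s flat-drift window at 2 ms resolution; parameter recovery on five
cohort subjects at 100 trials/cell (one BFGS start from the
method-of-moments point, 10 ms / 61-point solver grids) plus one
subject at the 200 trials/cell recovery profile; bound optimization
with 3 restarts at 5 ms / 101-point grids; curvature and learner
diagnostics on cohort seeds 1–3; bootstrap coverage with 200 replicates
of 600 trials at 1000 resamples. These sizes keep each check
well-resolved while the full suite stays comfortably rerunnable;
all of them are plain arguments, so any check can be rerun larger.

## Known limitations

* The solver's boundary-flux split is first-order accurate at very
  small bounds ($\theta^2$ of the order of the time step); the
  immediate-decision limit is special-cased at $\theta < 10^{-8}$.
* The parametric variant fixes $\sigma_0 = 1$: it is exactly collinear
  with the per-modality bounds in the scaled model, so only the
  slope of the variance map is identifiable.
* `fit_subject()` returns a maximum-likelihood point, not a posterior;
  restart dispersion is the only multimodality guard.
* Reward-rate optima along plateau directions (bounds beyond the
  diffusion's reach) are identified only up to the box constraint; the
  corresponding Hessian eigenvalues are near zero and are tagged
  degenerate in the curvature analysis.
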