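---
title: "Levy-flight models of two-choice decisions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Levy-flight models of two-choice decisions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The diffusion decision model (DDM) describes a two-choice decision as a
noisy evidence total $X(t)$ that starts at $z = z_r a$, drifts at rate $v$,
and triggers a response when it reaches $a$ (upper boundary) or $0$
(lower).  The Levy-flight (LF) model keeps this architecture but replaces
the Gaussian within-trial noise with symmetric alpha-stable noise:

$$X(t + \Delta t) = X(t) + v\,\Delta t + e\,\Delta t^{1/\alpha},
\qquad e \sim \mathrm{Stable}(\alpha,\ \beta = 0,\ \gamma = 1/\sqrt2,\ \delta = 0),$$

with the stability index $\alpha \in [1, 2]$ free.  At $\alpha = 2$ the
noise is Gaussian with unit variance and the model is exactly the DDM; as
$\alpha$ decreases the increment distribution acquires power-law tails
($\lambda(x) \sim |x|^{-1-\alpha}$), so occasional very large jumps in
accumulated evidence become possible.  Psychologically, $\alpha$ has been
read as an index of the stability of the decision strategy: lower values
mean more sudden shifts in the evidence stream.  Values of $\alpha$ below 1
correspond to sub-diffusive regimes not considered in this literature and
are excluded by the parameter class.

Between-trial variability follows the DDM conventions: per-trial drift is
$\mathcal N(v, s_v)$, the relative start point is uniform on
$z_r \pm s_{zr}/2$, and non-decision time is uniform on $t_0 \pm s_t/2$.
The observable response time is the first-passage (decision) time plus the
non-decision draw.

## Parameters

| Parameter | Meaning | Units | Typical range |
|---|---|---|---|
| `v` | mean drift rate | evidence/s | 0.3–3.5 |
| `a` | boundary separation (caution) | evidence | 0.3–7 |
| `zr` | relative start point $z/a$ (bias) | — | 0.3–0.7 |
| `t0` | mean non-decision time | s | 0.15–0.8 |
| `alpha` | stability (jump) index | — | 1–2 |
| `sv`, `szr`, `st` | between-trial spreads of `v`, `zr`, `t0` | as parent | ≥ 0 |

The "typical ranges" double as the uniform training/ABC prior
(`default_priors()`); they were chosen once to cover the parameter regime
of practice data in a motion-discrimination task, where early-session
thresholds can be very high.  Two joint constraints are enforced when
sampling: the start window must stay inside $(0,1)$ and non-decision time
must stay non-negative.

The noise scale is fixed at $\gamma = 1/\sqrt2$ so that the $\alpha = 2$
case reproduces unit-variance Gaussian noise; no separate diffusion
coefficient is exposed.  This is the same identifying convention the DDM
uses (evidence units are defined by the noise).

## Simulation

`simulate_trials()` uses the Euler-type update above with default
`dt = 0.001` s.  The step size is a speed/accuracy compromise guarded by a
convergence test (halving `dt` leaves the choice fraction within
Monte-Carlo error); oracle-grade comparisons in the test-suite use
`dt = 1e-4`.  Absorption is recorded at the first step whose end state
reaches a boundary, at that step's end time, with no crossing-time
interpolation: with heavy-tailed jumps the sample path has no continuity
to interpolate, and the matching convention on the solver side (density
killed on all exterior nodes) keeps the two routes consistent.  Euler
discretization makes first passages slightly late and slightly too rare on
the side the process barely reaches; at `dt = 1e-4` this bias is below
Monte-Carlo error at the sample sizes used.

Trials that do not absorb by `t_max` (default 10 s) are resampled up to
100 times by the data generator, but only flagged (never resampled) in
likelihood contexts, where resampling would bias densities.  Whether the
original analyses resampled or discarded such trials is not stated
anywhere we could find; the two policies are both exposed.

The alpha-stable draws use the Chambers–Mulligan–Stuck transformation,
which is exact and O(1) per draw.  With $\beta = 0$ the S0 and S1
parameterization dialects coincide, so no dialect option is exposed;
skewed stable laws are out of contract.

## The fractional Fokker–Planck solver

The evidence density of a single trial solves

$$\frac{\partial p}{\partial t} + v \frac{\partial p}{\partial x}
  = \gamma^\alpha D_x^\alpha p, \qquad
  p(x, 0) = \delta(x - z),\quad p(0, t) = p(a, t) = 0,$$

where $D_x^\alpha$ is the Riesz fractional derivative,
$-\tfrac{1}{2\cos(\alpha\pi/2)}$ times the sum of the left and right
Riemann–Liouville derivatives.  The factor $\gamma^\alpha = 2^{-\alpha/2}$
matches the characteristic function of the simulator's increments,
$\exp(-\gamma^\alpha |k|^\alpha\, \Delta t)$; at $\alpha = 2$ the
right-hand side is then $\tfrac12 \partial_x^2 p$, the unit-variance
Wiener limit.  Stating the coefficient explicitly matters: without it the
equation would describe noise with scale $\gamma = 1$ and the solver would
not cross-validate against the simulator.

Discretization (`fpde_solve()`): shifted Grünwald–Letnikov weights for the
two one-sided derivatives, first-order upwind differencing for the drift,
implicit Euler in time.  The scheme is unconditionally stable and all
off-diagonal generator entries are non-negative, so densities stay
non-negative up to rounding.  The density is forced to zero on **all**
exterior nodes, not only the two boundary points — the killed-on-exit
convention a jump process requires — and the mass each step deposits
beyond either end is credited to that side, which yields the defective
first-passage densities `g_upper`, `g_lower` as a by-product with exact
discrete mass balance ($S(t)$ plus cumulative exits $= 1$).  At $\alpha = 1$
the Riesz prefactor is singular; the solver requires $\alpha > 1$.

Defaults `nx = 200`, `nt = 800`, `T = 3` s put the survival curve within
0.01 of the analytic Wiener answer at $\alpha = 2$ and within 0.02 of
Monte-Carlo survival at $\alpha < 2$.  Pointwise accuracy of the exit
*densities* near their early sharp peak needs finer grids (the stepping is
first-order in time); the suite uses `nx = 400, nt = 12800` for that one
check.  Between-trial variability is handled outside the equation — which
describes a single trial — by Gauss–Legendre mixture quadrature with 5
nodes per varying parameter (the Normal drift mixture is truncated at
$\pm 3$ SD).  Upward/downward jump probabilities that appear in some
derivations of this equation are not exposed: with symmetric noise they
are equal.

## Likelihood approximation

No closed-form likelihood exists for $1 < \alpha < 2$.  Two approximations
are provided and cross-checked against each other and, at $\alpha = 2$,
against the exact Wiener series:

* **kde** (default): simulate `n_kde` trials per epoch at the candidate
  parameters; evaluate observed RTs against a Gaussian kernel density on
  log response times of the matching choice (Silverman bandwidth), scaled
  by the simulated choice probability so densities are defective.  Covers
  all five model variants uniformly.
* **pde**: interpolate the solver's defective exit densities, shifted by
  non-decision time (5-node quadrature over the `st` window).  Intended
  for no-variability or quadrature-variability configurations.

Densities are floored at $10^{-10}$: an observed RT below the minimum
possible non-decision time contributes the floor (with a warning semantics
of "impossible under this parameter vector") rather than $-\infty$.

## Amortized estimation

Five model variants are compared, all with epoch-wise decision thresholds
$a_1,\dots,a_4$ over four practice epochs of 240 trials: epoch-wise
$\alpha$ (11 free parameters); epoch-wise $s_v$, $s_{zr}$, or $s_t$ with a
single $\alpha$ (12 each); and epoch-wise $v$ and $\alpha$ jointly (14).

Each variant gets its own convolutional regression network
(`lf_train()`).  A dataset is encoded as four channels (one per epoch) of
choice-signed response times, sorted ascending — sorting removes trial
order, the sign carries the choice, and position within a channel then
means "quantile level".  The network has five convolutional layers with
64, 64, 128, 128, 128 filters, max-pooling between layers, a flattened
(position-preserving) linear head, and is trained with Adam (learning rate
$10^{-3}$, 0.95 per-epoch decay, early stopping on a 10% validation split)
to minimize MSE on min–max-normalized parameters over datasets simulated
from the uniform prior.  Kernel width (9) and the head were selected by
validation loss; the filter counts and channel structure follow the
reference architecture.  Outputs are point estimates clipped to the prior
support; optional uncertainty comes from a nonparametric bootstrap of
trials within epochs.  Whether such a network returns posterior means or
maximum-likelihood-style points is not formally defined; MSE training
targets the posterior mean under the training prior, and the shrinkage
that entails is visible in recovery studies (see Limitations).

The intended full-scale budget is 28000 training datasets; development,
the test-suite, and the acceptance script use scaled-down budgets (4000
for the headline recovery checks; a few hundred for the four control
variants, whose role there is only to provide plausible competing fits;
1000 in the acceptance script) with the same architecture.  One network
serves all three feedback conditions of a study — parameters vary freely
across conditions anyway, so the amortized mapping is condition-agnostic.

A rejection-ABC fitter (`abc_estimate()`) is kept as a network-free
reference: standardized Euclidean distance on per-epoch accuracy and RT
quantiles (0.1/0.3/0.5/0.7/0.9 per response side), top-1% acceptance,
posterior mean of accepted draws.  Sides with fewer than five trials fall
back to pooled-epoch quantiles so the summary vector keeps fixed length.
These summaries identify thresholds and drift well but carry little
information about $\alpha$ — recovery correlations for $\alpha$ hover near
0.15–0.2 regardless of reference-table size — which is precisely the
motivation for the trained summary network.

## Model comparison

`information_criteria()` implements two conventions.  The default,
`convention = "paper"`, reproduces the published fit table arithmetically:
summed over participants, $\mathrm{AIC} = -2\log L + K$ and
$\mathrm{BIC} = -2\log L + K\ln n$ with $K$ the total parameter count
(per-participant $k$ times 30 participants) and $n = 960$ trials per
participant.  Note the AIC penalty is $K$, not the textbook $2K$; the
textbook forms are available as `convention = "standard"`.  With the
printed log likelihoods, the first two models' AIC/BIC reproduce exactly;
the remaining three are off by one unit in the last digit, consistent with
rounding of unprinted log-likelihood decimals.

`epoch_change_summary()` reports the across-participant mean of
per-participant percent changes, $100(\theta_4 - \theta_1)/\theta_1$.
Published condition-level percentages cannot be recovered from the
across-participant mean estimates (mean of ratios versus ratio of means);
the per-participant mean is the definition used here.  Predictive checks
use type-7 (linear-interpolation) quantiles at levels
0.1/0.3/0.5/0.7/0.9, with a side reported as missing when it has fewer
than five trials.

## The synthetic study generator

`generate_study()` emulates a fixed-trial practice design: three feedback
conditions with 10/9/11 participants (low/medium/high information), four
epochs of 240 trials, and an accuracy exclusion rule (participants below
70% accuracy are removed; the boundary case is retained).  Ground-truth
trajectories are centered on the published condition means for the
epoch-varying-$\alpha$ model — thresholds fall with practice, $\alpha$
rises, most strongly under high-information feedback — with
between-participant SDs equal to the square roots of the published
across-participant variances, truncated to the training-prior support.
Individual epoch values are drawn independently around the trajectory.
The upper boundary is defined as the correct response (positive drift);
real-data ingestion would need an explicit correct/error coding since
stimulus direction is not modeled.  The original 24-blocks-of-40 structure
is not simulated; epochs are generated directly, because all analyses
operate on epochs.

What the generator does *not* emulate: learning dynamics (trajectories are
imposed, not emergent), feedback content, within-epoch non-stationarity,
contaminant responses, and any cross-epoch correlation of individual
parameter draws.  Passing recovery tests on these data therefore shows
that the estimation machinery works under the model's own assumptions; it
does not certify behavior on real data.

## Problem sizes

Statistical checks in the test-suite run at: $10^5$ trials for
simulator-level comparisons ($10^6$ draws for noise-level ones), solver
grids of $200 \times 800$ (with one $400 \times 12800$ density check),
4000 training datasets for the headline recovery network, 40 synthetic
participants for recovery scoring, and 20 replicates for model-recovery
ranking.  The acceptance script uses 1000 training datasets and 20
participants.  These sizes were chosen so the whole suite completes in
tens of minutes on a single core while keeping Monte-Carlo error well
below each tolerance being asserted.

## Limitations

* Epoch-wise $\alpha$ at 240 trials per epoch is intrinsically noisy: with
  the generator's between-participant spread, the per-participant sign of
  the epoch-1 to epoch-4 $\alpha$ change is recovered for only roughly six
  to seven in ten synthetic participants at the scaled-down training budget, and
  decomposition shows the residual error is dominated by posterior
  uncertainty rather than network approximation error, so more training
  simulations would not change it.  Condition-level mean changes are
  recovered much more reliably than individual signs.  MSE-trained point
  estimates also shrink extreme per-epoch contrasts toward zero.
* The `pde` likelihood path requires $\alpha > 1$ strictly and becomes
  expensive under quadrature mixing of several variability parameters.
* The exact trained weights behind any published estimates are not
  reproducible here; analyses of real data would need their own training
  run at full budget.
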