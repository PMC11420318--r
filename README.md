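# levydm: Levy-flight evidence-accumulation models of two-choice decisions

`levydm` implements the Levy-Flight (LF) sequential-sampling model of
simple decision making and the analysis pipeline built around it, for
mathematical psychologists and cognitive modelers who want to ask whether
evidence accumulation contains sudden large "jumps" — and whether the jump
parameter changes systematically with practice.

The LF model generalizes the diffusion decision model (DDM).  Evidence
X(t) starts at z = z_r·a, drifts at rate v toward absorbing boundaries at
0 and a, and is perturbed each time step by symmetric alpha-stable noise:

    X(t + Δt) = X(t) + v·Δt + e·Δt^(1/α),   e ~ Stable(α, β = 0, γ = 1/√2, δ = 0)

with stability index α ∈ [1, 2].  At α = 2 the noise is Gaussian and the
model is exactly the DDM; lower α gives the increments power-law tails
(λ(x) ~ |x|^(−1−α)), allowing rare, large jumps in accumulated evidence.
A response is produced when X(t) ≥ a (upper) or X(t) ≤ 0 (lower); observed
response time adds a non-decision component t0.  Between-trial variability
in drift (sv), start point (szr) and non-decision time (st) follows DDM
conventions.

The package covers the full pipeline:

* **Stable noise**: exact Chambers–Mulligan–Stuck sampling, densities and
  CDFs by characteristic-function inversion (`rstable`, `dstable`,
  `pstable`).
* **Simulation**: trial- and dataset-level forward simulation with
  censoring policies (`simulate_trials`, `simulate_dataset`), in C++.
* **Fractional solver**: the space-fractional Fokker–Planck equation of
  the evidence density (Riesz derivative via shifted Grünwald–Letnikov
  weights, implicit time stepping), giving survival curves and defective
  first-passage densities (`fpde_solve`, `survival`, `fpde_fpt`).
* **Likelihoods**: simulation-based kernel estimates or solver-based
  densities (`log_likelihood`), exact Wiener series at α = 2.
* **Amortized fitting**: a convolutional regression network trained on
  simulated datasets maps sorted choice-signed response times (one channel
  per practice epoch) to parameter estimates in one forward pass
  (`lf_train`, `lf_fit`, `estimate`), with a rejection-ABC fallback
  (`abc_estimate`).
* **Model comparison**: five model variants (epoch-wise α; epoch-wise
  sv/szr/st; epoch-wise v and α) ranked by log likelihood, AIC and BIC
  (`lf_model`, `compare_models`, `information_criteria`), epoch-change
  summaries and predictive checks.
* **Synthetic studies**: a generator of practice-design datasets (three
  feedback conditions, four epochs of 240 trials, accuracy exclusions)
  with known ground truth for recovery scoring (`generate_study`).

## Worked example

```r
library(levydm)
set.seed(42)

# accumulation noise: alpha = 2 is Gaussian, alpha < 2 heavy-tailed
p <- stable_params(alpha = 1.5)
round(dstable(0, p), 4)
#> [1] 0.4064        # = Gamma(1 + 1/alpha) / (pi * gamma)

# one practiced participant: threshold falls, alpha rises across epochs
truth <- Map(function(a, al) lf_params(v = 1.3, a = a, zr = 0.5,
                                       t0 = 0.46, alpha = al),
             a = c(4.51, 1.79, 1.91, 1.43),
             al = c(1.33, 1.39, 1.47, 1.50))
trials <- simulate_dataset(truth, n_per_epoch = 240)
tapply(trials$rt, trials$epoch, function(x) round(mean(x), 3))
#>     1     2     3     4
#> 2.223 1.099 1.091 0.923   # practice speeds responses (threshold drop)

# survival probability from the fractional solver (epoch-4 parameters):
# chance the decision is still unmade at t = 0, 0.3, 0.6, 0.9 s
g <- fpde_solve(truth[[4]], nx = 200, nt = 800, T = 3)
round(survival(g)[c(1, 81, 161, 241)], 3)
#> [1] 1.000 0.632 0.256 0.101

# fit-table arithmetic under the published convention
# (AIC = -2 logL + K, BIC = -2 logL + K ln 960; K = 30 participants x 11)
information_criteria(logL = -61624, k_total = 330, n_per_participant = 960)
#>      AIC      BIC
#> 123578.0 125514.1
```

Fitting uses a trained estimator — `est <- lf_train("alpha_varying",
training_config(n_datasets = 4000))` (minutes of simulation + training;
the full-scale default is 28000) — after which `coef(lf_fit(trials,
estimator = est))` returns the 11-parameter estimate for a participant in
a single forward pass, and `compare_models()` tabulates AIC/BIC across
variants.  See the vignette in `vignettes/levy-flight-models.Rmd` for the
model, numerical methods, and design decisions.

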