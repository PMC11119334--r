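# epmixreg

Joint order and variable selection for finite mixtures of linear
regressions with exponential power errors.

## The problem

Heterogeneous regression data — where observations arise from several
latent sub-populations, each with its own regression relationship — are
modeled by a finite mixture of linear regressions (FMLR):

    f(y | x) = Σ_{j=1}^m π_j f_{p_j}(y − xᵀβ_j; 0, σ_j)

Two model-selection questions come with every FMLR analysis: how many
components `m` are there, and which covariates enter each component's
coefficient vector β_j? `epmixreg` answers both simultaneously by
maximizing a doubly penalized likelihood

    Q̃_n(θ) = Q_n(θ) − n Σ_j Σ_t p_{λ1}(|β_jt|)
                     − n λ2 Σ_j [log(ε + p_{λ2}(π_j)) − log ε],

where `p_λ` is the SCAD penalty: the first term thresholds irrelevant
coefficients to zero, the second shrinks redundant mixing weights to zero
so that a fit started from a generous number of components collapses to
the supported order. The errors follow the exponential power
(generalized Gaussian) density `f_p(x; 0, σ) ∝ exp(−½|x/σ|^p)` with a
shape `p_j > 1` estimated per component — Gaussian at `p = 2`, Laplace at
`p = 1`, heavy-tailed below 2 — which makes the fit robust to outliers and
heavy-tailed noise where a Gaussian-error mixture breaks down.

Estimation uses a modified EM algorithm: posteriors in the E-step; an
exact simplex maximization of the locally linearized mixing penalty for
the weights; a closed-form scale update; a bounded one-dimensional shape
search; and a coefficient update that majorizes the `|r|^p` loss into
iteratively reweighted least squares combined with a local quadratic
approximation of the SCAD penalty. The penalty levels `(λ1, λ2)` are
chosen by a modified BIC, `−2 loglik + log(n)·(3m̂ − 1 + M̂_β)`, over a
grid. The intended users are statisticians and quantitative researchers
fitting regression mixtures to possibly contaminated data.

## Worked example

Simulate one benchmark dataset — three regression components with
coefficients `(1,1,1,1,0,0,0)`, `(1,2,3,4,0,0,0)`, `(5,6,7,8,0,0,0)`,
weights `(0.4, 0.3, 0.3)`, standard normal errors, `n = 600` — and let the
MBIC-tuned fit recover the structure starting from five components:

```r
library(epmixreg)
dat <- generate_scenario(scenario_spec(1, n = 600), seed = 42)
sel <- epmix_select(dat$x, dat$y, m_max = 5, grid = study_grid(),
                    control = study_control(), seed = 42)
print(sel)
#> MBIC-tuned EP mixture regression: m_hat = 3, MBIC = 2701.38, df = 20
#>   selected lambda1 = 0.15, lambda2 = 0.045
#> Mixture of 3 regression component(s), 7 covariate(s)
#>           pi  sigma      p  beta1  beta2  beta3  beta4 beta5 beta6 beta7
#> comp1 0.4107 0.9828 2.0796 1.0958 1.1563 0.9274 0.9175     0     0     0
#> comp2 0.3118 0.8754 1.7488 0.7185 1.9030 3.1072 3.9476     0     0     0
#> comp3 0.2775 1.1955 2.8740 5.0258 5.8939 7.1171 8.0104     0     0     0
```

Reading the output: the order is selected correctly (`m_hat = 3`), the
estimated weights and coefficients sit close to the truth, all twelve
noise coefficients are exact zeros (SCAD thresholding), the scales are
near the true value 1, and the shapes hover around the Gaussian value 2,
as they should under normal errors. `df = 20` counts 2 free weights,
3 scales, 3 shapes and 12 nonzero coefficients.

For data on disk, `read_dataset("data.csv", response = "y")` loads a
design matrix and response (`--standardize` z-scores scale-heterogeneous
covariates; penalties are scale-sensitive), `epmix_fit()` fits at fixed
penalties, and `write_fit()`/`read_fit()` serialize results as JSON. A
thin command-line driver with `fit`, `select` and `simulate` verbs lives
in `inst/exec/epmixreg.R`.

Monte-Carlo studies of the whole pipeline (order-selection proportions,
RMSEs of weights and coefficients, correct/incorrect zero counts over
replicates, for four error laws ranging from Gaussian to
infinite-variance t-mixtures) run through `run_study()`; see the methods
vignette (`vignettes/epmixreg-methods.Rmd`) for the model, the algorithm,
and the reasoning behind every tunable default.

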