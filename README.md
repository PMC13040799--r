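# mgpm — Bayesian inference for mixed Gaussian phylogenetic models

Continuous traits measured across related species are not independent
observations: they share an evolutionary history described by a phylogenetic
tree. A mixed Gaussian phylogenetic model (MGPM) lets different parts of that
tree evolve the trait under different Gaussian diffusions — Brownian motion
(`dx = σ dW`) or an Ornstein–Uhlenbeck process
(`dx = -α(x - θ) dt + σ dW`) — by painting the tree's edges into *regimes*,
each with its own process and parameters, all sharing one root state `X0`.
Over an edge of length `l` the trait transition is Gaussian,
`N(a·x_parent + b, V)`, with

* BM: `a = 1`, `b = 0`, `V = σ² l`
* OU: `a = e^{-αl}`, `b = (1 - e^{-αl}) θ`, `V = σ²(1 - e^{-2αl})/(2α)`

`mgpm` fits these models in a Bayesian way, for people (evolutionary
biologists, phylogenetic comparative methods users) who want posterior
uncertainty and biologically calibrated priors rather than bare maximum
likelihood point estimates. The package provides:

* an `O(n)` pruning likelihood (C++ kernel) plus an independent dense
  multivariate-normal oracle used to verify it;
* priors calibrated from the phylogenetic half-life (`t½ = ln 2 / α`) and
  from a plausible trait variance at the tips;
* posterior simulation by Laplace-initialized Population Monte Carlo
  (importance sampling → multinomial resampling → local-kernel
  rejuvenation), returning a weighted posterior sample `{Θᵢ, wᵢ}`;
* model evaluation by the posterior predictive loss
  `Σᵢ (xᵢ - m̃ᵢ)² + λ Σᵢ s̃ᵢ²` and its complexity-penalized variants
  (`λ = ln p`, `λ = p`);
* a multi-start maximum-likelihood baseline, forward simulation, seeded
  simulation-study harnesses, and a small command-line wrapper
  (`inst/cli/mgpm.R`).

## A worked example

Simulate a two-regime OU dataset on a random 40-tip unit-height tree and
re-infer the parameters:

```r
library(mgpm)

tree     <- random_ultrametric_tree(40, seed = 11)
painting <- random_painting(tree, 2, seed = 11)   # Ancestral + clade R1
model    <- mgpm(tree, painting, kinds = "OU", priors = "diffuse")

truth <- c(X0 = 0, alpha_Ancestral = 2, theta_Ancestral = 2,
           sigma_Ancestral = 1, alpha_R1 = 5, theta_R1 = 0, sigma_R1 = 0.5)
x   <- simulate_tips(model, truth, nsim = 1, seed = 12)[1, ]
fit <- mgpm_fit(model, x, nsample = 2000, seed = 7)
fit
```

```
MGPM posterior fit: 7 free parameter(s), S = 2000, ESS = 332.4
log-evidence estimate -12.3225; 6635 likelihood evaluations
Posterior summary (S = 2000, ESS = 332.4)
       parameter    mean     sd   mcse     q2.5     q50   q97.5
              X0  0.4701 8.6679 0.4425 -16.3812  0.2277 17.4945
 alpha_Ancestral  5.8880 3.1866 0.1984   2.2372  5.0651 13.7693
 theta_Ancestral  1.4025 0.1599 0.0146   1.0600  1.4095  1.7099
 sigma_Ancestral  1.1740 0.3105 0.0173   0.7754  1.1115  1.9393
        alpha_R1 11.2041 5.6615 0.3116   2.7956 10.4647 25.3041
        theta_R1  0.0124 0.0414 0.0022  -0.0912  0.0173  0.0847
        sigma_R1  0.5867 0.1834 0.0113   0.2769  0.5678  1.0083
```

Reading the output: each row is a free parameter in the layout order
`(X0, regime blocks)`; `mean`/`sd` are weighted posterior moments, `mcse` the
Monte Carlo standard error of the mean, and `q2.5`–`q97.5` the equal-tailed
95% credible interval. Here the optima (`theta_*`) and diffusion rates
(`sigma_*`) are recovered well; the rate parameters (`alpha_*`) are
right-skewed and sit above their generating values — at 40 tips the data say
little about how fast a near-stationary OU regime reverts, a known feature
of these models. `X0` is dominated by its prior because selection erases the
root signal over a unit-height tree. `ESS` is the effective sample size of
the weighted draws.

Model fit is scored by the posterior predictive loss (lower is better):

```r
ppl(fit, x, lambda = 1, S_p = 2000, seed = 14)
```

```
Posterior predictive loss: 7.2455 (SSE 3.3368 + lambda 1 x variance 3.9088)
```

`summary()`, `coef()`, `credible_interval()`, `predict()` (predictive
replicates or exact per-tip density curves), `simulate()`, `residuals()` and
`plot()` operate on the fitted object; `model_comparison()` ranks several
fitted models by the loss at `λ ∈ {1, ln p, p}`. Prior calibration for a real
tree of height `t_H` looks like:

```r
alpha_prior_from_halflife(14.02854, halflife_fraction = 0.01, p = 0.95)
# Half-Normal(scale = 2.521)   (95% quantile at alpha* = 4.941)
```

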