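# funclust

Function-informed soft clustering of microbial communities.

## The problem

Microbial community functions — butyrate production in the gut, nitrate
reduction in soil slurries, nutrient cycling in the ocean — are collective:
they are driven by *groups* of taxa whose summed abundance predicts the
function far better than any single member. Given paired tables of community
composition `X` (N samples × n features; species, ASVs, genera, or gene
modules) and measured function `F` (N × m; a metabolite concentration or a
time series), `funclust` learns simultaneously

* a grouping of the n features into a small number K of functional groups, and
* a (possibly nonlinear) structure–function map from group abundances to F,

so that the grouping is shaped by what it must predict, not by co-occurrence
alone.

## The model

For an abundance row `x`, group abundances are `g = (γ ⊙ x) C`, where
`γ = sigmoid(ℓ)` is an optional learnable gate (an L1 penalty `β‖γ‖₁`
sparsifies the active feature set) and `C` is an n × K clustering matrix with
approximately one-hot rows. A small fully connected network predicts
`f̂ = NN_θ(g)`, and everything is trained end to end on

```
L = (1/B) Σᵢ ‖fᵢ − f̂ᵢ‖² + β‖γ‖₁ .
```

The discrete assignment is made differentiable by the Gumbel-softmax
relaxation: with per-feature assignment probabilities `P` (row-wise softmax
of learned logits), each training step samples

```
C = softmax_rows( (Γ + log P) / τ ),   Γᵢⱼ ~ Gumbel(0,1),
```

with the temperature τ annealed exponentially from 1.0 to 0.1. Rows of `C`
are approximately one-hot, their argmax is distributed exactly per `P`, and
gradients flow from the prediction error back into the clustering. An
ensemble of models trained on independent 80/20 splits is distilled into a
consensus grouping by ranking members on held-out R², aligning group labels
across members, and majority vote.

The package also includes:

* a **synthetic benchmark** with known ground truth (12 species, 3 groups,
  regime-switching linear coefficients, hence a globally nonlinear map);
* **baselines**: co-occurrence clustering + linear/neural maps (Models I/II),
  simulated-annealing function-informed clustering + linear map (Model III),
  and PCA + linear regression;
* **Jaccard recovery scoring** against a known grouping;
* a **two-biomass consumer–resource model** of nitrate reduction
  (Monod kinetics on nitrate A and carbon C), with an adaptive ODE reference
  (deSolve), a piecewise-analytic approximation used for fitting, per-sample
  parameter inference (yields γ₁, γ₂ global; rates r₁, r₂ and carbon
  depletion time t* per sample), and abundance-matched null-model
  comparison with empirical p-values.

See the vignette `vignettes/function-informed-clustering.Rmd` for the full
methods account.

## Worked example

```r
library(funclust)

# 500 samples, 12 species in 3 planted groups, nonlinear regime-switching f
bm  <- generate_benchmark(seed = 1)
ens <- train_ensemble(bm$abundance, bm$functions, benchmark_config(seed = 1))
ens
#> <funclust_ensemble> 12 members, 12 features -> 3 groups; held-out R2 median 0.950 (range 0.888..0.975)

cons <- consensus(ens, top_fraction = 0.25, align_by = "overlap")
tidy(cons)
#> # A tibble: 12 x 4
#>    feature_id group active agreement
#>    <chr>      <int> <lgl>      <dbl>
#>  1 sp1            3 TRUE           1
#>  2 sp2            3 TRUE           1
#>  3 sp3            3 TRUE           1
#>  4 sp4            3 TRUE           1
#>  5 sp5            2 TRUE           1
#>  ...

jaccard_index(bm$truth, cons)$total
#> [1] 1
```

The ensemble's median held-out R² of ~0.95 says the learned groups plus the
neural map explain most of the function's variance on unseen samples; the
total Jaccard of 1 says the consensus grouping recovers the three planted
groups exactly (0.85 would mean one of twelve species misplaced). Group
labels are arbitrary; only the partition matters.

Fitting the consumer–resource model to a synthetic incubation series:

```r
ds  <- generate_crm_dataset(n_samples = 4, seed = 3)   # 2 mM nitrate, 4 days
fit <- fit_crm(ds$observations,
               crm_fit_config(gamma_grid_points = 8, n_restarts = 3, maxit = 300))
fit
#> <crm_fit> gamma1 = 0.4, gamma2 = 2.44 (1/mM), 4 samples, total objective 1.742e-07
```

recovering the generating yields (0.4 and 2.44 per mM) and, in
`tidy(fit)`, the per-sample rates and depletion times to within a few
percent.

A thin command-line interface over the same functions ships in
`inst/exec/funclust` (subcommands `benchmark`, `train`, `scan`, `consensus`,
`baselines`, `crm-fit`, `crm-null`).

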