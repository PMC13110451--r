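# sgbfa — supervised graph-guided Bayesian factor analysis

`sgbfa` is for analysts integrating several omics blocks measured on the
same samples — say SNP counts, gene expression and metabolite
abundances — who want one joint low-dimensional representation of all
blocks *and* a regression of clinical outcomes on that representation,
with known biological networks (pathways, interaction graphs) steering
which features are selected together.

## The model

Each modality $X^{(h)} \in \mathbb{R}^{p_h \times n}$ (Gaussian,
binomial/binary, or negative-binomial with a logit link) shares latent
factors $Z \in \mathbb{R}^{L \times n}$ through

$$\mu^{(h)} = m^{(h)} 1^\top + W^{(h)} Z ,$$

and continuous outcomes follow $y_j = \beta_{j0} + Z^\top \beta_j +
\varepsilon_j$. Loadings get dual-shrinkage Laplace priors with rate
$\phi^{(h)}_l \lambda^{(h)}_{jl}$ — a modality-level factor that can
zero out whole blocks (making factors all-shared, subset-shared or
modality-specific) and a feature-level factor whose logarithms are
coupled through a graph-constrained Wishart prior on their precision
matrix $\Omega$, so network-linked features are co-selected. Inference
is MCMC (Pólya–Gamma augmentation for count likelihoods,
normal–exponential mixtures for the Laplace priors, block Gibbs for the
graph-constrained $\Omega$), and $(\nu_1, \nu_2, L)$ are tuned by a DIC
grid search. The methods vignette
(`vignettes/sgbfa-methods.Rmd`) derives every layer.

## Worked example

Simulate the `ai` benchmark design (five Gaussian modalities, two
all-shared and two modality-specific factors, star-pathway graphs, one
outcome), fit at the true graph, and predict the held-out samples:

```r
library(sgbfa)

spec <- scenario_spec(structure = "ai", family = "gaussian", H = 5, p = 100,
                      n = 150, n_train = 100, n_outcomes = 1, sigma_y2 = 1,
                      graph_variant = "G2", seed = 42)
sim <- simulate_dataset(spec)

fit <- sgbfa_fit(sim$train$data, L = 4, outcomes = sim$train$outcomes,
                 graph = sim$graph,
                 config = chain_config(n_iter = 1500, n_burnin = 750, seed = 1))
fit
#> <sgbfa_fit> L = 4, 5 modalities (gaussian, gaussian, gaussian, gaussian, gaussian), 1 outcomes
#>   150 stored draws, mean loglik -14354.79, MH acceptance 0.37, 5.6s

classify_factors(fit)
#> # A tibble: 4 × 4
#>   factor type       n_active active_modalities
#>    <int> <chr>         <dbl> <list>
#> 1      1 all_shared        5 <int [5]>
#> 2      2 all_shared        5 <int [5]>
#> 3      3 specific          1 <int [1]>
#> 4      4 specific          1 <int [1]>

pm <- posterior_mean_mu(fit)
rre(pm$mu_hat, sim$train$mu)
#> 0.116

pred <- sgbfa_predict(fit, sim$test$data)
mean(mse_outcomes(sim$test$outcomes, pred$Y_hat))
#> 1.41
```

The classification recovers the generating structure exactly (two
factors loaded by every modality, two by a single one). The relative
reconstruction error of 0.12 means the posterior-mean $\hat m 1^\top +
\hat W \hat Z$ captures ~99% of the squared signal (a zero estimate
scores 1.0). The held-out MSE of 1.41 sits close to its floor — the
outcome noise variance $\sigma_y^2 = 1$ — so the re-fitted factors carry
almost all the predictable outcome variation.

`tidy(fit)`, `glance(fit)`, `autoplot(fit)` and `plot_dic()` give tidy
summaries and plots; `sgbfa_tune()` runs the DIC grid search;
`write_bundle()`/`read_bundle()` serialize datasets as TSV + JSON
bundles; `exec/sgbfa` exposes `simulate`, `fit`, `tune`, `predict`,
`evaluate` and `repro-sim2` subcommands for shell pipelines.

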