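# rwce — random-walk cluster ensembles for multi-omics consensus clustering

`rwce` finds one consensus partition of a sample cohort from one or several
omics data matrices (e.g. mRNA expression, miRNA expression, DNA
methylation on the same tumors). It is aimed at cancer-subtyping style
analyses, where single clustering runs are unstable and no single data type
tells the whole story, but applies to any matched multi-view tabular data.

## The method

Given $M$ crisp base clusterings $\Pi=\{\pi^{(1)},\dots,\pi^{(M)}\}$ of $n$
instances (generated here by k-means with a random cluster count per run),
the consensus is built by **random-walk refinement**:

1. pool $\Pi$ into the binary instance-cluster matrix
   $\mathrm{IC}\in\{0,1\}^{n\times K}$, $K=\sum_m K_m$;
2. connect clusters by the Jaccard index of their instance sets,
   $J_{xy} = |L_x\cap L_y|\,/\,|L_x\cup L_y|$;
3. diffuse with a random walk with restart,
   $F_{t+1} = \alpha F_t\hat A + (1-\alpha)F_0$, $F_0=\mathrm{IC}$,
   iterated to $\max|F_{t+1}-F_t| < 10^{-6}$;
4. compare walked cluster profiles with the scaled exponential kernel
   $\mathrm{sim}(C_i,C_j)=\exp(-\rho^2(z_i,z_j)/2\sigma^2)$;
5. fill the zero entries of IC with per-clustering normalized similarity
   (the refined instance-cluster matrix, RIC), member entries staying 1;
6. cut the weighted bipartite graph
   $W=\begin{pmatrix}0&\mathrm{RIC}\\\mathrm{RIC}^\top&0\end{pmatrix}$
   by normalized-cut spectral clustering, choosing $k$ at the largest
   eigengap of $L_{\mathrm{sym}} = I - D^{-1/2}WD^{-1/2}$.

For $T$ data types the per-view consensus clusterings form a new
$T$-member ensemble that is refined once more — the integrated subtyping.

## Worked example

```r
library(rwce)

sim <- simulate_multiview(n = 150, k = 3, views = 3, features = 30,
                          separation = 6, noise_fraction = 0.2, seed = 42)
fit <- run_integration(sim$views, rwce_config(ensemble_size = 20, seed = 42))
fit
#> <rwce_consensus> 'integration': 150 instances in 3 clusters
#>   random walk: 1 iterations, residual 0.00e+00
#>   integrated views: view1, view2, view3

glance(fit)
#> # A tibble: 1 × 7
#>   source          n chosen_k k_auto eigengap rwr_iterations rwr_residual
#>   <chr>       <int>    <int> <lgl>     <dbl>          <int>        <dbl>
#> 1 integration   150        3 TRUE      1.000              1            0
```

Three views of 150 samples share a planted 3-cluster structure; the
integrated fit selects `chosen_k = 3` by the eigengap (here the gap is a
full 1.000 because the three groups separate cleanly) and labels every
instance. `tidy(fit)` returns the `instance_id`/`label` table;
`autoplot(fit)` draws the Laplacian spectrum with the chosen k marked.

Scoring the result against the simulation truth and simulated survival:

```r
sv <- simulate_survival(sim$truth$label, hazard_ratios = c(1, 2, 4),
                        censor_rate = 0.2, seed = 42)
evaluate_clustering(sim$views$view1, fit$labels,
                    truth = sim$truth$label, survival = sv)
#> # A tibble: 1 × 6
#>       n     k silhouette   ari logrank_stat   logrank_p
#>   <int> <int>      <dbl> <dbl>        <dbl>       <dbl>
#> 1   150     3      0.224     1         29.5 0.000000387
```

Adjusted Rand index 1 means the planted partition was recovered exactly;
the silhouette of 0.22 reflects the 6-SD separation with 20% noise
features in the raw view; the log-rank p of 3.9e-7 confirms the three
recovered subtypes separate the simulated survival curves.

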