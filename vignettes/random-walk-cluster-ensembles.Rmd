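---
title: "Random-walk cluster ensembles: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk cluster ensembles: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwce)
```

## The problem

Molecular subtyping asks for one partition of a patient cohort from several
heterogeneous data types — say mRNA expression, miRNA expression and DNA
methylation measured on the same tumors. Any single clustering run on any
single data type is unstable: the result moves with the algorithm's
initialization, the chosen number of clusters, and the data type itself.
Cluster-ensemble methods embrace that instability: generate many cheap
*base clusterings*, then combine them into one *consensus* partition that is
more stable than any member.

The usual summary of an ensemble — a binary instance-by-cluster membership
matrix, or an instance-by-instance co-association matrix — is coarse: it
records only which cluster each instance fell into, not how the clusters of
different runs relate to each other. This package refines that summary with
a random walk over a cluster-similarity network before partitioning, so
that "hidden" associations between an instance and the clusters it did
*not* join are filled in from the network structure.

## The procedure

Let $\Pi = \{\pi^{(1)},\dots,\pi^{(M)}\}$ be $M$ crisp base clusterings of
$n$ instances, with $K_m$ clusters in clustering $m$ and
$K = \sum_m K_m$ pooled clusters.

1. **Pool.** The binary instance-cluster matrix
   $\mathrm{IC} \in \{0,1\}^{n \times K}$ has a 1 where the instance
   belongs to the cluster; every row sums to $M$.
2. **Cluster network.** Clusters are linked by the Jaccard index of their
   instance sets, $J_{xy} = |L_x \cap L_y| / |L_x \cup L_y|$. Clusters of
   the same base clustering are disjoint, so within-clustering edges are 0;
   the diagonal is 1.
3. **Random walk with restart.** Starting from $F_0 = \mathrm{IC}$, iterate
   $F_{t+1} = \alpha F_t \hat A + (1-\alpha) F_0$ until
   $\max |F_{t+1}-F_t| < 10^{-6}$. Here $\hat A$ is the row-normalized
   Jaccard network (see *Numerical choices*), $\alpha$ the retention
   probability and $1-\alpha$ the restart probability. The fixed point
   $F_\infty = (1-\alpha) F_0 (I - \alpha \hat A)^{-1}$ is a real-valued
   association matrix that sees the whole network, not just one-step
   overlaps.
4. **Kernel similarity.** Walked cluster profiles (columns of $F_\infty$)
   are compared with the scaled exponential kernel
   $\mathrm{sim}(C_i,C_j) = \exp(-\rho^2(z_i,z_j)/2\sigma^2)$, $\rho^2$ the
   squared Euclidean distance.
5. **Refined associations.** The refined instance-cluster (RIC) matrix
   keeps 1 for the instance's own cluster in each clustering and fills each
   other cluster $C$ of that clustering with
   $\mathrm{sim}(C, C^*) \big/ \sum_{C' \ne C^*} \mathrm{sim}(C', C^*)
   \times d_c$, where $C^*$ is the instance's cluster. Normalization is
   strictly per clustering.
6. **Bipartite cut.** RIC defines a weighted bipartite graph on
   $n + K$ vertices, $W = \begin{pmatrix} 0 & \mathrm{RIC} \\
   \mathrm{RIC}^\top & 0\end{pmatrix}$, partitioned by normalized-cut
   spectral clustering: eigenvectors of the $k$ smallest eigenvalues of
   $L_{\mathrm{sym}} = I - D^{-1/2} W D^{-1/2}$, row-normalized, clustered
   by k-means. With `k = "auto"`, $k$ maximizes the eigengap
   $\lambda_{i+1}-\lambda_i$ over $i \ge 2$.

For $T$ data types, steps 1–6 run per view; the $T$ per-view consensus
clusterings then form a new $T$-member ensemble that is refined once more
(`run_integration()`).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `ensemble_size` (M) | 50 | base clusterings per view; more buys stability at linear cost |
| `k_min`, `k_max` | 2, $\lceil\sqrt n\rceil$ | range of the per-run cluster count K; `k_range_mode = "linear"` raises the cap to $n-1$, which mostly produces near-singleton clusterings |
| `alpha` | 0.9 | walk retention; higher diffuses similarity further across the network, 0 reduces the method to raw membership |
| `sigma` | 1 | kernel bandwidth on walked profiles |
| `dc` | 1 | association mass split among a clustering's non-member clusters |
| `tol` | 1e-6 | walk convergence, max absolute entrywise change |
| `k` | `"auto"` | consensus cluster count, or eigengap selection |
| `eigengap_max` | 15 | eigengap search ceiling (subtype counts beyond ~10 are rarely interpretable) |

`alpha`, `ensemble_size` and the K-range cap are standard but not canonical
choices; they are exposed in `rwce_config()` precisely because the method's
definition does not pin them down.

## What the simulator emulates — and what it does not

`simulate_multiview()` draws each view as a Gaussian mixture: all views
share one latent partition (deterministic largest-remainder class sizes),
each view has its own centers, unit within-cluster standard deviation, a
`separation` equal to the minimum pairwise center distance in SD units, and
a `noise_fraction` of features carrying no class signal. This captures the
premise of multi-omics integration — several noisy, partly-redundant
reflections of one subtype structure — and makes ground truth available, so
recovery (adjusted Rand index), model selection (chosen k) and survival
separation can be tested exactly.

It does not emulate real omics marginals: no count overdispersion, no
bounded methylation beta values, no feature correlation blocks, no batch
effects, and no missing samples across views. Passing tests therefore show
that the pipeline recovers planted mixture structure and honors its
contracts — not that it will find clinically meaningful subtypes in any
particular cohort.

`simulate_survival()` draws exponential event times with cluster-specific
hazards and independent Uniform$(0,b)$ censoring; $b$ is solved by
`uniroot()` so the expected censored fraction under the cohort's mean
hazard equals `censor_rate`. Under equal hazards the log-rank p-value is
uniform, which the test suite uses for calibration.

## Numerical choices

* **Transition matrix.** The walk update multiplies by the raw Jaccard
  adjacency in its textbook form, but $\alpha \|A\| \ge 1$ makes that
  iteration divergent. The package row-normalizes to
  $\hat A = D^{-1}J$ by default, the standard random-walk-with-restart
  formulation, which converges for any $\alpha < 1$; `normalize_adjacency
  = FALSE` restores the raw iteration (and errors with a divergence message
  when it blows up). The unit Jaccard diagonal keeps every row sum positive,
  so isolated clusters simply hold their mass.
* **Similarity floor.** The RIC normalization divides similarities by their
  block sum. When every non-member similarity is numerically negligible
  (well-separated clusters push the exponential kernel to ~1e-20), that
  ratio amplifies noise into a full unit of association on an arbitrary
  cluster. Similarities below `sim_floor = 1e-8` are therefore treated as
  absent links and the fill-in is skipped — the same behavior as the exact
  zero-denominator case.
* **Two-cluster blocks.** When a clustering has exactly two clusters, the
  non-member ratio is 1 by construction, so with $d_c = 1$ the non-member
  association equals the member's. The definition is kept as stated; users
  clustering ensembles dominated by K = 2 members should lower `dc`.
* **Eigengap range.** A bipartite graph's normalized-Laplacian spectrum is
  symmetric about 1, so every low-end gap reappears mirrored at the top.
  The search is capped at half the spectrum (and at `eigengap_max`);
  near-ties within 1e-9 resolve to the smaller k.
* **Embedding k-means.** k-means++ seeding, 20 restarts, seeded from the
  pipeline seed; zero rows of the spectral embedding are left unnormalized
  with a warning.
* **Sub-seeding.** The master seed is scrambled with a stream index
  (`derive_seed()`) for every stochastic stage, and per-view streams derive
  from the view *name*, so per-view results do not depend on the order the
  views are listed.
* **Degenerate inputs.** Empty k-means clusters are relabelled to a
  contiguous 1..K; an instance with an all-zero refined row is an error (it
  cannot be cut into any part); all-zero cluster columns are dropped with a
  warning.

## Problem sizes in the test suite

Unit and property tests run on instances of 4–500 points. The end-to-end
recovery study uses the conditions the package treats as its reference
synthetic benchmark: $n = 300$, three views of 50 features, 3 latent
clusters at 6-SD separation with 20% noise features, $M = 30$, swept over
10 seeds. Statistical calibration uses 2000 null survival simulations at
$n = 200$. These sizes keep the full suite in the low minutes on one core
while leaving every property at a scale where failure modes are visible.

## Known limitations

* Cohorts must be matched across views; there is no handling of missing
  samples or partial overlap.
* The method is as good as its base clusterings: k-means bases inherit
  k-means' bias toward spherical, similarly-sized clusters. Precomputed
  base clusterings from any algorithm can be supplied via `as_ensemble()`.
* The two-cluster blur above means ensembles consisting *only* of K = 2
  clusterings carry no refinable signal at the default $d_c$.
* Spectral partitioning is dense ($O((n+K)^3)$ eigendecomposition);
  cohorts beyond a few thousand instances would need a sparse or
  randomized eigensolver.
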