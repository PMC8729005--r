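---
title: "Decomposing marginal correlations along network paths: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing marginal correlations along network paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairpath)
```

## The model

A Gaussian graphical model (GGM) on $n$ jointly Gaussian variables is
specified by its partial correlation matrix $\mathbf{P} = \{\pi_{ij}\}$:
$\pi_{ij}$ is the correlation of nodes $i$ and $j$ conditional on all other
nodes, and an edge is present exactly when $\pi_{ij} \neq 0$. Writing
$\mathbf{A}$ for the *normalized precision matrix* ($a_{ii} = 1$,
$a_{ij} = -\pi_{ij}$), the marginal Pearson correlation matrix is

$$\mathbf{C} = \mathbf{D}^{-1}\mathbf{A}^{-1}\mathbf{D}^{-1},
\qquad d_{ii} = \sqrt{(\mathbf{A}^{-1})_{ii}},$$

valid whenever $\mathbf{A}$ is positive definite. `pairpath` implements this
map (`correlation_from_partial()`), its inverse
(`partial_from_correlation()`), and — the point of the package — an exact
rewriting of $c_{ij}$ as a sum over network topology. For every simple path
$p$ joining $i$ and $j$ in the support graph, let
$\tau_p = \prod_{(k,l) \in p} \pi_{kl}$ be the product of partials along the
path and

$$\gamma_p \;=\; \tau_p\,
\frac{|\mathbf{A}_{p^*}|}{\sqrt{|\mathbf{A}_{i^*}|\,|\mathbf{A}_{j^*}|}},$$

where $\mathbf{A}_{p^*}$ deletes every node of $p$ (the empty determinant is
1, a convention forced by the three-node closed form) and
$\mathbf{A}_{i^*}$ deletes only $i$. Then
$c_{ij} = \sum_{p \in \mathcal{P}_{ij}} \gamma_p$ exactly. Because all
weighting determinants are principal minors of a positive definite matrix,
they are positive and $\operatorname{sign}(\gamma_p) =
\operatorname{sign}(\tau_p)$. The package verifies the identity numerically
rather than re-deriving it: the acceptance suite reconstructs $c_{ij}$ from
paths against independent matrix inversion on 500 random models to
$10^{-10}$.

The **pair-path subscore** normalizes the contributions:
$s_p = |\gamma_p| / \sum_q |\gamma_q|$ — the fraction of the marginal
association attributable to path $p$; scores lie in $[0,1]$ and sum to 1.
In estimation, enumeration is truncated at a user cutoff $K$
($\hat{s}^K_p$): paths longer than $K$ score 0. The relative ranking of two
paths of length $\le \kappa$ is the same for every $K \ge \kappa$, so
truncation is safe for *identifying* top paths even when the scores
themselves are still biased.

## Tunable parameters

* **`K` (path-length cutoff, dimensionless, default: full enumeration in
  the core functions, 4–5 recommended in practice).** Worst-case cost grows
  as $O(N!/(N-K)!)$ on a complete support; on a support with mean degree
  $\mathcal{D}$, roughly $O(\mathcal{D}^K)$. The truncation-sensitivity
  experiment (below) shows the error of $\hat{s}^K$ falls steeply as $K$
  first grows, then *rises slightly* once $K$ exceeds the lengths of paths
  whose estimated contributions are pure noise — setting tiny contributions
  to zero beats estimating them. An all-purpose $K$ of 4–5 sits in the flat,
  low-sensitivity regime; the Erdős–Rényi expected-path-length helper
  (`er_expected_path_length()`) supports this: a 100-node network needs a
  mean degree below 2.4 before expected path length exceeds 5.
* **`zero_threshold` (support-graph edge threshold, default 0).** Graphical
  lasso estimates contain exact zeros, so the exact default is right for
  them; for dense inverse-Pearson estimates a documented small threshold
  (`1e-10`) screens float noise if desired.
* **Positive-definiteness tolerance (`1e-10` on the minimum eigenvalue).**
  Separates genuine model invalidity from floating-point noise; inversion
  goes through symmetric (Cholesky) factorization and outputs are
  symmetrized before determinant ratios are formed.
* **Graphical lasso penalty `lambda` (default `"cv"`).** 5 folds and a
  30-point log-spaced grid on $[10^{-3}, 1] \cdot \max|s_{ij}|$, selected by
  mean held-out Gaussian log-likelihood
  $\log\det\hat\Theta - \mathrm{tr}(S_{\text{test}}\hat\Theta)$. These CV
  details are conventional choices declared here, not values inherited from
  a reference; fold assignment is seed-deterministic. EBIC, StARS and
  FPR-controlled selection are deliberate non-goals (extension points).
* **Bootstrap `B` (default 1000) with the percentile method**; the
  coverage test runs at a reduced `B = 200`, which already attains nominal
  coverage at `n = 1000`. Coverage is a property of bootstrap *calibration*
  and is therefore measured with a statistic whose bias vanishes at this
  `n`: enumeration on the true support, exactly as in the truncation
  experiment. On a dense estimated support the statistic itself is biased
  by noise paths in the denominator (see limitations) and no resampling
  interval around it can cover the truth.

## What the simulator states, and what it does not

`random_ggm()` draws Erdős–Rényi edges with probability 0.2 and edge
partials uniform on $(-1, 1)$, unit-variance Gaussian marginals — the
stated generative world for all experiments. Positive definiteness is
enforced by rejection sampling (redraw up to a budget), which preserves the
stated marginals *conditional on acceptance*. That conditioning is not
neutral: at the default wide partial range, dense draws are rejected more
often, and the accepted 10-node models average edge density ≈ 0.14 rather
than 0.20. The test suite documents this deviation and verifies the
Bernoulli mechanism where acceptance is near-certain (narrow partials).
The generator emulates sparse random topologies with exchangeable nodes; it
does not emulate features of real metabolomics networks such as scale-free
hubs, block structure from chemical classes, measurement error, or
non-Gaussian tails — so a green simulation test establishes correctness of
the machinery on the stated world, not field performance.

`sample_gaussian()` draws $X = Z\,\mathrm{chol}(\mathbf{C})$ with fresh
standard normals $Z$, rather than delegating to an external multivariate
normal generator: same distribution, one fewer dependency, and
reproducible from the seed alone.

## The two experiments

* **Truncation sensitivity** (`k_sensitivity_experiment()`): percent error
  $|\hat{s}^K_{p_{\max}} - s_{p_{\max}}| / s_{p_{\max}}$ of each pair's true
  best path across $n$ and $K$. Enumeration runs on the *true* support with
  estimated partials plugged in. This is a deliberate design choice: with a
  dense inverse-Pearson estimate the estimated support is complete and no
  finite $K$ is ever exact, whereas on the true support the largest $K$
  coincides with the untruncated estimator — which is the regime the
  experiment is designed to probe (pairs with any path longer than
  $\max K$ are excluded for the same reason).
* **Path identification** (`success_rate_experiment()`): the fraction of
  replicate datasets on which the estimated top path equals the true one,
  per pair and sample size, stratified by true path length and by the
  smallest $|\pi|$ on the true path. The cross-validated graphical lasso
  materially beats plain inversion at small $n$ because exact zeros remove
  noise paths from the denominator.

Both experiments are pure functions of (model, config, seed); plugging the
truth in as an "oracle" estimator yields perfect scores by construction,
which the tests assert.

## Numerical and design choices

* Determinants are computed in log space from symmetric factorizations and
  cached by removed-node set; the same principal minor recurs across the
  many paths sharing a node set, and the cache is shared across pairs in
  whole-network scans.
* Path enumeration delegates to `igraph::all_simple_paths()` with a depth
  cutoff; results are then ordered deterministically (length, then
  lexicographic node sequence), which also fixes tie-breaking for the
  arg-max path across platforms.
* Paths are *vertex*-simple. The submatrix $\mathbf{A}_{p^*}$ removes "the
  nodes of the path", which is ill-defined if a node repeats, so
  vertex-simplicity is the only consistent reading even though the path
  definition is sometimes phrased edge-wise.
* A pair with no connecting path decomposes to an empty table with
  reconstructed correlation 0 — and the implied marginal correlation is
  indeed 0 (block structure). When contributions cancel to a near-zero
  marginal correlation, subscores remain defined (they normalize absolute
  contributions); the table flags the cancellation instead of dividing by
  zero.
* The graphical lasso is implemented in-package (block coordinate descent,
  off-diagonal penalty, $W$ initialized at $S + \rho I$) because no sparse
  precision estimator is available in the supported dependency set; at
  $\rho = 0$ it reduces to plain inversion and it was cross-checked against
  an independent implementation during development. Exact zeros are
  propagated so that lasso supports really are sparse in enumeration.
* Cross-condition comparison of two scans handles support mismatch by
  comparing a pair connected in only one condition against 0 with a
  `one_sided` flag; bootstrap replicates where a statistic is undefined are
  recorded as missing rather than silently dropped. Whether the lasso
  penalty should be re-selected on each bootstrap resample is genuinely
  open; the pipeline re-selects by default and exposes a frozen-$\lambda$
  path through the `lambda` config field, since the choice materially
  affects interval width.
* "Connected with", for per-node averages, means joined by at least one
  enumerated path within $K$ (adjacency-only averaging can be had by
  filtering the scan to `length == 1`).

## Known limitations

* Reliable identification of top paths needs large samples ($n > 1000$ in
  the 10-node world) because noise in near-zero partials propagates into
  every denominator; regularization mitigates but does not remove this.
* Enumeration cost on dense supports limits $K$ (the complete-graph count
  grows factorially); the package reports path counts per pair so users can
  see the lever they control.
* High subscores say nothing about mechanism by themselves: a high edge
  score means only that little of the pair's correlation is routed through
  the rest of the network. Mapping paths onto biochemical pathways requires
  external biological information, and confounding (e.g. shared sources)
  applies exactly as in multiple regression.
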