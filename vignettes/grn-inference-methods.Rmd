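---
title: "Methods: kernel-PC regression boosting for regulatory network inference"
author: "kpcboost authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-PC regression boosting for regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpcboost)
```

## The inference problem

`kpcboost` treats gene regulatory network reconstruction as unsupervised
classification: for each ordered pair (TF $p$, gene $j$) it estimates the
posterior probability $\hat C_{j,p} = P(C_{j,p} = 1 \mid x)$ that $p$
regulates $j$, from an expression matrix of $G$ genes by $n$ steady-state
samples and a user-supplied list of $P$ transcription factors. The central
modelling assumption is additive regulation with arbitrary smooth links:

$$x_i^{(j)} = \sum_{p \in A_j} f\!\left(x_i^{(p)}\right) + \varepsilon_i^{(j)},
\qquad \varepsilon_i^{(j)} \sim N(0, \sigma_j^2),$$

where $A_j$ is the (small) set of regulators of gene $j$. Nothing about
$f$ is assumed beyond continuity: it is represented nonparametrically
through kernel principal components.

## Kernel principal-component regression

For each TF the RBF kernel
$K_{iu} = \exp(-(x_i^{(p)} - x_u^{(p)})^2/\gamma)$ is computed on the
standardized expression vector, double-centered in feature space
($\bar K = K - 1_{nn}K - K1_{nn} + 1_{nn}K1_{nn}$, $1_{nn}$ the matrix of
$1/n$), and eigendecomposed. Because the RBF feature space spans all
polynomials of the input, the leading kernel principal components (KPCs)
can approximate any continuous regulator–target relationship while costing
only an $n \times n$ decomposition per TF. The KPC columns are normalized
to unit Euclidean norm, which makes them orthonormal regressors: the
least-squares fit of a residual vector $\varepsilon$ on one TF's KPC block
$g$ is simply $\beta = g^\top \varepsilon$, no inversion needed. Boosting
shrinks this to $\beta = \nu\, g^\top \varepsilon$.

Two conventions are worth stating because they are genuinely open choices:

* **Eigenvector scaling.** One can either keep eigenvectors unit-norm and
  divide regression coefficients by the eigenvalues, or absorb the
  eigenvalues into unit-norm *projections*. We do the latter: unit-norm KPC
  columns with $\beta = \nu g^\top\varepsilon$, which is the exact
  least-squares solution for orthonormal regressors scaled by $\nu$ and
  removes the ambiguity entirely.
* **Component retention.** The eigenvalue threshold is *relative*:
  component $i$ is kept when $\lambda_i \ge$ `eig_threshold`
  $\cdot\,\lambda_1$, default $10^{-6}$. A relative rule is scale-free in
  $n$ and in the kernel magnitude. Eigenvalues in $[-10^{-10}, 0)$ —
  numerical noise of the symmetric decomposition — are clipped to zero
  first; a TF whose centered kernel has no positive eigenvalue (a constant
  expression profile, for instance) is excluded and receives zero posterior
  everywhere. Eigenvector signs are fixed so the largest-magnitude entry of
  each component is positive; fits are sign-invariant, this only pins down
  reproducible output. We impose no cap on the number of retained
  components beyond the threshold.

## Greedy boosting and Bayesian model averaging

Enumerating all $2^P$ TF subsets per gene is infeasible, so the model space
is explored greedily, mirroring least-angle-regression-style boosting:

1. Iteration 1 scores every candidate TF (all non-excluded TFs except the
   gene itself — self-regulation is excluded by design, since a gene's
   expression trivially predicts itself and benchmark gold standards carry
   no self-loops) as a singleton model.
2. The TF with the highest unnormalized log posterior is selected (ties go
   to the lowest TF index, for determinism), the shrunken component is
   subtracted from the residuals, and each subsequent iteration scores
   every candidate as an extension of the selected prefix. With $\nu < 1$
   the same TF can be selected repeatedly — a sign of a strong effect.

Each model $A_j^{(d)}$ is scored in log space by
$\log P(A_j^{(d)}) + \log \pi(A_j^{(d)})$ with the Jeffreys-marginalized
likelihood $P(A_j^{(d)}) \propto \mathrm{RSS}^{-(n-1)/2}$ and a binomial
prior $\pi(A_j^{(d)}) = \prod_p w_{j,p}^{[p \in A]}(1-w_{j,p})^{[p \notin A]}$
over the *distinct* member set (a TF selected twice counts once in the
prior and in edge membership). The posterior
$\hat C_{j,p}$ averages over **every model evaluated at any iteration**,
not only the selected ones — the Occam's-window flavour of model
averaging; with `iterations` $\times$ $P'$ explored models per gene the
weights are normalized by log-sum-exp, which keeps the computation exact
for any $n$ (raw likelihoods would underflow beyond $n \approx 50$).

Finally the variance-scaling heuristic multiplies each TF column of
$\hat C$ by its sample variance (denominator $G-1$). A TF with a flat
posterior profile across genes — equally plausible everywhere, hence
uninformative — is damped, while a TF with a few confident targets is
preserved; within a column the ranking is unchanged. The raw matrix keeps
probability semantics; the scaled one is better suited to cross-TF
ranking.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `gamma` | 60 | RBF width on standardized expression (dimensionless after standardization). Large widths keep the kernel near-linear while retaining curvature in the leading components. |
| `nu` | $10/n$ if $n>10$, else $0.5$ | Shrinkage in $(0,1]$. The likelihood exponent $(n-1)/2$ makes posteriors overconfident as $n$ grows; $\nu \propto 1/n$ flattens RSS differences to counteract exactly that growth. The cut at $n>10$ is strict: $n = 10$ uses 0.5. |
| `iterations` | 3 | Boosting rounds, which is also the maximum number of TFs per gene model. Most genes have few direct regulators; three keeps the explored set small and the false-positive pressure low. |
| `eig_threshold` | $10^{-6}$ | Relative eigenvalue retention. |
| `tau` | 0.2 | Probability threshold for extracting a discrete network, applied to the **raw** matrix: the scaled matrix lives on a different scale than a probability cutoff. `threshold_network(use_scaled = TRUE)` exposes the alternative. |

Standardization (mean 0, sample variance 1, denominator $n-1$) is applied
to every gene before anything else; constant genes are flagged and carry a
zero posterior row. The residual sum of squares is floored at
$10^{-12} n$ before taking logs, so a numerically perfect fit caps the
evidence instead of producing an infinite likelihood, without affecting
rankings among imperfect fits.

## Evaluation metrics

AUROC is computed with tied scores handled by trapezoidal averaging
(equivalently, the normalized Mann–Whitney statistic); AUPR by step-wise
summation over distinct thresholds in descending order, ties grouped at a
single threshold and no interpolation between steps — interpolated
precision–recall areas are known to be optimistic. Threshold semantics
everywhere are keep-if-strictly-greater. `best_f1_threshold()` scans every
distinct score value plus one candidate below the minimum (so "keep
everything" is attainable) and resolves ties toward the lowest threshold.
Gold standards may be partial (DREAM-style): only labeled pairs enter the
metrics. Both areas are cross-checked in the test suite against brute-force
threshold enumeration and, for AUROC, against `pROC`.

For post-inference analysis the package reports **outgoing harmonic
closeness**, $\sum_{u \ne v,\ u \text{ reachable}} 1/d(v,u)$: thresholded
regulatory networks are always disconnected, where classical closeness is
ill-defined, while the harmonic form remains meaningful and reads as a
distance-discounted count of genes a TF reaches directly or indirectly.
Non-TF nodes have no outgoing edges and score zero.

## What the synthetic generator does and does not emulate

`simulate_network()` draws a directed acyclic TF→gene topology over a fixed
topological order (TFs first), with per-TF edge propensities drawn from an
exponential distribution so a few TFs become hubs, and the expected mean
outdegree matches `avg_outdegree`. `simulate_expression()` then emulates a
multifactorial steady-state design: unregulated genes are i.i.d. standard
normal across samples, and each regulated gene is
$\sum c\,f(x_{\mathrm{reg}})$ plus $N(0, \texttt{noise\_sd}^2)$ noise, with
per-edge coefficients $\pm U(0.5, 1.5)$ and $f$ linear, $\tanh$-saturating
or quadratic. Evaluation in topological order makes steady states exact. All
randomness flows from the single spec seed (expression uses seed + 1 so
topology and expression draws are decoupled); the global RNG state of the
caller is restored afterwards.

The default spec — 50 genes, 10 TFs, mean outdegree 3, 100 samples, noise
sd 0.25, linear links — defines the package's standard recovery benchmark.
What the generator deliberately does **not** reproduce: feedback loops and
cycles (real GRNs have them; a DAG gives exact steady states without
fixed-point solving), kinetic/ODE dynamics, time series, knockout designs,
technology-specific noise (count overdispersion, log-normal microarray
noise), and unmeasured confounders. Passing the recovery tests therefore
demonstrates correctness of the inference machinery under the model's own
generative assumptions, not performance on any real dataset.

`perturb_prior()` emulates prior knowledge of varying quality: it flips the
presence/absence status of $\lfloor$`flip_fraction` $\cdot$ #pairs$\rfloor$
labeled pairs — balanced between deletions and additions where availability
allows, so `flip_fraction = 1` yields the exact complement network — and
encodes the result with weights `w_in` = 0.6 for present and `w_out` = 0.4
for absent pairs. These mild weights let the data overrule a wrong prior
while still breaking likelihood near-ties in favour of known edges.

## Numerical and design notes

* The whole core is deterministic; no randomness enters `kboost()` itself.
* The per-TF kernel matrices are transient: only KPC blocks are retained,
  so peak additional working memory is one $n \times n$ kernel.
* The greedy path is validated in the tests against a deliberately naive
  reference (explicit loops, kernels recomputed per gene and iteration,
  straight from the model equations) to $10^{-8}$ agreement on small
  instances, and the kernel PCA against explicit polynomial feature-map
  PCA via principal angles.
* Benchmark problem sizes in the test suite (ten replicates of the default
  spec; sub-second per fit) were chosen so the whole suite re-runs in
  seconds while keeping the recovery and prior-effect comparisons
  well-resolved.

## Known limitations

Edges are scored marginally per (TF, gene) pair, so densely co-regulated
genes can receive probability mass on co-regulators (indirect edges) — the
greedy search and variance scaling mitigate but do not remove this, and it
is the dominant error mode on the synthetic benchmark. Regulation strength
and sign are not reported, only probability. The binomial prior treats
edges independently; structured priors (motif co-occurrence, operons) are
out of scope. Cyclic regulation is neither simulated nor given special
treatment at inference time: the model simply scores predictive
relationships, cycles included, but evaluation against cyclic gold
standards is untested here.
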