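---
title: "Per-sample log-contrast regression with sparse network fusion: models and methods"
author: "compnetlasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-sample log-contrast regression with sparse network fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compnetlasso)
```

## The problem

Microbiome covariates are *compositional*: a sample is a vector of relative
abundances on the simplex, strictly positive and summing to one. The
standard regression model for such covariates is the log-contrast model in
its symmetric form,

$$ y_i = z_i^\top \beta + \varepsilon_i, \qquad z_{ij} = \log x_{ij},
\qquad \textstyle\sum_j \beta_j = 0, $$

where the zero-sum constraint makes the fit invariant to the closure
(rescaling) of the composition. A single coefficient vector, however,
assumes one biological regime for all hosts — while gut communities are
known to fall into recurring configurations (enterotype-like clusters) in
which the same taxon can relate differently to a phenotype.

`compnetlasso` treats every sample as its own task: each sample $i$ carries
its own zero-sum coefficient vector $w_i$, and a graph $R$ of sample
relations (built from host covariates or from the compositions themselves)
couples the tasks through a *network lasso* penalty:

$$ \min_{w_1,\dots,w_n} \sum_{i=1}^n (y_i - z_i^\top w_i)^2
 + \lambda_1 \sum_{m>l} r_{m,l} \lVert w_m - w_l \rVert_2
 + \lambda_2 \sum_{i=1}^n \lVert w_i \rVert_1,
 \qquad \mathbf{1}^\top w_i = 0 \;\; \forall i. $$

The group-lasso norm on differences induces *exact fusion*: samples
connected in the graph get identical coefficient vectors at the optimum
when $\lambda_1$ is large enough, so latent clusters of regression regimes
can be read directly off the fit. The elementwise $\ell_1$ term performs
variable (taxon) selection within each task. We call the combination a
sparse network lasso; the package also fits the unconstrained variant
(dropping the zero-sum constraint) and the single-model compositional
lasso, both used as baselines.

## Estimation

The objective is convex but nonsmooth in two places (fusion norms,
$\ell_1$), with a linear constraint. The solver is ADMM on the splitting
$w_m = a_{m,l}$ (one pair of directed copies per positive-weight edge),
$w_i = b_i$, with the zero-sum constraint enforced through a scalar
multiplier per sample:

* **w-update** — for each sample, a linear solve with the matrix
  $2 z_i z_i^\top + (\rho\,d_i + \phi) I + \psi \mathbf{1}\mathbf{1}^\top$
  ($d_i$ = graph degree). Because this is a scaled identity plus two
  rank-one terms, the solve is done in $O(p)$ by two Sherman–Morrison
  downdates; a dense solve is available behind `snlControl(exactSolve =
  TRUE)` and is used in the tests to verify the shortcut.
* **fusion update** — the proximal operator of
  $\lambda_1 r \lVert a_{m,l} - a_{l,m}\rVert_2$ pulls each connected pair
  toward its midpoint by a factor
  $\theta = \max\!\big(1 - \lambda_1 r_{m,l} / (\rho \lVert u - v
  \rVert_2),\, 0.5\big)$; the clamp at $1/2$ is exact fusion. The update
  conserves the pair sum, an invariant the tests check on random calls.
* **b-update** — elementwise soft-thresholding with $\lambda_2/\phi$.
* **dual updates** — the edge dual is kept in scaled form ($s \mathrel{+}=
  w - a$), which is what the augmented Lagrangian implies and coincides
  with the conventional unscaled update at the default $\rho = 1$; the
  sparsity and zero-sum duals are unscaled.

Edges with zero relation weight carry no auxiliary variables: their fusion
penalty is zero, so the optimum is unchanged and memory scales with the
number of actual edges.

**Convergence.** Iterations stop when the largest primal residual —
$\lVert w_m - a_{m,l}\rVert_\infty$, $\lVert w_i - b_i\rVert_\infty$, and
for constrained fits $|\mathbf{1}^\top w_i|$ *and*
$|\mathbf{1}^\top b_i|$ — falls below `tol` (default `1e-4`), or after
`maxIter` iterations. The reported coefficients are the sparse copies
$b_i$; including $|\mathbf{1}^\top b_i|$ in the stopping rule is what
guarantees the documented zero-sum tolerance on the *returned* rows
(thresholding alone could break it by up to $p \cdot \lVert w - b
\rVert_\infty$). All primal and dual variables start at zero; warm starts
across a regularization grid are supported and used by the CV driver.

The solver cores are compiled (RcppArmadillo): the simulation protocol
runs thousands of fits, and the per-iteration work is a stream of
length-$p$ vector operations per edge that would dominate in interpreted
code.

**Tuning parameters.** $\rho = \phi = \psi = \mu = \eta = 1$ by default;
the updates are kept exactly in their closed forms (no adaptive $\rho$).
$\lambda_1$ controls how aggressively related samples are fused (units:
response-squared per unit coefficient distance), $\lambda_2$ the
per-sample sparsity. Both default CV grids are log-spaced
($\lambda_1 \in 10^{-2..2}$, $\lambda_2 \in 10^{-3..1}$) and fully
configurable.

## Prediction for unseen samples: the constrained Weber problem

A new sample has no fitted $w$. Given its graph weights $r_{i^*,i}$ to the
training samples, its coefficient vector is the *weighted geometric
median* of the fitted vectors,

$$ \min_{w^*} \sum_i r_{i^*,i} \lVert w^* - \hat w_i \rVert_2, \qquad
\mathbf{1}^\top w^* = 0 \text{ (constrained model)}, $$

solved by a small ADMM on the splitting $e_i = w^* - \hat w_i$: the
$e$-update is a group soft-threshold toward zero with radius $r_i/\mu$,
the $w^*$-update solves $(\mu n I + \eta \mathbf{1}\mathbf{1}^\top)$
against the anchor-shifted average. The geometric median is robust: a
validation sample wired mostly into one fused cluster inherits that
cluster's vector even when a few edges are wrong. Degenerate cases
(a single anchor, all anchors equal) return the anchor (projected onto the
zero-sum plane if needed); anchors with zero weight are dropped. A new
sample with *no* positive weights has no information in the graph; the
predictor falls back to uniform weights and warns.

The published update listing for this subproblem appears to drop the
anchor term in the $w^*$-step and mixes sign conventions in the clipped
$e$-step; the updates here are re-derived from the optimization problem
itself and validated in the tests against an independent IRLS
(Weiszfeld-type) oracle to $10^{-4}$ relative objective.

## Model selection and evaluation

`cvSparseNetwork()` runs seeded K-fold CV (default $K = 5$): each fold is
fitted on the training subgraph and the held-out samples are predicted
through the Weber problem with their observed weights to the fold's
training samples — the same mechanism used for genuinely new samples, so
the CV error measures the full prediction path. Exact ties in mean CV
error are broken toward stronger regularization. `loocvR2()` reports the
leave-one-out $R^2$ used for real-data evaluation. Within a fold the grid
is traversed in ascending order with warm starts.

**Centering and standardization.** A constant offset cannot be represented
by zero-sum coefficients acting on log-features, so centering is the
analyst's decision, not an automatic step: all fitters take
`center` (default `TRUE`, storing the training-mean offset for
prediction). The simulation protocol below generates data with no
intercept and therefore runs the constrained model and the compositional
lasso uncentered. Rescaling log-features would destroy the log-contrast
meaning of the constraint, so `standardize` is available only for the
unconstrained variant — which is how that baseline is defined: a generic
per-sample network-lasso regression on standardized covariates with a
centered response, applied to compositional data while ignoring their
nature. Standardization here means unit-SD *scaling* of the columns; they
are deliberately not mean-centered, because the response offset already
plays the intercept's role and removing the columns' locations would
discard between-sample level information that per-sample models exploit.

## The synthetic-data generator

`simulateDataset()` reproduces the three-cluster study design and is the
package's test bed:

* $n = 120$ samples in three clusters of 40; $p$ features.
* Latent Gaussians $c_i \sim N(\omega, \Sigma)$ with $\omega_j =
  \log(0.5\,p)$ for $j \le 5$ (five dominant taxa) and 0 otherwise, and
  AR(1) covariance $\Sigma_{ij} = 0.2^{|i-j|}$; compositions by softmax
  closure $x_{ij} = e^{c_{ij}} / \sum_k e^{c_{ik}}$.
* Three fixed zero-sum coefficient vectors (eight structured leading
  entries, zero-padded); responses $y_i = z_i^\top w^{(g_i)} + \sigma
  \varepsilon_i$ with standard normal $\varepsilon_i$.
* The true relation graph is the exact block graph of the cluster labels;
  the *observed* graph flips each upper-triangle entry independently with
  probability $1 - \text{PR}$ and is then symmetrized (the corruption of
  present and absent edges is treated identically; the generating paper
  does not pin this down).
* A uniformly random 100/20 train/validation split.

All draws come from one stream seeded once, in a fixed order (latent
Gaussians, unit noise, corruption uniforms, split), so changing $\sigma$
alone rescales the same noise realization and changing PR alone re-flips
the same graph — convenient for ablations. Each study repetition $r$ uses
seed `baseSeed + r`, including a fresh corruption draw (consistent with
reporting repetition SDs).

What the generator does *not* emulate about real microbiome data:
sequencing-depth variation and zero inflation (compositions are strictly
positive by construction), taxon correlations beyond AR(1), covariate-
driven graph noise (corruption is i.i.d.), or any phylogenetic signal.
Passing the simulation checks therefore demonstrates correctness of the
estimator and protocol, not robustness to those real-data features.

## The simulation study

`runSimulationStudy()` executes the full protocol per repetition —
simulate, 5-fold CV on the 100 training samples with the observed-graph
subgraph, final fit, Weber prediction of the 20 validation samples, MSE —
for the proposed model, the unconstrained variant, and the compositional
lasso. Design choices for the study driver:

* CV fits use a compact grid ($\lambda_1 \in \{0.1, 1, 10, 100\}$,
  $\lambda_2 \in \{0.01, 0.1, 1\}$) and are capped at 250 ADMM iterations —
  an inexact fit at an extreme grid point can only affect the CV *ranking*,
  and the final fit at the selected point runs to 3000 iterations. Both
  choices keep a full multi-cell study tractable on a single CPU. The
  acceptance checks use 10–30 repetitions per cell.
* Repetitions that fail to converge are flagged in the output
  (`nonconverged` column), never dropped.

## Numerical choices and edge cases

* Zero counts are replaced by one count before closure (configurable);
  aggregation on a phylogeny happens on raw counts *before* zero
  replacement, since pseudo-counts would inflate merged sums. Whether
  replacement should precede aggregation is genuinely open; the choice is
  surfaced in the documentation.
* Feature agglomeration cuts single-linkage clusters on cophenetic
  distances strictly below the threshold ("merge while smaller than"),
  merged features keep the lexicographically smallest member id, and the
  operation conserves total count mass and is idempotent.
* Natural logarithms throughout (the log base only rescales coefficients,
  but consistency matters between the generator's $\log(0.5p)$ location
  and `logFeatures()`).
* k-NN graphs break distance ties toward the smaller sample index;
  entries of $(S + S^\top)/2$ are 0, 0.5 or 1.
* Fused clusters are read off the coefficient matrix as connected
  components under an $\lVert\cdot\rVert_\infty$ tolerance (default
  `1e-4`, the solver tolerance); hierarchical display grouping uses Ward
  linkage on Euclidean distances (configurable) — both are reporting
  conveniences, not inference.
* Thresholding small $|w_{ij}|$ (default cutoff 0.05) simplifies
  interpretation but can break exact zero sums; the report flags this
  instead of silently re-projecting.

## Known limitations

* Fusion quality depends entirely on the supplied graph; with heavy
  corruption (PR $\le 0.8$) the fused model can do worse than the
  unconstrained variant, mirroring the degradation the protocol measures.
* ADMM convergence at extreme penalties is slow (linear rate); the
  iteration caps trade exactness at grid edges for runtime, which matters
  only for the CV ranking, not the final fit.
* The Weber predictor assigns one vector per new sample; it cannot
  extrapolate to samples unlike any training cluster.

## A worked run

```{r example, eval = FALSE}
sim <- simulateDataset(p = 30, sigma = 0.1, pr = 0.99, seed = 1)
tr <- sim@trainIdx; va <- sim@validationIdx
r <- relationMatrix(sim@observedGraph)

cv <- cvSparseNetwork(sim@z[tr, ], sim@y[tr], r[tr, tr],
                      lambda1Grid = c(0.1, 1, 10), lambda2Grid = c(0.01, 0.1),
                      seed = 1, center = FALSE)
sel <- selectedLambda(cv)
fit <- fitSparseNetwork(sim@z[tr, ], sim@y[tr], r[tr, tr],
                        sel$lambda1, sel$lambda2, center = FALSE)
extractFusedClusters(coef(fit))          # three latent clusters
mse(sim@y[va], predictResponse(fit, sim@z[va, ], r[va, tr]))
```
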