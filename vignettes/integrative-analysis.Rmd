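---
title: "Horizontal and vertical integrative analysis of disease omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Horizontal and vertical integrative analysis of disease omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omifuse)
```

## Scope and data model

omifuse analyses paired case-control omics data for two related diseases
(the motivating setting is bipolar disorder and schizophrenia against one
shared pool of normal controls). For each sample we observe a
p-dimensional gene-expression vector $x_i^{(k)}$, a p-dimensional CNV
(copy-number) vector $z_i^{(k)}$, and a binary outcome $y_i^{(k)}$
(1 = case); $k$ indexes the disease. Samples live in an `omics_dataset`;
`assemble_contrasts()` builds the two disease-versus-control datasets from
jointly measured matrices, sharing the control pool between contrasts
(an option splits it disjointly). Missing values are not imputed: any
non-finite entry is an error, because none of the downstream models has a
missing-data mechanism. Pathway prescreening is supported through GMT
gene sets and `subset_to_gene_set()`.

Three analyses are provided: a *vertical* integration of expression and
CNV into one outcome model per disease, and two *horizontal* (cross-
disease) penalized estimations -- marker identification and
expression-CNV regulation discovery -- that borrow information between
the diseases through contrast ("fusion") penalties.

## Vertical integration (A1)

For one disease, the pipeline is

1. sparse PCA of expression; the top $K$ sparse components
   $x_{pc,i}$ summarize expression;
2. a *reversed* least-squares regression $z_i = x_{pc,i}\,\omega +
   \varepsilon_i$ of each CNV on the expression scores, whose fitted part
   is the CNV information overlapping with expression;
3. sparse PCA of the residual $z_i - \hat z_i$, giving CNV components
   $z_{pc,i}$ that carry only information independent of expression;
4. an unpenalized logistic model
   $P(y_i = 1) = \text{logit}^{-1}(x_{pc,i}\theta_x + z_{pc,i}\theta_z +
   \alpha)$.

Comparators: A2 runs sparse PCA on both blocks without the decomposition
(so collinear information enters twice); A3 and A4 use only expression or
only CNV. Forcing $\omega = 0$ in A1 reproduces A2 exactly, which is also
a package test.

Sparse PCA is implemented as a penalized matrix decomposition: rank-one
steps maximize $u^TAv$ subject to $\|u\|_2 \le 1$, $\|v\|_2\le 1$,
$\|v\|_1 \le c$, alternating a power-iteration update of $u$ with a
soft-threshold-and-rescale update of $v$ (threshold found by bisection,
smaller thresholds preferred on ties), followed by rank-one deflation.
Columns are mean-centered, not variance-scaled, before decomposition
(scaling is a flag); loadings are sign-normalized so the
largest-magnitude entry is positive. Convergence is declared when the
objective changes by less than `1e-7`, with a 200-alternation cap.

Defaults and their reasons:

* `n_components = 10` per block, truncated to `min(10, n - 1, p)`. The
  aim of the pipeline is an outcome model, not component selection, so a
  fixed, generous number is used.
* sparsity bound `c = sqrt(p)/2`: halfway between the fully dense bound
  `sqrt(p)` and the 1-sparse bound 1 on the natural scale of the
  constraint; `tune_sparsity_bound()` instead targets a nonzero count.
* the reversed regression is plain least squares, with a ridge of `1e-6`
  added only on rank deficiency (then with a warning).
* the logistic step is iteratively reweighted least squares (tolerance
  `1e-8`, 100 iterations); on separation or non-convergence it refits
  with a small ridge (`1e-4`) and warns. With 20 scores and a few dozen
  samples separation is common, and the ridge keeps the fit finite
  without meaningfully changing predictions.
* prediction for new samples reuses the training centering, loadings and
  $\hat\omega$ with no refitting -- required for honest resampled
  evaluation.

## Horizontal marker identification (B1/B2)

Per disease, a logistic model $P(y_i^{(k)} = 1) =
\text{logit}^{-1}(x_i^{(k)}\beta^{(k)} + \alpha^{(k)})$; jointly, the
objective

$$-l(\beta^{(1)}) - l(\beta^{(2)})
  + \lambda_1 \sum_{k,j} |\beta_j^{(k)}|
  + \frac{\lambda_2}{2}\,\rho(\beta^{(1)}, \beta^{(2)}),$$

with two fusion choices. The *magnitude* penalty
$\rho_M = \sum_j \sum_{k \ne k'} (\beta_j^{(k)} - s_j^{(kk')}
\beta_j^{(k')})^2$, where $s_j^{(kk')}$ indicates equal signs
($\mathrm{Sgn}(0) = 0$), shrinks value differences of same-sign effects
(quantitative similarity, B1). The *sign* penalty
$\rho_S = \sum_j \sum_{k \ne k'} (\mathrm{Sgn}(\beta_j^{(k)}) -
\mathrm{Sgn}(\beta_j^{(k')}))^2$ shrinks sign disagreements (qualitative
similarity, B2). With $\lambda_2 = 0$ both collapse to two independent
lasso fits (B3 is that baseline, fit per disease).

By default each log-likelihood is scaled by $1/n_k$ so penalty levels are
comparable across sample sizes; `normalize_likelihood = FALSE` restores
the literal unnormalized sum. Predictors are standardized inside the
solver and coefficients returned on the standardized scale with the
scaling attached (`coef(fit, scale = "original")` back-transforms).

### Solver

Coordinate descent with three design points worth spelling out:

* **Loss majorization.** Each sweep majorizes the logistic losses by the
  global quadratic bound with curvature 1/4 (the maximum of
  $p(1-p)$). Unlike IRLS weights, this is a true majorizer, so every
  sweep provably decreases the exact objective; the per-sweep objective
  trace is recorded and non-increasing, which the tests assert to
  `1e-10`.
* **Pairwise updates.** For every gene the coefficient *pair*
  $(\beta_j^{(1)}, \beta_j^{(2)})$ is updated jointly -- the loss is
  separable across diseases, so exact joint minimization is available by
  enumerating the sign-region branches (at most a 2-by-2 linear solve
  per branch). One-at-a-time updates cannot move a fused pair off zero
  together (whichever coordinate moves first pays the whole penalty), a
  deadlock that pairwise updates remove.
* **Sign smoothing.** The sign penalty is discontinuous; the solver
  optimizes the smooth surrogate $\mathrm{Sgn}(x) \approx
  x/\sqrt{x^2 + \tau}$ with $\tau = 10^{-2}$ on standardized predictors.
  Each sweep freezes the denominators at the sweep-start iterate (the
  penalty becomes quadratic and the pair update closed-form) and accepts
  a pair update only if it decreases the exact surrogate objective, so
  the recorded trace stays monotone even though the frozen-denominator
  step alone is not a true majorizer. Reported penalty *values*
  (`sign_penalty()`) use exact signs. The surrogate also matters
  statistically: near zero it acts as a strong quadratic fusion, letting
  weakly-supported markers enter alongside their partner instead of
  paying the full sign cost at once.

Convergence: maximum coefficient change below `1e-5` (default), 1000
sweeps cap with a warning. `lambda_max_markers()` gives the smallest
$\lambda_1$ with an all-zero solution (intercepts at the logit class
frequencies); it carries a $1+10^{-10}$ safety factor so floating-point
ties at the threshold still give an exactly zero fit.

### Tuning

The selection problem is two-dimensional and the two axes play different
roles, which the default *profiled* search respects: for every fusion
level $\lambda_2$, the lasso level is chosen along a warm-started path by
extended BIC ($-2(l_1+l_2) + \log(n_1+n_2)\,\mathrm{df} +
2\gamma\sum_k \log\binom{p}{\mathrm{df}_k}$, $\gamma = 0.5$, df = nonzero
count; $\gamma = 0$ recovers plain BIC) -- the extended term is the
standard correction for $p > n$ model search and keeps false selections
near zero. The fusion level is then chosen among the profiled candidates
by BIC with *fusion-aware effective degrees of freedom*: an actively
fused pair contributes $\mathrm{tr}\{(H + P)^{-1}H\}$ (between 1 and 2),
with $H$ the loss curvatures and $P$ the fusion Hessian, so the
comparison across fusion levels does not double-count parameters the
penalty ties together. Plain nonzero-count BIC never selects
$\lambda_2 > 0$, because fusion costs in-sample likelihood without any
df credit. Five-fold stratified cross-validated deviance (with the
one-standard-error rule) is available as `criterion = "cv"`. A joint
grid search is available as `search = "joint"`.

## Horizontal regulation discovery (C1/C2)

Expression of gene $j$ is regressed on *all* CNVs,
$x_{ij}^{(k)} = z_i^{(k)}\eta_j^{(k)} + \delta_{ij}^{(k)}$, jointly for
the two diseases:

$$\sum_k \frac{1}{2n^{(k)}}\sum_{j,i}
  (x_{ij}^{(k)} - z_i^{(k)}\eta_j^{(k)})^2
  + \lambda_3 \sum_{k,j,l} |\eta_{jl}^{(k)}|
  + \lambda_4 \sum_j \rho(\eta_j^{(1)}, \eta_j^{(2)}),$$

with the same two fusion penalties. The problem decouples over genes;
each gene is a fused pair of linear regressions solved by the same
coordinate core with exact quadratic loss (no majorization needed).
Cis (diagonal) entries are penalized like any other, as both cis- and
trans-acting regulation are of interest. A single global
$(\lambda_3, \lambda_4)$ is shared across genes, matching the single
pair of tuning parameters in the objective; per-gene selection of
$\lambda_3$ is available (`per_gene = TRUE`) and is used for the
separate-lasso baseline C3 and the normal group, where the per-gene
problems are fully independent. Responses are centered and CNV columns
standardized per dataset; a zero-variance CNV column is pinned at zero
with a warning.

Estimated coefficient matrices are compared across groups with
$\mathrm{Dist} = \sum_{j,l}(\eta^A_{jl} - \eta^B_{jl})^2$ (magnitude and
sign) and $\mathrm{SignDist} = \sum_{j,l}(\mathrm{Sgn}\,\eta^A_{jl} -
\mathrm{Sgn}\,\eta^B_{jl})^2$ (direction only), summed over genes --
summation rather than per-gene averaging is assumed; rescaling by $p$ is
trivial if preferred.

## Synthetic-data generators

`simulate_marker_scenario()` implements the four-scenario case-control
design: expression for disease-$k$ cases from $N(\mu_k, \Sigma)$,
controls from $N(0, \Sigma)$, all groups of size 40 and $p = 100$ by
default; $\Sigma$ is block-diagonal over the 8 important and 92
unimportant variables, each block AR(1) with correlation $0.3^{|j-k|}$;
$\mu_1 = (-1,-1,-1,-1,2,2,2,2,0,\dots)$ throughout, and $\mu_2$ equal to
$\mu_1$ (scenario I), same signs with different magnitudes (II, III), or
partially conflicting signs (IV). One control draw is shared by the two
disease datasets per replicate, mirroring a single normal group.

`simulate_regulation_data()` builds sparse regulation matrices: each gene
is regulated by 10% of the CNVs, coefficients half from
$U(0.6, 1.2)$ and half from $U(-1.2,-0.6)$, with 6 regulators per gene
shared across the two diseases with matching signs (supports re-drawn
per gene; disease-specific regulators are drawn disjointly so the
designated sharing is exact); errors are $N(0,1)$. Two constraints are
worth noting. First, the construction is infeasible when
$0.1\,p < 6$; the scaled-down study sizes used in the tests
($p = 40, 30$) therefore scale the shared count to half the support
size (minimum 2, maximum 6), preserving the sharing *ratio* of the
full-scale design ($p \approx 130$: 6 of 13). Second, real CNV
measurements are replaced by `simulate_cnv_matrix()`, a multivariate-
normal AR(0.3) surrogate with optional tertile discretization to
$\{-1,0,1\}$ -- a stand-in, clearly not a model of array-derived copy
number, so passing tests demonstrate solver behaviour, not platform
realism.

`simulate_vertical_data()` is the test harness for the vertical
pipeline: two sparse expression factors, CNV carrying a scaled copy of
them (the overlap) plus two independent CNV factors, and an outcome
driven by one expression factor and one independent CNV factor
(coefficients 1.5 each, n = 120, p = 40, residual sd 0.5 by default --
moderate signal so that integration is advantageous but prediction stays
imperfect). With `independent_cnv_effect = 0` the CNV block is redundant
and A1 collapses toward A3; with `overlap_strength = 0` the reversed
regression has nothing to remove.

## Evaluation

`selection_metrics()` gives TPR and FPR against a known support.
`cpr()` is the corrected prediction ratio: its exact formula here is
balanced accuracy, $(\text{sensitivity} + \text{specificity})/2$ at a
0.5 threshold, with ties deterministically predicted as class 0 --
"corrected" in the sense of being 0.5 for any uninformative rule under
class imbalance; raw accuracy is a flag. `evaluate_cpr_resampling()`
repeats stratified 75/25 train/test splits (200 by default), refitting
the entire pipeline (including sparse PCA and the reversed regression)
on each training set.

## Simulation-study protocol

The replicate drivers (`marker_simulation_study()`,
`regulation_simulation_study()`, `regulation_distance_study()`) compare
the fused methods with their separate-lasso baselines **at matched model
size**: the baseline tuned by extended BIC sets the support size, and
the fused fit is taken from a fine regularization path (at each strictly
positive fusion level, with the level itself chosen by effective-df BIC)
at the size closest to it. Two reasons. First, the comparison then
isolates what the fusion penalty is supposed to deliver -- a better
*ranking* of candidate markers by borrowing strength -- rather than a
different sparsity calibration. Second, at the sparsity levels an
information criterion selects in these designs, false-positive rates sit
near zero, and criterion-based FPR comparisons between methods are
dominated by sub-one-feature noise; at matched size the TPR and FPR
orderings are two views of the same ranking comparison. The study
problem sizes (30 replicates at the full marker design; 20 replicates at
$p = 40$ genes for regulations; 25 replicates at $p = 30$ for the
distance contrasts; 100 resampling splits for the vertical comparison)
were chosen as the smallest giving stable orderings across seeds.

## Known limitations

* The generators draw from exact multivariate normals with homogeneous
  noise; real expression/CNV data have heavy tails, batch structure and
  platform artifacts that none of the tests exercise.
* The sign-penalty solution depends mildly on the smoothing constant
  $\tau$; results are reported for $\tau = 10^{-2}$ on standardized
  predictors.
* Fused problems are nonconvex (the fusion indicator $s$ and the sign
  surrogate both depend on the iterate); the solver guarantees monotone
  descent and the tests verify agreement with orthant-restricted
  numerical optimization at the converged sign pattern, but global
  optimality is not guaranteed.
* No inference (p-values, intervals) is attached to selections;
  penalized high-dimensional inference is out of scope.
* At most two diseases are fused; the penalties extend to more, but the
  pairwise-update solver is written for the two-dataset case.
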