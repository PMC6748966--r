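# omifuse

Integrative analysis of paired case-control omics data for two related
diseases — built for settings like bipolar disorder and schizophrenia
profiled with gene expression and copy-number variation (CNV) against a
shared pool of normal controls. Sample sizes in such studies are small
and the feature space large, so each analysis borrows strength: across
omics types (vertical integration) or across diseases (horizontal
integration).

Three analyses, all operating on `omics_dataset` objects (samples ×
genes expression matrix `X`, aligned CNV matrix `Z`, binary outcome
`y`):

1. **Vertical integration** (`fit_vertical()`). Sparse PCA reduces
   expression to ten sparse components $x_{pc}$; a *reversed* regression
   $z = x_{pc}\,\omega + \varepsilon$ strips from CNV the information
   overlapping with expression; sparse PCA of the residual yields CNV
   components $z_{pc}$ carrying independent information; a logistic
   model $P(y=1) = \mathrm{logit}^{-1}(x_{pc}\theta_x + z_{pc}\theta_z +
   \alpha)$ combines both. Comparator variants: stacked sparse PCs of
   both blocks (A2), expression only (A3), CNV only (A4).

2. **Cross-disease marker identification**
   (`solve_penalized_logistic()`, `select_tuning_markers()`). Two
   logistic regressions minimized jointly under
   $-l(\beta^{(1)}) - l(\beta^{(2)}) + \lambda_1\sum_{k,j}
   |\beta_j^{(k)}| + \tfrac{\lambda_2}{2}\rho(\beta^{(1)},\beta^{(2)})$,
   where $\rho$ is either the magnitude-based contrast penalty
   $\sum_j\sum_{k\ne k'}(\beta_j^{(k)} - s_j^{(kk')}\beta_j^{(k')})^2$
   (shrinks value differences of same-sign effects) or the sign-based
   penalty $\sum_j\sum_{k\ne k'}(\mathrm{Sgn}\,\beta_j^{(k)} -
   \mathrm{Sgn}\,\beta_j^{(k')})^2$ (shrinks sign disagreements).
   Solved by coordinate descent with exact pairwise updates and a
   provably monotone objective.

3. **Cross-disease regulation discovery**
   (`solve_penalized_regulation()`). Per-gene sparse regressions of
   expression on all CNVs, fused across diseases with the same two
   penalties; estimated regulation matrices are compared between groups
   with `dist_matrices()` / `signdist_matrices()`.

Synthetic-data generators (`simulate_marker_scenario()`,
`simulate_regulation_data()`, `simulate_vertical_data()`) reproduce the
corresponding study designs, and `selection_metrics()` /
`evaluate_cpr_resampling()` provide TPR/FPR and resampled
balanced-accuracy (corrected prediction ratio) evaluation.

## Worked example

```r
library(omifuse)

# two diseases, 40 cases each + 40 shared controls, p = 100, the first
# eight variables associated with both outcomes (scenario I: identical
# effects)
sim <- simulate_marker_scenario(marker_scenario_spec("I"), seed = 1)

fit <- select_tuning_markers(sim$d1, sim$d2, penalty = "magnitude")
fit
#> marker_fit ( magnitude penalty, expression ): 2 dataset(s)
#>   lambda1 = 0.06798  lambda2 = 1
#>   dataset 1 ( bipolar ):  5 nonzero of 100
#>   dataset 2 ( schizophrenia ):  6 nonzero of 100

selection_metrics(support(fit)[[1]], sim$truth, p = 100)
#> TPR = 0.625, FPR = 0.000 (5 selected, 8 true)
```

The fused fit selects 5 and 6 markers for the two diseases at the
tuning chosen by the profiled (extended-)BIC search; for the first
disease all five selections are true markers (5 of the 8 simulated
signals, no false positives).

```r
vd <- simulate_vertical_data(seed = 1)
vfit <- fit_vertical(vd$dataset, "A1")
vfit
#> vertical_fit ( A1 ): n = 120
#>   components: 10 expression 10 CNV
#>   log-likelihood: -35.0957

evaluate_cpr_resampling(vd$dataset,
                        function(tr) fit_vertical(tr, "A1"),
                        n_splits = 50, seed = 2)
#> CPR over 50 splits: 0.77 (0.06)
```

The vertical model combines ten expression components with ten
residual-CNV components; over 50 stratified 75/25 train/test splits its
corrected prediction ratio (balanced accuracy) averages 0.77
(sd 0.06) on held-out samples.

## Command-line interface

A thin wrapper over the same functions is installed at
`system.file("cli", "omifuse.R", package = "omifuse")`:

```sh
Rscript omifuse.R simulate --design marker-I --out sim/ --seed 1
Rscript omifuse.R vertical --expr expr.tsv --cnv cnv.tsv \
    --labels labels.tsv --out results/ --seed 1
Rscript omifuse.R markers  --expr expr.tsv --cnv cnv.tsv \
    --labels labels.tsv --penalty sign --out results/ --seed 1
```

Inputs are TSV matrices (features in rows by default), a label file with
columns `sample_id` and `group`, and optionally a GMT gene-set file for
pathway prescreening; outputs are TSV tables plus a JSON run summary.

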