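# drfs — dual-regularized feature selection

`drfs` is an R package for supervised, embedded feature selection on
sample-by-feature expression matrices (bulk or single-cell transcriptomics,
or any tabular data with class labels). It targets the situation where
feature associations differ *between classes*: two genes may co-vary only
in one disease subtype, while a pair of globally near-identical probes is
redundant everywhere. Filter scores computed per feature miss the first
structure; global-manifold regularizers miss it too.

## The model

Given `X` (n samples × d features), one-hot labels `Y` (n × r) and a
non-negative feature-weight matrix `W` (d × r), the package minimizes

```
min_{W ≥ 0}  ||XW − Y||_F² + α ||W||_{2,1}
             + β ( (1/r) Σ_l w_lᵀ L^(l) w_l  +  (1/(r(r−1))) Σ_{p≠q} w_pᵀ M w_q )
```

* `L^(l)` is the graph Laplacian of a k-NN RBF **feature**-similarity graph
  built from class l's samples only (`M_ij = exp(−||x^i − x^j||²/σ_l²)` for
  neighbouring features, σ_l² = mean pairwise squared feature distance in
  class l, k = 10). The quadratic form keeps weights smooth over each
  class's feature manifold.
* `M` is the same construction over **all** samples; the cross-column
  bilinear term penalizes spending weight, in different class columns, on
  globally similar (redundant) features.
* `α ||W||_{2,1}` (sum of row norms) drops whole features; `W ≥ 0` keeps
  the weights interpretable as importances.

The problem is solved with an augmented Lagrangian: a slack copy `Z = W`
carries the graph terms, `W` is updated by an NMF-style multiplicative rule
derived from the KKT conditions (with iteratively reweighted ℓ2,1), `Z` by
per-class SPD solves plus projection onto the non-negative orthant, then
multiplier and penalty updates (μ₀ = 1, ρ = 1.1, μ_max = 1e8). The
importance of feature i is the row sum `Σ_p W_ip`; features are ranked by
descending importance.

## Worked example

The built-in generator plants 10 informative features (two class-assigned
correlated blocks of 5, mean shift 1.5), 5 near-duplicates and 85 noise
features over 3 × 50 samples:

```r
library(drfs)
ref <- reference_instance()
fit <- drfs_fit(ref$data, drfs_control(alpha = 1, beta = 1))
print(fit)
#> drfs_fit: d=100, r=3, 86 iterations (converged)
#> objective 82.1787, primal residual 1.35e-07
#> top features: inf08 inf09 inf06 inf07 inf05

accuracy_curve(ref$data, fit$ranking, grid = c(10, 50, 100))
#>   n_features classifier  accuracy
#> 1         10        svm 0.9400000
#> 2         50        svm 0.9666667
#> 3        100        svm 0.9466667
#> 4         10        1nn 0.8866667
#> 5         50        1nn 0.8933333
#> 6        100        1nn 0.8466667

recovery_auroc(fit$scores, ref$ground_truth)
#> [1] 0.9207843
```

The five top-ranked features are planted informative ones; selecting the
top 10 gives a 5-fold cross-validated linear-SVM (C = 1) accuracy of 0.94,
and the importance scores detect the planted informative + redundant set
with AUROC 0.92.

The same pipeline is scriptable (the CLI lives in `inst/cli/drfs` after
install):

```sh
drfs simulate --preset reference --out run/sim
drfs fit  --input run/sim/dataset.csv --out run/fit --alpha 1 --beta 1
drfs eval --input run/sim/dataset.csv --ranking run/fit/ranking.tsv --out run/eval
drfs check-identities        # graph-factorization and expansion self-tests
```

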