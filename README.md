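# fknnimpute

Fuzzy nearest-neighbor imputation of missing values in numeric tabular
data, with conventional baselines and a classification-accuracy benchmark
harness.

## The problem and the method

Classification datasets routinely arrive with missing cells, and most
classifiers cannot use incomplete rows. Deleting them loses information;
filling every hole in a column with one fixed value (the mean or median)
ignores which observations the incomplete row actually resembles.

`fknnimpute` fills each missing cell from its local neighborhood. For a
missing cell in row *r*, column *j*:

1. find the *k* complete-case rows nearest to *r* by Euclidean distance
   over the feature columns observed in *r* (excluding *j*);
2. fit a fuzzy membership function to the neighbors' column-*j* values
   *X* = {x₁, …, x_k} — either **triangular**, with
   (a, b, c) = (min X, mean X, max X) and

   μ(x) = 0 for x ≤ a; (x−a)/(b−a) for a < x ≤ b; (c−x)/(c−b) for
   b < x < c; 0 for x ≥ c,

   or **Gaussian**, μ(x) = exp(−(x−μ)²/2σ²) with μ = mean X and σ the
   population standard deviation of X;
3. impute the weighted average Σ xᵢ μ(xᵢ) / Σ μ(xᵢ).

Every cell is computed against the original matrix, so imputation is
order-independent and never chains its own output. Baselines (column
mean, column median, listwise deletion), MCAR injection, a synthetic
two-class data generator and a four-classifier accuracy benchmark
(nearest-neighbor, Gaussian naive Bayes, decision tree, multi-layer
perceptron — each delegated to the standard R library) complete the
toolkit. See the methods vignette
(`vignettes/fuzzy-knn-imputation.Rmd`) for the full design notes.

## Worked example

`demo_grid()` is a five-row, six-column grid with one missing cell at
(row 3, column A), small enough to verify by hand:

```r
library(fknnimpute)
g <- demo_grid()

ns <- select_neighbors(g, 3, 1, imputer_config(k = 3))
ns$values
#> [1] 2 1 7
round(ns$distances, 4)
#> [1]  23.0324 100.7256 102.6353
```

The three nearest complete rows carry column-A values {2, 1, 7}. The
triangular fit gives (a, b, c) = (1, 10/3, 7), so μ(2) = 0.4286 while the
minimum and maximum get weight 0 — the weighted average is exactly the
value 2. The Gaussian fit (μ = 10/3, σ ≈ 2.6247) weights all three
neighbors (0.8789, 0.6736, 0.3769) and blends them:

```r
impute_cell(g, 3, 1, imputer_config(3, "triangular"))
#> [1] 2
impute_cell(g, 3, 1, imputer_config(3, "gaussian"))
#> [1] 2.627587
```

On synthetic class-structured data the neighborhood information pays off
in restoration error — blank 5% of cells, impute, compare to the truth:

```r
fm  <- generate_synthetic(synthetic_spec(seed = 42))   # 500 x 10, binary label
inj <- inject_mcar(fm, 0.05, seed = 42)
imp <- impute_matrix(inj$matrix, imputer_config(3, "triangular"))
restore_truth_error(fm, imp, inj$mask)                 # fuzzy-KNN
#> [1] 1.148698
restore_truth_error(fm, mean_impute(inj$matrix), inj$mask)
#> [1] 1.437381
```

The benchmark harness sweeps imputers × k ∈ {3, 5, 7, 9} × classifiers
and scores held-out accuracy after a stratified 80/20 split and min–max
normalization:

```r
res <- run_benchmark(inj$matrix, seed = 42, dataset_id = "synthetic")
head(summarize_benchmark(res), 3)
#>    imputer  k classifier mean_accuracy n_datasets
#> 1 listwise NA        knn           100          1
#> 2     mean NA        knn           100          1
#> 3   median NA        knn           100          1
```

(On this widely separated synthetic dataset most handlers saturate; the
grid is the point — `res` holds one row per (imputer, k, classifier) cell
with its accuracy and status.)

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fknnimpute.R",package="fknnimpute"))')" \
  impute --input data.csv --output completed.csv --method triangular --k 3
```

Subcommands: `impute`, `inject`, `benchmark`, `synth`; flags include
`--method {triangular,gaussian,mean,median,listwise}`, `--k`,
`--label-column`, `--missing-marker`, `--proportion`, `--seed` and a YAML
`--config` file. Every run logs its version, configuration and any
degenerate-case fallback.

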