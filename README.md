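# aesim

Monte Carlo tools for asking a practical psychometric question: when a
questionnaire's responses are non-normal and the sample is small, how well do
autoencoders and principal component analysis (PCA) recover the latent
construct structure of the instrument?

`aesim` is aimed at behavioral and health-science methodologists who validate
multi-item scales. It provides the three ingredients of that kind of
simulation study as reusable pieces:

1. **A generator of correlated multivariate non-normal data.** Each item is a
   Fleishman cubic transform of a standard normal variable,
   `Y = a + bZ + cZ² + dZ³`, solved so that `Y` has unit variance and
   prescribed skewness γ₁ and excess kurtosis γ₂. Target item correlations
   `r` are converted to pre-transform ("intermediate") correlations ρ by the
   Vale–Maurelli relation

   ```
   r = ρ(b₁b₂ + 3b₁d₂ + 3d₁b₂ + 9d₁d₂) + ρ²(2c₁c₂) + ρ³(6d₁d₂)
   ```

   and the assembled intermediate matrix is imposed on independent normals
   through its principal-component factor pattern `F = V√Λ` (Kaiser–Dickman
   decomposition). Three 15-item, three-block population correlation
   structures are built in (`high`, `wide`, `low` communality), together with
   three moment scenarios: (γ₁, γ₂) = (0, 0), (1, 3), (2, 20).

2. **Five dimension reducers under one contract.** `reducer()` fits PCA or
   one of four autoencoder variants — simple (linear, SGD), tied-weight
   (decoder = encoder transpose), deep (11–6–6–k–6–6–11 with tanh hidden
   layers), and independence-penalized (off-diagonal latent covariance and
   encoder/decoder orthogonality penalties) — all exposing
   `encode()`/`reconstruct()` with a k-unit bottleneck, plus the usual
   `print`/`summary`/`coef`/`predict`/`fitted`/`residuals`/`plot` methods.
   Reconstruction quality is scored by MSE, MAE and a sign-based normalized
   Euclidean distance (`mse()`, `mae()`, `ned()`).

3. **A factorial experiment driver.** `grid_spec()` + `run_grid()` cross
   communality × non-normality × sample size (the built-in ladder runs
   100–190 by 10 and 200–1000 by 50; 243 conditions), with an 80/20
   train/test split, z-scoring by training statistics, and seed-derived
   reproducibility; `summarize_results()` aggregates mean/SD per algorithm by
   any design factor. `assign_items()` classifies each item into the
   construct with its largest absolute bottleneck weight.

## Worked example

Generate strongly non-normal data (skewness 2, excess kurtosis 20) from the
high-communality population, fit PCA and a tied autoencoder on a training
split, and compare test reconstruction errors:

```r
library(aesim)

x <- generate_dataset(structure = "high", scenario = "s3", n = 400, seed = 42)
train <- x[1:320, ]; test <- x[321:400, ]
sc <- standardize_fit(train)
train_z <- standardize_apply(sc, train)
test_z  <- standardize_apply(sc, test)

pca  <- reducer(train_z, "pca", k = 3)
tied <- reducer(train_z, "tied_ae", k = 3, seed = 42)
summary(pca)
#> pca reducer with 3 latent dimensions (15 items, n = 320)
#>   training reconstruction: MSE 0.2120, MAE 0.2904, NED 2.5171
#>   variance explained by 3 components: 78.7%
tied
#> tied_ae reducer: 15 -> 3 -> 15
#>   trained on 320 observations; 284 epochs (adam, lr 0.001), final training loss 0.21205

unlist(reconstruction_metrics(test_z, reconstruct(pca, test_z)))
#>       mse       mae       ned
#> 0.2035109 0.2771129 2.6452816
unlist(reconstruction_metrics(test_z, reconstruct(tied, test_z)))
#>      mse      mae      ned
#> 0.203460 0.277063 2.639946
```

The two test MSEs agree to four decimals: a converged *linear* autoencoder
with a rank-3 bottleneck cannot beat the top-3 principal subspace
(Eckart–Young), and on this population the floor is the residual eigenvalue
mass 12 × 0.3 / 15 = 0.24 of the high-communality matrix (here slightly lower
in-sample because the split is finite).

Item-to-construct assignment picks, for every item, the latent unit with the
largest absolute weight; on this dataset the first block is recovered
cleanly:

```r
head(assign_items(tied), 6)
#>     item construct    weight1   weight2    weight3
#> 1 item01         1 0.41962775 0.1225210 0.06397785
#> 2 item02         1 0.42144155 0.1156963 0.06373101
#> 3 item03         1 0.42484805 0.1304005 0.05231218
#> 4 item04         1 0.41916256 0.1020330 0.08794320
#> 5 item05         1 0.43595384 0.1401727 0.07048474
#> 6 item06         2 0.05501568 0.3817934 0.25525964
```

A scaled-down grid run and its per-sample-size summary:

```r
gs <- grid_spec(structures = "high", scenarios = "s1",
                sample_sizes = c(100, 200), replicates = 2,
                variants = c("pca", "tied_ae"), master_seed = 1)
summarize_results(run_grid(gs), by = "sample_size")
#>   level algorithm mse_mean mae_mean ned_mean  mse_sd  mae_sd ned_sd
#> 1   100       pca    0.262    0.414     3.04 0.02477 0.01102  0.349
#> 2   100   tied_ae    0.262    0.414     3.04 0.02490 0.01105  0.349
#> 3   200       pca    0.249    0.402     2.93 0.00930 0.00384  0.216
#> 4   200   tied_ae    0.249    0.402     2.93 0.00935 0.00387  0.216
```

## Command line

A thin launcher wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "aesim.R", package = "aesim"))') \
    generate --structure high --scenario s2 --n 500 --seed 7 --out data.csv
# subcommands: generate | run-grid | summarize | assign
```

`run-grid` takes a YAML configuration; the shipped default at
`inst/extdata/study-grid.yaml` reproduces the full 243-condition study.

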