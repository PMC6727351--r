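# decomix

Reference-free cell-type deconvolution for bulk gene expression and DNA
methylation data, with iterative cross-cell-type marker selection.

Bulk samples from complex tissues are mixtures of cell types.  Estimating the
mixing proportions matters both as a biological readout and as a confounder
adjustment, but purified reference profiles are often unavailable — so
reference-free (RF) methods factorize the data matrix directly.  RF accuracy
hinges on which features enter the factorization: the conventional choice,
the most variable features, is contaminated by features whose variance is
within-cell-type noise rather than cross-cell-type signal.  `decomix`
addresses this for researchers running deconvolution on microarray/RNA-seq
expression or methylation beta matrices without a reference panel.

## Model

The observed matrix **Y** (P features × N samples) is modelled as

    Y ≈ W H,    H ≥ 0, every column of H on the unit simplex (Σ_k h_ks = 1),
                W ≥ 0 (and W ≤ 1 for methylation beta values)

where **W** holds the pure cell-type profiles and **H** the mixing
proportions.  Given estimated proportions θ_s, each feature is regressed on
the proportion-valued design

    E(Y_p) = V β_p,   V[s, k] = θ_sk,

so the OLS coefficient μ_pk is the mean level of feature p in cell type k.
Cell-type-specific features are detected with the one-vs-rest contrast

    H0 : μ_pk − (1/(K−1)) Σ_{i≠k} μ_pi = 0

tested by a Wald t statistic (df = N − K) whose residual variance is floored
at the 10th percentile of all per-feature residual variances.  The algorithm
alternates: deconvolve on the current feature set → test all features with
the estimated proportions → keep the top 1000 (round-robin across cell
types) → re-deconvolve; after 30 iterations the iteration with the smallest
reconstruction RMSE, √(Σ(Y−WH)²/PN), is reported.

## Worked example

```r
library(decomix)

# simulate a 4-cell-type expression mixture with known ground truth
pp  <- default_panel_params(5000, 4, seed = 1)
sim <- simulate_expression_dataset(pp, n = 100, seed = 1)

fit <- decomix(sim$mixture, k = 4, seed = 1)
fit
#> Reference-free deconvolution with iterative marker selection
#>   cell types: 4   samples: 100   markers per iteration: 1000
#>   chosen iteration: 1 of 30  (reconstruction RMSE 20.0857 )
#>   mean estimated proportions: C1=0.237  C2=0.156  C3=0.486  C4=0.120

evaluate_deconvolution(coef(fit), sim$h_true)
#> metric  value
#> corr_C1 0.994046
#> corr_C2 0.985525
#> corr_C3 0.995776
#> corr_C4 0.983176
#> mean_correlation        0.989631
#> rms_bias        0.152718

# the un-iterated baseline, for comparison
evaluate_deconvolution(fit$H_list[[1]], sim$h_true)$mean_correlation
#> [1] 0.6156795
```

The per-type correlations compare estimated and true proportions across
samples after optimally matching the unlabeled components to the truth;
`rms_bias` is the root mean squared difference of the two proportion
matrices.  Correlation rewards tracking the truth across samples, while
RMSBias also penalizes systematic level shifts, which the factorization's
scale indeterminacy can induce — hence a near-1 correlation can coexist
with a non-trivial bias.  Iterative marker selection lifts the mean
correlation from 0.62 (initial variance-window features) to 0.99.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/decomix", package = "decomix"))')
Rscript $CLI simulate --modality expression --n 100 --p 5000 --k 4 --seed 1 --out-dir sim
Rscript $CLI run --input sim/mixture.tsv --k 4 --seed 1 --out-dir fit
Rscript $CLI evaluate --est fit/proportions.tsv --truth sim/true_proportions.tsv
```

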