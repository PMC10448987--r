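# beene — batch-effect estimation with guided nonlinear embeddings

Integrating RNA-seq data from several experiments means living with batch
effects: systematic, non-biological differences between groups of samples
processed under different conditions. Before (and after) correcting them,
you need to *measure* them. The standard recipe — compute kBET rejection
rates or iLISI mixing scores in the top principal components — works well
when the batch distortion is linear, and under-reports it badly when it is
not, because a linear projection simply cannot see an expression-dependent
distortion.

`beene` estimates batch effects in an embedding trained to retain them. A
guided autoencoder compresses each cell's profile into a 50-dimensional
latent code while two auxiliary heads predict the cell's batch and
(optionally) its biological class from that code. All parts are trained
jointly on

    J(phi, theta, psi, omega) =
        sum_i [ lambda1 * ||x_i - f_theta(f_phi(x_i))||^2
                - lambda2 * sum_k 1{b_i = k} log B_ki
                - lambda3 * sum_k 1{y_i = k} log Y_ki ]
        + 1e-4 * sum_w ||w||^2

so the latent space keeps both batch-specific and biological variation —
linear *or* nonlinear. kBET and iLISI computed on this embedding respond to
batch-effect strength over a much wider dynamic range than in PCA space,
without flagging batch-free data. The package also ships the two metrics
themselves (usable on any embedding), a PCA baseline, a gamma-Poisson
single-cell count simulator with controllable linear/nonlinear additive
batch effects, an end-to-end pipeline with 5-fold cross-validation and
amplitude/proportion sweeps, and a small CLI
(`inst/scripts/beene-cli.R`).

It estimates; it does not correct. Feed it raw data or the output of
ComBat/Harmony/MNN to quantify what correction left behind.

## Worked example

Simulate the two-cell-type condition (2 × 1000 cells, 2500 genes, two
batches) with a nonlinear batch effect of amplitude range [0, 0.4], train
the guided embedding, and score it against PCA:

```r
library(beene)

be <- simulateCondition("nonlinear_2type", b = 0.4, seed = 1)
report <- runEstimation(be, seed = 1)
print(report)
#> Batch-effect estimation report
#>   beene      n=400   kBET mean rejection 0.871 | iLISI mean 1.184
#>   pca_test   n=400   kBET mean rejection 0.164 | iLISI mean 1.694
#>   pca_full   n=2000  kBET mean rejection 0.448 | iLISI mean 1.545
```

Reading the numbers: on the held-out test cells, 87% of kBET's local
neighborhoods reject the well-mixed null in the guided embedding (mean
iLISI 1.18 — locally, cells effectively see ~1.2 of the 2 batches), while
the same test in PCA space rejects only 16–45% of neighborhoods. The same
pipeline on the batch-free control (`simulateCondition("batchfree_2type")`)
gives a latent-space rejection rate near 0 and iLISI near 2 — the
sensitivity is not an artifact of the trained head.

Sweeps and cross-validation:

```r
sw <- runSweep(mode = "amplitude", values = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
               nReps = 3, seed = 1)
attr(sw, "summary")     # per-amplitude means of PCA/latent kBET + iLISI

cv <- crossValidatedScores(be, nFolds = 5, seed = 1)
cv$mean; cv$sd
```

Real data enter through `loadExpression()` (MTX or CSV/TSV) +
`attachLabels()` + `normalizeExpression()`, or any matrix you already have
in memory via `BeeneExperiment()`. For ~10k+ gene matrices use
`variant = "high_dim"`; for PC-score inputs (e.g. scoring
Harmony-corrected embeddings) use `variant = "pc_input"`.

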