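# fuseAE — feature-level multi-omics integration with multi-view autoencoders

fuseAE is an R package for integrating several omics modalities (gene
expression, DNA methylation, miRNA expression, copy-number calls — any
continuous samples × features matrices over the same cohort) for
classification and right-censored survival prediction. It is aimed at
computational biologists who want a self-contained, CPU-only,
reproducible implementation of autoencoder-based feature-level
integration, including the simulation machinery needed to validate the
integration principles without any external data.

## The models

For one modality, an encoder q(x) maps the input to a latent vector z,
a decoder p(z) reconstructs x̂, and a task head consumes z — a linear
classifier c(z), or a small fully connected survival network s(z) whose
scalar output h is a log-relative hazard trained with the Cox negative
log partial likelihood

    L_sur = -(1/N_ob) Σ_{i: C_i=1} ( h_i − log Σ_{j: T_j ≥ T_i} exp(h_j) ),

with risk sets under the Breslow tie convention, and evaluated with
Harrell's concordance index (ties count 0.5).

Two integration strategies combine modalities at the feature level:

* **ConcatAE** (complementary principle) — one independent autoencoder
  per modality; the task head consumes the concatenated latents
  [z₁, z₂]; the reconstruction loss is the sum of per-modality MSEs.
* **CrossAE** (consensus principle) — equal latent dimensions, trained
  in three phases: per-modality reconstruction, cross-modality
  reconstruction (decoder p₁ rebuilds x₁ from z₂ and vice versa,
  L_cross = (1/N) Σ ((x₁−x̂₁₂)² + (x₂−x̂₂₁)²)), then task training on
  the element-wise average of the latents.

Around the models, the package implements the full study pipeline:
missing-feature removal, log2(X+1) for expression-like modalities,
train-fitted min-max scaling, PCA-100 or top-1000-variance feature
reduction, stratified four-fold 60/15/25 cross-validation with
validation-based checkpoint selection, and `mean ± sd` reporting.

## Worked example

Simulate a two-modality survival cohort with known risk and compare a
single-modality survival network against ConcatAE integration when each
modality carries disjoint prognostic signal:

```r
library(fuseAE)

res <- survivalRecoveryExperiment(effectShared = 0, effectUnique = 1,
                                  seeds = 1,
                                  integrations = c("single1", "single2",
                                                   "concat"))
round(res, 3)
#>   seed oracle single1 single2 concat
#> 1    1  0.776   0.659   0.655  0.756
```

The oracle column is the concordance index of the generating (true)
risk — the ceiling any model can reach. Each single modality only sees
its own half of the risk signal (C-index ≈ 0.66); concatenating the two
latent spaces recovers most of the combined signal (0.756), which is
the complementary-integration claim in miniature.

The same machinery runs on files from the command line:

```sh
Rscript inst/scripts/fuseae.R simulate omics --out data --seed 7
Rscript inst/scripts/fuseae.R train --data data --out run \
        --integration concat --features pca --epochs 100
cat run/report.txt
#> cindex: 0.765 ± 0.018
```

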