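# ssm6mA — selective state-space models for DNA N6-methyladenine prediction

`ssm6mA` predicts whether the central adenine of a fixed-length DNA window
(41 bp by default, site at position 21) carries an N6-methyladenine (6mA)
mark. 6mA is an epigenetic modification involved in transcription,
replication and DNA repair; experimental mapping at single-base resolution
(SMRT sequencing) is costly and noisy, so sequence-based classifiers are
the standard complement. The package is aimed at computational
epigenetics researchers who work with the paired positive/negative FASTA
benchmark layout and want a trainable, inspectable model plus the full
experimental harness around it.

## The model

Windows are embedded base-by-base into X ∈ R^(L×N) and processed by three
parallel branches of six stacked selective state-space (Mamba-style)
layers at filter window sizes K ∈ {3, 5, 7}. Each layer applies a
**position-specific linear filter bank** — every position i has its own
weights:

    g[i,p] = Σ_k Σ_j f(K)[i,p,k,j] · d[i − ⌊K/2⌋ + k − 1, j]

followed by SiLU and an input-dependent recurrence discretized by
zero-order hold:

    Ā_t = exp(Δ_t A),  B̄_t = Δ_t B_t,
    h_t = Ā_t ⊙ h_(t−1) + B̄_t g_t,   z_t = ⟨C_t, h_t⟩

with B_t, C_t, Δ_t computed from the current input. Branch outputs Z₃,
Z₅, Z₇ are fused by per-cell softmax weights derived from learnable query
vectors (Z = Σ_K W′_K ⊙ Z_K, Σ_K W′_K = 1), flattened, and classified by
a 384→16→1 fully connected head with sigmoid output. Training follows the
benchmark protocol: Adam, binary cross-entropy, batch 64, 5-fold
cross-validation, early stopping on validation accuracy, and a
size-dependent learning rate (5e-5, or 1e-5 above 40k training windows).
Evaluation reports ACC, MCC, SN, SP (confusion-matrix formulas) and
rank-based AUC.

The forward/backward passes and the optimizer are implemented in C++
(RcppArmadillo); everything is driven from R. See the vignette
(`vignettes/selective-ssm-6mA.Rmd`) for conventions, parameter meanings
and design rationale.

## Worked example

Simulate a planted-motif benchmark (GAG flanking the central adenine in
90% of positives, 10% of negatives), train a reduced model with 2-fold
cross-validation, and locate the signal:

```r
library(ssm6mA)

train <- simulateWindows(generatorConfig(
  nPerClass = 500, motif = motifSpec("GAG", anchor = 20,
                                     plantProbability = 0.9,
                                     decoyProbability = 0.1), seed = 1))
test <- simulateWindows(generatorConfig(
  nPerClass = 500, motif = motifSpec("GAG", 20, 0.9, 0.1), seed = 2))

cfg <- modelConfig(embeddingDim = 8, hiddenDim = 16, numFilters = 16,
                   stateDim = 4, layersPerBlock = 1, fcDims = c(64, 16, 1))
fit <- crossValidate(train, test, cfg,
                     trainConfig(batchSize = 50, learningRateSmall = 1e-3,
                                 maxEpochs = 6, patience = 3, folds = 2,
                                 seed = 42))
fit
#> MetricsReport over 2 fold(s)
#>   fold   ACC    MCC    SN   SP    AUC
#> 1    1 0.863 0.7287 0.906 0.82 0.8647
#> 2    2 0.863 0.7287 0.906 0.82 0.8553
#> summary:
#>   statistic   ACC    MCC    SN   SP      AUC
#> 1      mean 0.863 0.7287 0.906 0.82 0.860006
#> 2        sd 0.000 0.0000 0.000 0.00 0.006638
#> train/test overlapping sequences: 0

head(positionEnrichment(train)[order(-positionEnrichment(train)$log2Odds), ], 3)
#>     position base   freqPos   freqNeg  log2Odds
#> 87        22    G 0.9093625 0.2918327 1.6397142
#> 79        20    G 0.9292829 0.3157371 1.5573942
#> 112       28    T 0.2798805 0.2161355 0.3728751
```

The held-out MCC of 0.73 is essentially the information ceiling of this
generator: the classes differ only in the flanking G's, and the
Bayes-optimal rule ("positive iff G at 20 and 22") achieves sensitivity
0.906 and specificity 0.844 — exactly the pattern the model converges to.
The enrichment table confirms G at positions 20 and 22 as the dominant
class difference.

A command-line interface wrapping the same functions ships at
`inst/scripts/ssm6mA` with subcommands `simulate`, `train`, `evaluate`,
`predict`, `ablate` and `interpret` (see `?runCli`).

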