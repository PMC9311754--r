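# pssmLPP

Sequence-based prediction of protein–protein interactions (PPIs) with
evolutionary profiles, Locality Preserving Projections and a Rotation
Forest ensemble.

High-throughput interaction screens (yeast two-hybrid, TAP) are costly
and noisy, so computational predictors that need nothing but the amino
acid sequence of a protein pair are widely used to prioritize candidate
interactions. `pssmLPP` implements one such pipeline for people who work
with PSI-BLAST profiles and labeled pair lists: parse the profiles,
embed each protein, classify each pair, and evaluate honestly.

## The method

1. **Profile representation.** Each protein of length *N* is represented
   by its position-specific scoring matrix (PSSM), the *N* × 20 matrix of
   log-odds scores `α_{i,j}` produced by PSI-BLAST (`-out_ascii_pssm`),
   which captures which substitutions each position tolerated during
   evolution. The package parses that format; it does not run PSI-BLAST.
2. **Fixed-length descriptor.** Scores are squashed with the logistic
   function `s = 1/(1+e^{-x})` and condensed into the length-normalized
   cross-product matrix `C = SᵀS / N` (20 × 20, flattened to 400 values),
   which is invariant to sequence length and row order.
3. **Locality Preserving Projections (LPP).** A linear embedding
   `y = Wᵀx` that minimizes `Σ_{ij} (y_i − y_j)² P_{ij}` over a
   symmetrized k-nearest-neighbor graph with heat-kernel weights
   `P_{ij} = exp(−‖x_i−x_j‖²/t)`, solved as the generalized eigenproblem
   `X L Xᵀ w = λ X D Xᵀ w` (L = D − P the graph Laplacian, D the degree
   matrix) under the constraint `wᵀX D Xᵀw = 1`, keeping the eigenvectors
   of smallest eigenvalue. The problem is solved on the span of the
   centered training data, which is what makes the projection usable on
   proteins not seen during fitting.
4. **Pair features and Rotation Forest.** A pair (a, b) is the
   concatenation of the two protein embeddings. The classifier is a
   Rotation Forest: for each of L trees the feature set is randomly split
   into K disjoint subsets, a PCA basis is computed per subset from a 75%
   bootstrap sample, the per-subset loadings form a block-diagonal
   rotation `F_i`, and a CART tree is grown on `X F_i`. Class posteriors
   are averaged over trees: `μ_j = (1/L) Σ_i d_{i,j}(x F_i)`.
5. **Evaluation.** Stratified 5-fold cross-validation, an embedding
   dimension sweep, and a train-on-one-dataset / test-on-another
   protocol; metrics are accuracy, precision (two dialects, see the
   vignette), sensitivity, Matthews correlation coefficient, and ROC/AUC.

A synthetic benchmark generator plants a tunable latent-similarity
interaction signal in realistic PSSM-shaped data, so the entire pipeline
is testable without any database downloads.

## Worked example

```r
library(pssmLPP)

dat <- simulate_ppi_data(synthetic_config(seed = 1))   # 120 proteins, 200+200 pairs
cv  <- cross_validate(dat$pssms, dat$pairs, pipeline_config(out_dim = 20), seed = 1)
print(cv)
#> 5-fold cross-validation (400 pairs, seed 1)
#>   n_test accuracy precision sensitivity    mcc    auc
#> 1     80   0.9875     0.975       1.000 0.9753 0.9856
#> 2     80   0.9875     1.000       0.975 0.9753 1.0000
#> 3     80   0.9500     0.950       0.950 0.9000 0.9747
#> 4     80   0.9750     0.950       1.000 0.9512 0.9675
#> 5     80   0.9375     0.900       0.975 0.8775 0.9569
#> mean:
#>    accuracy   precision sensitivity         mcc         auc
#>      0.9675      0.9550      0.9800      0.9359      0.9769
#> sd:
#>    accuracy   precision sensitivity         mcc         auc
#>      0.0227      0.0371      0.0209      0.0448      0.0166
```

Each fold holds out 80 pairs; LPP is fitted on the training-fold
proteins only, every protein is embedded with the fitted projection, and
a K = 5 / L = 5 rotation forest is trained on the training pairs. The
mean row is the headline result: on the default synthetic benchmark
(separation 4) the pipeline recovers the planted interaction signal at
~97% accuracy and AUC ~0.98. With `separation = 0` the same pipeline
stays at chance (~0.50), which is the null calibration the test suite
checks.

Real data enter through the same interfaces: `read_fasta()`,
`read_ascii_pssm()` (one file per protein) and `read_pair_list()`
(TSV `id_a  id_b  label`).

### Command line

A thin launcher `exec/pssmlpp` wraps the same functions:

```sh
pssmlpp simulate --out fixture/ --seed 1
pssmlpp cv --fixture fixture/ --out results/ --dim 20 --seed 1
pssmlpp sweep --fixture fixture/ --dims 10,20,40 --out sweep/ --seed 1
```

Every run writes its effective configuration next to its outputs and is
byte-reproducible from `--seed`.

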