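---
title: "Predicting protein–protein interactions from PSSM profiles: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein–protein interactions from PSSM profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmLPP)
```

## The problem

Experimentally mapped protein–protein interactions cover a small, biased
slice of any interactome. Sequence-based predictors fill the gap: given
only the amino-acid sequences of two proteins, output a probability that
they interact. `pssmLPP` implements a three-stage pipeline — evolutionary
profile, graph-based linear embedding, rotated tree ensemble — together
with the evaluation protocols used in this literature and a synthetic
benchmark that makes the whole chain testable offline.

## Pipeline and assumptions

### From PSSM to a fixed-length descriptor

The input profile for a protein of length $N$ is its PSSM
$D \in \mathbb{R}^{N\times 20}$, whose entry $\alpha_{i,j}$ scores how
readily position $i$ mutates into residue type $j$. Columns follow the
PSI-BLAST header order (`A R N D C Q E G H I L K M F P S T W Y V`);
all code indexes by this order. Only the log-odds block of the ASCII
file is used — it is the scale on which the logistic squashing
$s = 1/(1+e^{-x})$ is a natural soft normalizer (PSI-BLAST log-odds
essentially saturate outside roughly $[-10, 12]$).

Proteins have different lengths but downstream stages need one vector
per protein. The bridge is the squashed cross-product descriptor
$$C = \tfrac{1}{N} S^\top S \in \mathbb{R}^{20\times 20},$$
flattened row-major to 400 values. $C$ captures the co-occurrence
structure of the residue profile, is exactly invariant to row order and
row duplication, and makes embedding dimensions in the tens a genuine
reduction. A 20-dimensional column-mean variant
(`pssm_to_composition(..., method = "plain-mean")`) is kept for
ablation.

### Locality Preserving Projections

LPP seeks a linear map $y_i = W^\top x_i$ minimizing
$\sum_{ij}(y_i-y_j)^2 P_{ij}$, i.e. points that are close in descriptor
space must stay close after projection. Choices the method leaves open,
and what this package does:

* **Link rule.** "Linked" is taken as the symmetrized $k$-nearest-neighbor
  relation under Euclidean distance, default $k = 5$ — the standard
  construction.
* **Heat scale.** $P_{ij} = \exp(-\lVert x_i-x_j\rVert^2/t)$ with
  $t$ = mean squared linked distance by default (`heat_scale = "auto"`),
  so typical linked weights sit near $e^{-1}$ at any data scale. The
  exact invariance (scaling $X$ by $c$ and $t$ by $c^2$ leaves $P$
  unchanged) is tested.
* **Centering.** Columns are mean-centered before the eigenproblem;
  this removes the trivial constant direction and is reapplied at
  transform time.
* **Span restriction.** The generalized eigenproblem
  $X L X^\top w = \lambda X D X^\top w$ is solved on the span of the
  centered training data (SVD pre-projection). With 400-dimensional
  descriptors and ~100 proteins, the ambient problem is massively
  rank-deficient: its smallest eigenvectors live in the data null
  space, vanish on every training sample, and take arbitrary —
  typically enormous — values on new proteins. Restricting to the span
  removes those directions; it is the difference between an embedding
  that transfers to unseen proteins and one that only works
  transductively. If the requested dimension exceeds the data rank the
  trailing embedding coordinates are constant zero.
* **Regularization.** Within the span, the right-hand matrix gets a
  ridge $\varepsilon = 10^{-6}\,\mathrm{tr}(XDX^\top)/r$ by default;
  $\varepsilon = 0$ is allowed and errors informatively if the matrix is
  singular.
* **Determinism.** Eigenvalues are returned ascending; each eigenvector
  is rescaled to the constraint $w^\top XDX^\top w = 1$ and
  sign-canonicalized (largest-magnitude entry positive). Ties in
  eigenvalues are broken by solver order; with the sign convention this
  makes results platform-stable.

The solver path is Cholesky whitening plus one dense symmetric
eigendecomposition. The test suite checks it against an independently
coded oracle (Gram-matrix span basis, eigendecomposition-based inverse
square root) to $10^{-6}$, verifies the defining residual
$\lVert XLX^\top w - \lambda(XDX^\top+\varepsilon I)w\rVert$ to
$10^{-8}$ relative, and confirms the identity
$\tfrac12\sum_{ij}(y_i-y_j)^2P_{ij} = w^\top XLX^\top w$.

### Pair representation

A labeled pair (a, b) becomes the concatenation of the two protein
embeddings, in pair-list order (2d features for per-protein dimension
d). The embedding dimensions quoted in this method family (40…140) are
read here as the *per-protein* dimension; the default benchmark uses
d = 20 (pair vectors of 80 features), appropriate for its 120-protein
scale, and `dimension_sweep()` reproduces the sweep table for any list
of dimensions. No symmetrization is applied by default — (a, b) and
(b, a) are distinct vectors — but `make_pair_features(...,
symmetrize = TRUE)` appends reversed pairs for training augmentation.

### Rotation Forest

Each of the $L$ trees sees the data through its own sparse rotation:
the $m$ features are randomly partitioned into $K$ disjoint subsets
(sizes $\lceil m/K\rceil$ or $\lfloor m/K\rfloor$), a full-rank PCA is
computed per subset on a bootstrap sample of 75% of the rows (drawn
with replacement; a without-replacement option exists), and the
loadings are assembled block-diagonally. Because every block is
orthonormal and all components are retained, $F^\top F = I$: the data
are rotated, never reduced — this orthogonality is asserted to
$10^{-8}$ over many seeded builds. A subset with zero variance in its
bootstrap sample falls back to an identity block. Base learners are
CART trees (Gini splits) grown to purity (`minsplit = 2`, `cp = 0`),
matching the "fully grown trees" reading of the method; posteriors are
the across-tree average and an exact 0.5 tie is resolved to
non-interacting, the conservative call. Defaults $K = L = 5$ are the
method's headline settings. The classifier is binary by construction.

The original rotation-forest formulation also subsamples classes before
each PCA; that step is omitted here (the method description this
package follows does not include it) and the omission is documented
rather than silently absorbed.

### Metrics: two precision dialects

Published tables in this family sometimes report specificity under the
heading "precision". `compute_metrics()` therefore supports
`dialect = "as_printed"` (precision computed as $TN/(TN+FP)$ — the
quantity those tables actually tabulate; the default, so package output
is comparable to them) and `dialect = "standard"`
($TP/(TP+FP)$). Accuracy, sensitivity and MCC are identical in both.
The ROC always uses the standard $FPR = FP/(FP+TN)$ — any other
denominator does not produce a ROC curve — with a threshold sweep over
unique scores and trapezoidal AUC, validated exhaustively against a
concordance (pair-counting) oracle. Metrics with zero denominators are
reported as 0 and flagged in an `undefined` attribute.

### Evaluation protocols

`cross_validate()` stratifies folds on the pair label. By default LPP
is fitted on training-fold proteins only (no transductive leakage);
`transductive = TRUE` fits it on all proteins for comparison with
protocols that do not make the distinction. Note this is *pair-level*
cross-validation: a protein may appear in both training and test
pairs, only pairs are held out. `independent_test()` is the stricter
protocol — fit everything on one dataset, evaluate on another.

## The synthetic benchmark

`synthetic_config()` defines the study conditions; the defaults are the
conditions under which the package's acceptance checks run: 120
proteins, lengths 50–120 (mirroring the common ≥ 50-residue dataset
filter), 200 interacting + 200 non-interacting pairs, seed 1.

The generative model plants a *latent functional-module* signal:

* 12 module directions, mutually orthogonal, norm 3, drawn once per
  world seed; a protein's latent vector is its module direction plus
  spherical $N(0, 0.25^2)$ noise. Modules emulate complexes/pathways —
  groups of proteins with correlated evolutionary profiles and
  concentrated interactions.
* PSSM rows are integer scores clipped to $[-10, 12]$ with column means
  $\mu = b + 2\,\Lambda z$ ($\Lambda$ a fixed random 20×latent loading,
  scaled $1/\sqrt{d}$), unit noise per entry. Sequences are the
  per-position argmax residue, so FASTA and PSSM are consistent.
* Interacting pairs are drawn with the shifted logistic weight
  $w_{ab} = \mathrm{plogis}\big(\text{separation}\cdot(\langle z_a,z_b\rangle - \tau)/\sigma\big)$,
  $\tau$ the 95th percentile of pair inner products and $\sigma$ their
  MAD: interaction probability increases with latent alignment, and at
  the default separation 4 concentrates on the aligned (same-module)
  tail. Negatives are uniform over the remaining pairs. At
  `separation = 0` all weights are equal and the labels are pure noise —
  the null benchmark.

Why modules rather than one diffuse latent cloud: with spherical
latents the positive region is a thin "aligned band" that axis-aligned
tree ensembles cannot carve at any useful accuracy, so a benchmark
built that way measures nothing but classifier mismatch. Module
structure keeps the same monotone inner-product link while making the
signal recoverable by the actual pipeline.

What the generator does *not* emulate: homology between proteins,
domain architecture, hub proteins, length-dependent profile quality,
and dataset-construction artifacts of real interaction databases.
Passing the synthetic checks therefore demonstrates that the
implementation recovers a planted signal of known strength through the
full PSSM → descriptor → LPP → forest chain — not that the method will
attain any particular accuracy on real organisms.

Two quantitative consequences of the design are worth knowing:

* **Accuracy ceiling.** Uniform negatives occasionally fall in the
  same-module pool (~5% at the default sizes); those pairs are
  statistically indistinguishable from positives, capping benchmark
  accuracy near 0.97–0.98. Observed 5-fold CV accuracy ~0.97 sits at
  that ceiling.
* **Pair-level vs protein-level generalization.** In pair-level CV,
  test-fold proteins usually occur in training pairs, so fully grown
  trees may key on individual proteins' embedding coordinates. The
  same-world independent test (`world_seed` reuse with fresh proteins)
  exposes this: transfer is well above chance (AUC ≈ 0.83 at the
  default conditions) but clearly below the CV numbers. Coarser base
  trees trade CV accuracy for transfer; the package keeps fully grown
  trees as the documented default and exposes `control` on
  `rotation_forest()` for users who want the other end of that
  trade-off. The gap itself is a faithful reproduction of a known
  optimism of pair-level protocols.

## Problem sizes and runtime

Defaults were chosen so a full check cycle is interactive on one CPU:
the benchmark CV (120 proteins, 400 pairs, d = 20) runs in about a
second; the 10-seed null calibration in ~10 s; LPP oracle comparisons
use 20 instances with $n \le 50$, $m \le 10$; rotation-matrix
orthogonality is checked over 100 builds. The acceptance script
recomputes everything in well under a minute.

## Known limitations

* Binary classification only; multi-class interaction typing is out of
  scope.
* PSI-BLAST itself is not run; profile quality is the caller's
  responsibility, and the percentage block of the ASCII PSSM is ignored.
* Sequence-identity clustering for dataset construction (CD-HIT-style)
  is not provided — only the ≥ 50-residue length filter.
* Pair-level cross-validation overstates performance on truly novel
  proteins; use `independent_test()` for the stricter claim.
* Model persistence uses R serialization (`.rds`), so saved models are
  not portable across package versions.
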