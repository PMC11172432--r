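---
title: "Sequence-only PPI prediction by deep feature fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-only PPI prediction by deep feature fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dfppi` predicts whether two proteins physically interact using nothing but
their amino-acid sequences. It fuses two complementary sequence
representations inside one neural classifier: *handcrafted descriptors*
(fixed formulas summarizing composition, local structure and
physicochemical order) and a *learned residue embedding* read by a second
network channel. This vignette explains the model, every tunable parameter
that matters, the synthetic benchmark the package tests itself on, and the
numerical choices made where the design was genuinely open.

## The representation: three handcrafted descriptors

Each protein sequence is mapped to a 910-dimensional vector, the
concatenation of three descriptors. All three are defined on the 20
standard residues; non-standard codes (B, O, U, X, Z and any other letter)
are stripped before descriptor encoding, while the embedding channel keeps
them as dedicated tokens.

**Local descriptor (630 values).** The 20 residues are mapped to seven
physicochemical groups ({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K},
{D,E}, {C}); the sequence is cut into ten overlapping regions — seven
windows of 25% length starting every 12.5% and three windows of 75% length
starting at 0, 12.5 and 25% (the unique overlapping layout in which the
three long windows jointly cover the sequence). Each region contributes 63
values: 7 group frequencies (composition), 21 adjacent group-pair
alternation rates (transition), and, for each group, the
length-normalized positions of its first, 25th-percentile, median,
75th-percentile and last occurrence (distribution). Region boundaries are
`floor(start*L)+1 .. floor(end*L)` in 1-based coordinates, which keeps
every region non-empty for sequences of at least 8 standard residues.

**F-vector (140 values).** For each of the choose(7,4) = 35 ways of
merging four groups into one class G0 and spreading the remaining three
groups (ascending group index) over G1, G2, G3, residues are placed on the
unit circle: residue *j* of class G*k* sits at angle
\((n_j(G_k)/(n(G_k)+1) + k)\,\pi/2\), where \(n_j(G_k)\) counts class-k
residues among the first *j* and \(n(G_k)\) is the class total — each
class sweeps one quadrant. The point cloud is summarized by the mean and
the sample variance of each coordinate, giving four values per partition.
The dispersion terms are variances, not standard deviations: that is how
the defining formula is printed, and the choice only rescales features the
network learns to weight anyway. For a single-residue sequence the
variance terms are defined as 0.

**Pseudo-amino-acid composition with tripeptide terms (20 + 4λ values).**
The amphiphilic pseudo-amino-acid composition couples the 20 residue
frequencies with lagged correlations of standardized hydrophobicity
(Tanford-style) and hydrophilicity (Hopp–Woods) profiles:
\(\tau_k = \frac{1}{L-k}\sum_i h_i h_{i+k}\) for lags 1..λ on both scales.
The variant implemented here adds triplet correlations
\(\upsilon_k = \frac{1}{L-2k}\sum_i h_i h_{i+k} h_{i+2k}\), capturing
sequence order at the tripeptide scale. All terms are divided by
\(C=\sum f + w_1\sum\tau + w_2\sum\upsilon\). Defaults λ = 30,
w1 = w2 = 0.5. Two conventions deserve note: the published index ranges of
the lag terms are typographically inconsistent, so lags run k = 1..λ with
the two property scales alternating (reproducing the printed 2λ + 2λ term
counts); and any term whose averaging window is empty (L − k ≤ 0 or
L − 2k ≤ 0) is set to 0 rather than raising, because curated benchmarks
contain 50-residue sequences that must remain encodable at λ = 30. The
property table is shipped as a plain TSV and can be overridden.

## The representation: learned residue embeddings

Residues are tokenized 0–19 (standard residues, alphabetical), 20–24
(B, O, U, X, Z; other letters fold into X) and 25 (padding). Sequences
are right-truncated or right-padded to a fixed length N, conventionally
the floored mean training-sequence length. A distributed-memory
paragraph-vector model treats each protein as a document and each residue
as a word: for every position, the document vector and the word vectors in
a ±5-residue window are averaged and a softmax predicts the center token.
Because the vocabulary has only 25 words, the full softmax is exact and
cheap — no negative sampling or hierarchical approximations — which makes
training bitwise-reproducible from the seed. Word vectors become the
initial weights of the model's trainable embedding layer; document
vectors are discarded. The padding token's embedding is pinned to zero
throughout (its gradient is masked), so padded positions contribute
nothing. Pinned training defaults (window 5, min_count 1 — no token may be
dropped from a 25-word vocabulary — 10 epochs, learning rate 0.05) are
package choices: the reference implementations' "defaults" drift across
versions, and pinning keeps results stable. The embedding dimension
default is 32, the best value of the sweep over {8, 16, 32, 64, 128}
reported for this architecture.

## The model

Each protein passes through a two-channel block. Channel 1 reads the
910-dimensional handcrafted vector through dense layers of 1024, 512, 256
and 128 units; channel 2 reads the flattened N×32 embedding output through
2048, 512, 256 and 128 units. Every dense layer is followed by relu, batch
normalization and dropout, in that order. The two 128-dimensional channel
outputs are fused by a convex combination
\(f = \omega h' + (1-\omega) e'\); ω = 0.5 by default (the optimum of the
sweep over {0.1, 0.3, 0.5, 0.7, 0.9}), ω = 1 or 0 exactly reduces the
model to a single-channel network (the unused channel is then not even
evaluated). The two per-protein vectors are averaged,
\(f_{AB} = (f_A+f_B)/2\), and a small head (dense 16 + relu + norm +
dropout, then dense 2 + softmax) emits the interaction probability.

Open design points, resolved as follows:

* *Flatten vs. pool the embedding output.* The N×32 embedding block is
  flattened into one long vector (the 2048-unit first layer of channel 2
  indicates a wide flat input); mean-pooling would discard residue order,
  the very information the embedding channel is meant to contribute.
* *Per-protein vector width.* The source description is self-contradictory
  (256 in one place, 128 in another); 128 is adopted, consistent with the
  fusion being a convex sum of two 128-dimensional vectors.
* *Weight sharing.* The two protein blocks are drawn as separate networks
  and are independent by default. Because the averaging head is symmetric
  in (f_A, f_B), a `share_block_weights = TRUE` option makes the whole
  model exactly invariant to swapping the pair; with independent blocks
  that invariance is deliberately not guaranteed.
* *Unstated hyper-parameters.* Dropout rate 0.2, batch size 128 and 45
  epochs are configurable defaults; the time-based learning-rate decay
  coefficient defaults to `lr0 / epochs`, the standard convention.
* *Feature scaling.* The 910 handcrafted features span very different
  scales, which destabilizes batch normalization; they are standardized
  feature-wise using training-fold statistics only (stored in the model,
  reapplied at prediction time).

Training minimizes binary cross-entropy on the interaction probability
with Adam at its standard settings (learning rate 0.001, β₁ = 0.9,
β₂ = 0.999, ε = 1e-8) under time-based decay
`lr_t = lr0 / (1 + decay * (t-1))`. Numerical details: batch
normalization uses biased batch variances with ε = 1e-5 and running-stat
momentum 0.1 (inference uses running statistics; a freshly built model has
mean 0/variance 1); dropout is inverted (scaling by 1/(1−rate) at train
time); softmax is computed with row-max subtraction; probabilities are
clipped at 1e-12 inside the log loss. All randomness (initialization,
shuffling, dropout) flows from explicit seeds through R's RNG on a single
worker, so training trajectories are bitwise-reproducible; the analytic
backward pass (including the fusion wiring, pair averaging and the
embedding scatter-gradient) is verified against central-difference
numerical gradients in the test suite. Predictions call a pair
interacting when probability ≥ threshold (ties positive); 0.5 by default,
or a threshold selected on a stratified 8:1 train/holdout split by
maximizing holdout F1 over a 0.001-step grid in [0.5, 1], ties broken
toward the smallest threshold.

## Evaluation protocols

`metrics()` implements accuracy, sensitivity, specificity, precision,
negative predictive value, F1 and Matthews correlation from the confusion
counts; ratios with zero denominators are reported as 0 with a warning so
fold aggregation stays total. AUROC uses the midrank (Mann–Whitney)
construction, AUPRC step integration with tied scores grouped.
Cross-validation is stratified (the source protocol says only "randomly
divided"; stratification reduces fold variance and is standard practice),
with per-fold mean ± SD reporting, a fresh model per fold and
fold-assignment reproducibility from the seed. For positive-only test
sets, the threshold-accuracy AUC integrates the fraction of probabilities
≥ t over t ∈ [0, 1] by the trapezoid rule on a uniform 1001-point grid
(the integration rule is unstated in the source; a uniform trapezoid is
the least-surprising choice, and the value is insensitive to the grid at
this resolution). Network reconstruction predicts every edge of a known
interaction network and reports the count recovered at a threshold.

## The synthetic benchmark

Real curated benchmarks (interaction databases filtered at 40% sequence
identity) are external downloads; the package instead tests itself on a
generator whose signal is planted and therefore known exactly. Background
sequences are i.i.d. residues (uniform composition by default), lengths
uniform on [50, 150] — the lower bound mirrors the common "< 50 residues
removed" filter, the upper bound keeps desk-scale runtimes. A positive
pair receives an 8-residue motif (CWCWCWCW) written into protein A at a
random position and a complementary motif (HMHMHMHM) into protein B;
negatives receive none. A motif-pair rule was chosen over, say, a
composition shift because every part of the model can in principle detect
it — composition-sensitive descriptors, order-sensitive lag terms, and the
embedding channel — so fusion-ablation experiments on synthetic data are
meaningful. `insertion_rate` scales the signal down (at 0 nothing is
learnable and accuracy drops to chance, a property the tests assert) and
`label_noise` flips labels. What the generator does *not* emulate: domain
structure, codon-level biases, homology between pairs, and
subcellular-localization-based negative sampling. Passing the recovery
experiment therefore shows the pipeline can find a planted sequence
signal end-to-end; it does not certify benchmark-level accuracy on real
proteomes.

The package's self-check ("parameter recovery") runs 5-fold
cross-validation on 2000 generated pairs at full signal and zero noise,
embedding dimension 32, and requires ≥ 0.90 mean accuracy, with the fused
model (ω = 0.5) within 0.02 of the better single-channel ablation on the
same folds. Problem sizes used here — 2000 pairs, a 300-document corpus, 6
training epochs at batch 128 — are the package's desk-scale choices: large
enough for the planted signal to be comfortably learnable, small enough
for a single CPU.

## Known limitations

* The networks are trained on CPU in double precision; at benchmark scale
  (tens of thousands of pairs, N ≈ 550) a GPU framework would be the
  practical choice. The architecture and all protocols are faithful at any
  scale; only the default experiment sizes are desk-scale.
* The paragraph-vector trainer updates parameters once per document
  (exact batch gradient over the document's positions) rather than per
  position; with a 25-word vocabulary this converges to useful embeddings
  in a few epochs and keeps the implementation exactly reproducible.
* APAACplus normalization divides by \(C=\sum f+w_1\sum\tau+w_2\sum\upsilon\),
  which is signed; for extreme compositions C can approach zero and blow
  up the feature scale. Standardization at train time absorbs this in
  practice, but the descriptor itself inherits the instability from its
  defining formula.
* With independent (non-siamese) blocks, predictions are not symmetric
  under swapping the proteins of a pair; use `share_block_weights = TRUE`
  when symmetry matters.
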