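# dfppi — sequence-only protein–protein interaction prediction by deep feature fusion

`dfppi` predicts whether two proteins physically interact using only their
amino-acid sequences. It is aimed at computational biologists who have
protein FASTA files and labeled (or candidate) pair lists, and who want a
self-contained, reproducible R implementation of a fusion architecture
that combines handcrafted sequence descriptors with learned residue
embeddings.

## The method

Each protein is represented twice:

* **Handcrafted channel** — a 910-dimensional vector concatenating
  * the *local descriptor* (630): composition, transition and
    distribution statistics of seven physicochemical residue groups over
    ten overlapping sequence regions;
  * the *F-vector* (140): for each of the 35 ways of partitioning the
    seven groups into classes of size 4/1/1/1, residues are placed on the
    unit circle at angles θⱼ = (nⱼ(Gₖ)/(n(Gₖ)+1) + k)·π/2 and the point
    cloud is summarized by coordinate means and variances;
  * the *amphiphilic pseudo-amino-acid composition with tripeptide
    terms* (20 + 4λ = 140 at λ = 30): residue frequencies plus lagged
    hydrophobicity/hydrophilicity correlations
    τₖ = Σᵢ hᵢhᵢ₊ₖ/(L−k) and triplet terms
    υₖ = Σᵢ hᵢhᵢ₊ₖhᵢ₊₂ₖ/(L−2k), normalized by
    C = Σf + w₁Στ + w₂Συ.
* **Embedding channel** — the sequence is tokenized (tokens 0–19 standard
  residues, 20–24 non-standard codes, 25 padding), fixed to length N, and
  looked up in a residue embedding matrix pre-trained with a
  distributed-memory paragraph-vector model (each protein a document,
  each residue a word) and fine-tuned during training.

Per protein, channel 1 processes the handcrafted vector through dense
layers (1024, 512, 256, 128) and channel 2 the flattened N×32 embedding
block through (2048, 512, 256, 128), each layer followed by relu, batch
normalization and dropout. The channels are fused per protein as
f = ω·h′ + (1−ω)·e′ (ω = 0.5 by default), the two protein vectors are
averaged, and a small softmax head outputs the interaction probability.
Training uses Adam on binary cross-entropy with time-based learning-rate
decay; everything is bitwise-reproducible from seeds on one worker.

Evaluation utilities implement the standard binary metrics (accuracy,
sensitivity, specificity, precision, NPV, F1, MCC), AUROC/AUPRC,
stratified k-fold cross-validation with mean ± SD, a positive-only
threshold-accuracy AUC protocol, holdout-based F1 threshold selection and
interaction-network edge reconstruction. A synthetic-data module
generates reproducible benchmarks with a planted, learnable interaction
rule (complementary sequence motifs), so the whole pipeline is testable
without downloads.

## Worked example

```r
library(dfppi)

# a synthetic benchmark: 300 pairs whose positives carry complementary
# planted motifs, plus a disjoint embedding corpus
scfg  <- synthetic_config(n_pairs = 300, seed = 7)
ds    <- gen_pair_dataset(scfg)
corp  <- gen_corpus(200, scfg, exclude = ds$records)
emb   <- train_embeddings(build_corpus(corp, exclude = ds$records),
                          embedding_config(dim = 32, seed = 7))

cv <- dfppi_crossval(ds$pairs, ds$records, emb, k = 5, seed = 7,
                     cfg = model_config(omega = 0.5, embed_dim = 32),
                     tc  = train_config(epochs = 6, seed = 7))
cv
#> 5-fold cross-validation (mean +/- SD):
#>   acc    0.8167 +/- 0.0408
#>   sen    0.8867 +/- 0.0869
#>   spe    0.7467 +/- 0.1304
#>   pre    0.7869 +/- 0.0694
#>   npv    0.8828 +/- 0.0822
#>   f1     0.8289 +/- 0.0330
#>   mcc    0.6506 +/- 0.0654
#>   auroc  0.9273 +/- 0.0417
#>   auprc  0.9301 +/- 0.0450
```

The report reads like any cross-validated classifier summary: `acc` is
the fraction of held-out pairs labeled correctly at threshold 0.5, `mcc`
the Matthews correlation (1 = perfect, 0 = chance), `auroc`/`auprc` the
ranking areas. Chance accuracy is 0.5; with only 300 training pairs the
deep model reaches ~0.82, and at 1000-2000 pairs (the sizes the
acceptance script and test suite use) it exceeds 0.9.

To pick an operating threshold and reconstruct a known interaction
network:

```r
sel <- holdout_threshold(ds$pairs, ds$records, emb,
                         cfg = model_config(embed_dim = 32),
                         tc = train_config(epochs = 6, seed = 7), seed = 7)
sel$threshold
#> [1] 0.622
net <- gen_network(n_nodes = 12, n_edges = 16, scfg)
reconstruct_network(sel$model, net$edges, net$records,
                    threshold = sel$threshold,
                    n_tokens = attr(sel$model, "batch")$n_tokens)
#> recovered edges: 16/16
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/dfppi.R` (subcommands `tokenize`, `featurize`,
`train-embeddings`, `train`, `predict`, `crossval`, `simulate`).

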