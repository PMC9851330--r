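---
title: "Classifying phage lifestyle from protein-cluster token sentences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phage lifestyle from protein-cluster token sentences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Temperate phages integrate into their host's chromosome and replicate
passively until induction; virulent phages are locked into the lytic cycle.
Telling the two apart from assembled sequence matters for microbiome work
(prophage induction reshapes gut communities) and for phage therapy (only
strictly virulent candidates are acceptable). Marker genes such as integrases
identify some temperate phages, but markers are absent from many genomes and
from most short metagenomic contigs. `lysotype` instead learns the lifestyle
from the *composition and ordering of all protein families* on a contig.

# The model

A contig is read as a sentence whose words are protein clusters:

1. **Vocabulary.** An all-against-all protein similarity search (12-column
   tabular alignments) defines a graph whose nodes are proteins and whose
   edge weights are `-log10(evalue)` (floored at `1e-200`, the strongest
   direction kept). Markov clustering (MCL) partitions the graph; clusters
   with a single member are removed; the survivors, sorted by descending size
   then smallest member, become tokens `5, 6, ...` after the five specials
   `[PAD]=0, [UNK]=1, [CLS]=2, [SEP]=3, [MASK]=4`.
2. **Tokenization.** Genes are called (prodigal in meta mode, or a
   precomputed protein table), each protein is aligned against the cluster
   representatives and takes the token of its best hit (lowest e-value, then
   highest bit score, then smallest token id); proteins with no hit become
   `[UNK]`. The token list, in gene order, is framed as
   `[CLS] t1 ... tk [SEP]` and padded to exactly 300 positions; contigs with
   more than 298 genes keep the first 298.
3. **Encoder.** Token and position embeddings are learned lookup tables whose
   rows are added, giving the input matrix X. A stack of post-norm
   transformer blocks (multi-head self-attention, residual + layer norm,
   position-wise FFN with ReLU, residual + layer norm) produces a latent
   matrix Y of the same shape. Padding is excluded from attention, which is
   implemented by encoding only the non-PAD prefix — numerically identical to
   an attention mask, since padded keys would receive zero weight and padded
   rows feed nothing downstream.
4. **Heads.** For masked-token pretraining, latent rows at masked positions
   go through a projection and softmax over the vocabulary (cross-entropy
   loss). For classification, the `[CLS]` row goes through a 2-unit dense
   layer and softmax; index 1 is the temperate probability. Temperate is the
   positive class everywhere, and a contig is called temperate when
   `p >= 0.5` (ties go to temperate, by convention).

Training is two-stage, both with Adam at learning rate 0.001: self-supervised
masked-token recovery over all genomes (5% of content tokens masked per
sentence, always replaced by `[MASK]`), then supervised fine-tuning on
lifestyle-labeled fragments. Cross-validated splits select the returned model:
lowest validation loss for pretraining, highest validation AUCROC for
fine-tuning.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `evalue_cutoff` | 1e-5 | alignment significance for a graph edge (conventional protein-search default) |
| `inflation` | 2.0 | MCL granularity; self-loops at each node's max incident weight, `tol` 1e-6, pruning 1e-8 |
| `d_model` | 512 (desk preset 64) | embedding width |
| `n_layers` / `n_heads` | 8 / 8 (desk 2 / 4) | encoder depth and heads |
| `ffn_dim` | 4 x d_model | FFN inner width (the original-transformer convention) |
| `max_len` | 300 | sentence length; 298 content tokens |
| `dropout` | 0.1 | sublayer dropout during training only |
| mask rate | 0.05 | per-content-token masking probability |
| augmentation grid | 100, 400, 800, 1200, 1800, 5000, 10000, 20000 bp | fragment lengths, 10,000 per class per length |

# Design choices where the design was open

* **E-value to weight.** MCL needs similarity weights; `-log10(evalue)` is
  the standard transform for alignment graphs. The floor at `1e-200` keeps
  zero e-values finite.
* **MCL hyperparameters** (inflation 2.0, per-node max self-loops, tol 1e-6)
  follow common protein-family protocol settings; the clustering is
  deterministic because nodes are sorted lexicographically before the matrix
  is built and all tie-breaks are lexicographic.
* **Unmatched proteins become `[UNK]`** rather than being dropped, so
  sentence length still reflects gene count and the position embedding keeps
  its meaning.
* **Token assignment against cluster representatives.** Queries are aligned
  to one representative per cluster (its lexicographically smallest member)
  rather than to every member; the representative is the cluster's proxy.
* **Post-norm blocks.** Layer normalization sits after each sublayer's
  residual addition (the original-transformer arrangement). A pre-norm
  reading is also defensible; post-norm was chosen and is tested as such.
* **Learnable position embeddings**, not sinusoidal: both embedding tables
  are listed among the learnable parameters of the model.
* **Masking is pure `[MASK]` replacement** — no 80/10/10 corruption mix. A
  deliberate simplification of standard BERT practice, matching the
  description of the pretraining task this package implements.
* **Cross-validation as model selection.** "k-fold" pretraining/fine-tuning
  is interpreted as k train/validation splits from which the single
  best-validated model is returned (lowest masked-token loss, respectively
  highest AUCROC).
* **Genome-level CV splits.** Fragments of one genome never straddle a
  train/validation boundary; fragment-level splitting would leak and inflate
  validation scores.
* **Checkpoints** are single-file RDS archives (config block + named
  tensors); save/load/forward reproduces predictions bitwise, and the test
  suite pins that contract.
* **Near-duplicate removal** for benchmark sets uses bottom-k k-mer sketches
  (k = 12, 32 hashes) with banded candidate lookup; a later fragment is
  dropped when sketch containment with an earlier-kept one exceeds 0.8.

# The synthetic universe

Tests and the acceptance script run on a seeded generator, never on
downloads. It emulates exactly the statistical structure the method relies
on:

* protein clusters as point-mutated copies (5% per residue) of random
  120-residue ancestors;
* genomes as ordered mosaics of back-translated genes (fixed codon table, one
  codon per amino acid, `TAA` stops, zero intergenic space), 12-20 genes per
  genome, 60 genomes per lifestyle;
* a planted lifestyle signal: 5 of 20 clusters are "markers" whose sampling
  probability is multiplied by 12 in temperate genomes. Under these defaults
  the Bayes accuracy of the optimal marker-count test is about 0.99, so a
  well-trained classifier can legitimately reach the >= 0.95 held-out
  accuracy the test suite demands — the signal strength was set by this
  likelihood-ratio computation, not by tuning against the classifier;
* alignment tables synthesized from the ground truth: within-cluster pairs
  get e-values of 10^-U(30,120) in both directions plus self hits,
  cross-cluster pairs are absent, and every genome gene hits its cluster
  representative. No aligner runs during tests.

What the generator does **not** emulate: sequence errors, host contamination,
codon usage, overlapping or strand-mixed genes, homology between clusters,
and real marker biology (integrases are a single family, not five). Passing
tests therefore demonstrate that the pipeline's machinery — clustering,
tokenization, optimization, selection, evaluation — is correct and that the
model recovers a planted compositional signal; they say nothing about
accuracy on real phage data, which depends on training corpora this package
does not ship.

# Problem sizes and numerical notes

All training tests run a desk-scale preset (d_model 32, 2 layers, 4 heads,
sentence length 16-32) chosen so the whole suite trains in minutes on one
CPU; the architecture is the same at every scale, and the full-scale preset
(512/8/8, length 300) differs only in dimensions. Typical suite sizes: 600
labeled fragments for planted-signal CV, 400 sentences for the bigram
masked-recovery check, 600 sentences for pretraining in the ablation.
Corpus-bookkeeping checks run at the full published scale (3,474 genomes;
160,000 augmented fragments; 4 x 80,000 benchmark fragments) because they are
sampling-only.

Degenerate inputs are contracts, not errors: a geneless contig encodes as
`[CLS][SEP]` and predicts as "unclassified" with NaN probabilities; an empty
alignment table gives an empty graph; an all-singleton clustering gives a
specials-only vocabulary with a warning; a sentence whose masking draw
selects nothing gets one forced mask so every example has a target.
Non-finite values in the encoder or a NaN training loss abort immediately.
AUC handles ties by grouping equal scores, which makes the trapezoidal value
equal the Mann-Whitney identity exactly (a tested invariant).

# Known limitations

* Training is plain R matrix arithmetic: fine for desk-scale studies and for
  verifying the method, not for corpus-scale pretraining.
* Gene calling fidelity is out of scope; tests use the precomputed-proteins
  path, and the prodigal backend is a thin subprocess wrapper.
* The dense MCL iteration targets vocabularies up to a few thousand proteins;
  the published-scale protein universe would need a sparse implementation.
* The ROC-comparison significance test reported alongside some published
  benchmarks is not implemented (the test is unnamed in the source
  material); a seeded bootstrap CI on an AUC difference would be the honest
  substitute if needed.
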