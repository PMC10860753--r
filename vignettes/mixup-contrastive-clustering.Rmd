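---
title: "Mixup-based sibling contrastive clustering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixup-based sibling contrastive clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixcc)
```

## The clustering problem

Short documents — a dozen tokens of a headline or a clinical one-liner —
carry too little co-occurrence signal for classical bag-of-words clustering,
and labels are usually absent. `mixcc` clusters such corpora by learning a
representation and a partition *jointly*: an instance-level contrastive loss
shapes the embedding space so that perturbed copies of the same document
coincide, while a deep-embedded-clustering head simultaneously sharpens
soft cluster assignments against learnable centroids. A mixup view enlarges
the set of contrastive samples within each mini-batch without any extra
text, which is what makes small-batch CPU training workable.

The number of clusters `K` is an input, as in the deep clustering
literature; the package does not attempt model selection over `K`.

## Pipeline

One optimizer step processes a mini-batch of `N` documents:

1. **Augmentation.** Two views per document: by default word deletion
   (each token dropped with probability 0.15) and character noise (each
   character substituted/deleted/extended with probability 0.10). Both obey
   a *keep-one* rule so no view is ever empty. A `mask_and_fill` augmenter
   accepts an injected token predictor — the package deliberately ships no
   pretrained language model, only the contract.
2. **Encoding.** A pluggable encoder maps token sequences to `N × d`
   embeddings. The built-in reference encoder is a feature-hashed token
   embedding table (default 1024 buckets, width 64) with mean pooling;
   hashing matters because character noise mints unseen tokens at every
   step, and a hashed table gives each of them a stable row with no
   vocabulary bookkeeping. Inputs are truncated to `max_len = 32` tokens.
3. **Mixup.** The virtual third view
   `e³ = λe + ((1−λ)/2)(e¹ + e²)` is a convex combination (coefficients sum
   to one); `λ = 0.8` by default, or one draw per batch from
   Beta(`beta_shape`, `beta_shape`).
4. **Contrastive head.** A two-layer ReLU perceptron (hidden width = `d`,
   output 128) projects the three views onto the unit sphere. The
   *sibling* loss scores each positive pair against denominator terms
   anchored at the pair's third view; classical two-sided InfoNCE is
   available as `variant = "infonce"`. The total is averaged over the three
   pairs and `N` documents (factor `1/(3N)`).
5. **Clustering head.** Student-t soft assignments `q` of each view against
   `K` centroids (degrees of freedom `df = 1`; 10 is the documented choice
   for biomedical-style corpora; as `df → ∞` the kernel tends to a
   Gaussian). The anchor's assignment is squared, frequency-normalized, and
   renormalized into the target `p`, and the mean KL divergence
   `KL(p ‖ q^view)` over the three views is the cluster loss.
6. **Update.** One Adam step on `instance + γ·cluster` (`γ = 10`), with the
   projection head and centroids at `5e-4` and the encoder at its own rate
   (below). Final assignments are the argmax of `q` on the anchor
   embeddings (`predict_mode = "argmax_q"`); a fresh seeded k-means on the
   final embeddings is available as `"kmeans_features"`.

## Design choices in detail

**Denominator conventions.** The printed form of both losses sums over all
`3N` similarity terms of the denominator anchor, including its self- and
same-document terms; this is `denominator = "literal_all"`, the default.
`"exclude_self"` removes only the self-similarity. `"exclude_siblings"`
removes all three same-document terms and keeps the positive-pair term
itself in the denominator, i.e. the positive against exactly `3N − 3`
cross-document negatives — the composition under which a perfectly
separated batch drives the loss to zero as `τ → 0`. All three are pinned
against a brute-force oracle in the tests.

**Stop-gradient on the target.** The sharpened target `p` is treated as a
constant within each step, the convention of the deep-embedded-clustering
lineage: letting gradients flow through the target rewards the model for
making its own target easier. The literal reading is available as
`grad_through_target = TRUE` and its full gradient is finite-difference
checked. Similarly, the batch frequencies `f_k` are computed within the
mini-batch, and the target is recomputed every step.

**Clustering-head variants.** `cluster_variant` selects the default
anchor-to-children loss, `self_paired` (each view sharpens its own target),
or `single_anchor` (KL on the anchor alone); these mirror the documented
head variants and make the comparison experiment reproducible.

**Encoder scale and learning rates.** The reference encoder's embedding
table is initialized standard normal, so document embeddings and their
pairwise distances are order-one — the geometry regime that the fixed head
learning rate (`5e-4`) and unit temperature scale assume. At a smaller
initialization scale the centroid updates are larger than the entire
cluster separation and the k-means initialization is destroyed rather than
refined. For the same reason the encoder learning rate resolves
automatically: user-supplied encoders (typically pretrained sentence
encoders being fine-tuned) default to `5e-6`, while the built-in
from-scratch table uses Adam's conventional `1e-3` — a fine-tuning rate
applied to random parameters trains nothing. Both can be overridden via
`lr_encoder`.

**Centroid initialization.** k-means++ seeding followed by Lloyd iterations
(≤ 300), restarted 10 times keeping the lowest within-cluster sum of
squares — the conventional k-means default. Single starts on
high-dimensional embeddings whose cluster structure occupies a small
subspace end in poor local optima often enough to matter. `K = 1` returns
the grand mean; `K = M` returns the points themselves; fewer than `K`
distinct points is an error naming the deficit.

**Numerical conventions.** All softmax-type quantities use log-sum-exp with
max subtraction (stable for similarities in `[−1, 1]` and `τ ≥ 1e-4`);
Student-t kernels are floored at `1e-300` before row normalization;
`0·log 0 = 0` throughout the KL and entropy arithmetic; a cluster with zero
soft frequency contributes zero to the sharpened target with a warning;
zero vectors reaching the projection head's normalization raise an error
naming the rows (they indicate degenerate parameters, not data). Argmax
ties in prediction break toward the lower cluster index. Natural logarithms
everywhere. Training aborts on a non-finite loss, reporting the iteration
and both components.

**Determinism.** Every stochastic routine takes an explicit seed and
restores the caller's RNG state. Documents are augmented under the sub-seed
`xor(seed, corpus index)`, so views do not depend on how the corpus was cut
into batches; epoch shuffles, Beta draws, and k-means restarts derive
separate streams from the run seed. Identical configuration and seed
reproduce the loss trace bit for bit on a single-threaded BLAS.

## The synthetic corpus generator

`synthetic_corpus()` draws a mixture-of-unigrams corpus: `K` topics with
disjoint vocabularies plus a shared vocabulary; each token of a
topic-`t` document comes from the shared pool with probability
`noise_rate`, otherwise uniformly from topic `t`'s vocabulary. The
defaults (50 topic words, 50 shared words, 12-token documents, 20% noise)
produce corpora that are separable by construction but not trivially so.

The generator emulates exactly one property of real short-text corpora —
topical vocabulary separation under noise — and none of the others: no
word order, no syntax, no polysemy, no Zipfian frequencies, no class
imbalance. Tests passing on it show that the optimization machinery
recovers recoverable structure; they do not show that the method reaches
any particular quality on real corpora, which depends mostly on the
encoder.

## Problem sizes

The test suite and the reproduction script run desk-scale configurations
chosen to exercise every code path with comfortable margins: the benchmark
study uses 4 topics × 50 documents, batch 32, 500 iterations, five seeds;
unit fixtures use batches of 2–8 documents in 2–16 dimensions, where every
loss is cross-checked against brute-force oracles and every gradient
against central finite differences.

## Limitations

* The reference encoder is a bag-of-hashed-tokens model: adequate for
  benchmarking the training machinery, far below a pretrained sentence
  encoder on real text. Real applications should supply an encoder through
  the `mcc_encoder()` contract.
* Self-training sharpens whatever the initialization believed: documents
  mis-assigned at k-means time near cluster boundaries can be locked in
  with high confidence rather than corrected.
* The joint objective's components are not on comparable scales; `γ`
  balances them and its useful range depends on the encoder's geometry.
* Mini-batch frequency normalization makes the target noisy for small
  batches and many clusters (`N` not ≫ `K`).
* Training cost grows as `O(N²)` per step from the `3N × 3N` similarity
  matrix; the design targets `N ≤ 400`.
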