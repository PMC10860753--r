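# mixcc

Unsupervised clustering of **short texts** — news headlines, search
snippets, tweet-length medical case notes — by jointly training a text
encoder, an instance-level contrastive head, and a deep embedded clustering
head, with a **mixup** view that enlarges the contrastive batch at almost no
cost. The package is aimed at practitioners who need to group a few hundred
to a few tens of thousands of short documents into a known number of topical
clusters without labels, on a single CPU.

## The model

Each mini-batch of `N` documents is augmented twice (word deletion and
character noise by default; a mask-and-fill predictor can be plugged in),
giving aligned views that are encoded to embeddings `e_i`, `e_i^1`, `e_i^2`.
A third, virtual view is built by representation-level mixup

    e_i^3 = λ e_i + (1-λ)/2 e_i^1 + (1-λ)/2 e_i^2,    λ = 0.8 by default,

so that three positive pairs per document — and `3N − 3` cross-index
negatives — are available to the contrastive loss. The three views are
projected by a two-layer perceptron onto the unit sphere and scored by a
temperature-scaled InfoNCE objective; in the default *sibling* variant the
denominator of the softmax for pair `(a, b)` is anchored at the third view
of the same document:

    ℓ_i^{a,b} = −log [ exp(s(z_i^a, z_i^b)/τ) / Σ_{j,k} exp(s(z_i^c, z_j^k)/τ) ].

In parallel, a clustering head measures each view against `K` learnable
centroids (initialized by k-means) with a Student-t kernel,

    q_ik ∝ (1 + ‖e_i − μ_k‖² / α)^{−(α+1)/2},

sharpens the anchor's assignment into a target
`p_ik ∝ q_ik² / f_k` (with `f_k = Σ_i q_ik`), and pulls the three augmented
views toward that target with a Kullback–Leibler loss. One Adam step per
batch minimizes

    L = L_instance + γ L_cluster,    γ = 10 by default.

Evaluation uses Hungarian-matched clustering accuracy (ACC) and normalized
mutual information (NMI).

## A worked example

A synthetic topic-separable corpus ships with the package, so the whole
pipeline runs without downloads:

```r
library(mixcc)

corpus <- synthetic_corpus(n_topics = 3, docs_per_topic = 30,
                           vocab_per_topic = 40, shared_vocab = 40,
                           doc_len = 10, noise_rate = 0.2, seed = 42)
fit <- mcc(corpus, k = 3,
           control = mcc_control(batch_size = 16, iterations = 300, seed = 1))
print(fit)
#> Mixup contrastive clustering fit: 90 documents, k = 3
#>   encoder: reference (hashed, 1024 buckets); sibling contrastive loss (tau = 0.5), gamma = 10
#>   300 iterations; final loss 3.3410 (instance 2.6401, cluster 0.0701)
#>   cluster sizes: 33 28 29
summary(fit)
#> Mixup contrastive clustering: 90 documents in k = 3 clusters
#>   cluster sizes: 33 28 29
#>   after 300 iterations: total 3.3410, instance 2.6401, cluster 0.0701
#>   against gold labels: ACC 0.9667, NMI 0.8800
```

`fitted(fit)` returns the named cluster assignments, `coef(fit)` the trained
centroids, `plot(fit)` the loss traces, and
`predict(fit, newdata, mode = "argmax_q")` assigns new documents. The
numbers above mean: 90 documents were grouped into three clusters of sizes
33/28/29, and the best one-to-one matching against the generating topics
labels 96.7% of documents correctly, with NMI 0.88 against the gold
partition.

Real corpora are read with `read_corpus()` (JSON lines with `id`, `text`,
optional `label`, or one document per line) and results written with
`write_results()`. A thin command-line interface
(`inst/cli/mcc.R`: `synth`, `train`, `eval`) wraps the same functions for
shell pipelines.

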