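# mdapred

Predicting miRNA–disease associations from multi-view similarity
networks with multi-order proximity features and attention-based
neighbor aggregation.

## The problem

Dysregulated microRNAs are implicated in many complex diseases, but
confirming an individual miRNA–disease association experimentally is
slow and expensive. Given a catalogue of known associations (a sparse
binary matrix `A`, nm miRNAs × nd diseases) plus similarity networks
over each node type, the goal is to score every unobserved pair so that
genuinely associated pairs rank highly — a bipartite link-prediction
problem for prioritising candidates ahead of wet-lab validation.

## The model

`mdapred` scores pairs with an end-to-end trained graph model built
from three ingredients:

1. **Similarity views.** Diseases: semantic similarity from MeSH-style
   descriptor DAGs (average of a depth-decay variant,
   `D_A(t) = delta^depth(t)`, and a frequency variant,
   `contribution(t) = -log(count(t)/nd)`, both normalised by shared
   ancestor contributions over total semantic value), plus a Gaussian
   interaction-profile (GIP) kernel
   `K(i,j) = exp(-gamma ||IP(i) - IP(j)||^2)` on the columns of `A`.
   miRNAs: best-match-average functional similarity over associated
   disease sets, plus the GIP kernel on the rows of `A`.
2. **Multi-order proximity features.** Each view is row-normalised and
   diffused by random walk with restart,
   `P_k = alpha P_{k-1} Ghat + (1 - alpha) I`, for `K` steps; each
   `P_k` becomes a shifted positive pointwise mutual information matrix
   `X_k = max(0, log2(P_k * total / (rowsum * colsum)))`. The `S*K`
   channels are fused by learned convolution filters (one length-n
   filter per output channel, summed over input channels) into a
   high-order representation, concatenated with the first-order views:
   `X~ = G1 || G2 || Xhat`.
3. **Attention with neural aggregation.** Per head, both node types are
   projected to a shared width; attention scores
   `e_ij = LeakyReLU(h_i h_j^T)` over the edges of the bipartite
   association network are softmax-normalised, and the aggregated
   neighbor representation `h_N = ELU(sum_j a_ij h_j)` is combined with
   the node's own features by two fully connected branches,
   `Z = [(h || h_N) W1 + b1] || [(h + h_N) W2 + b2]`. Heads are
   concatenated and pair scores decoded as
   `Ahat = sigmoid(Zm Zd^T)`, trained with balanced cross-entropy and
   Adam.

Evaluation uses balanced 5-fold cross-validation in which the GIP
kernels **and** the message-passing graph are recomputed from training
edges only, so no test pair can leak into training. Ablation variants
(`no_high_order`, `integrated_similarity`, `plain_gat`) and the two
case-study ranking protocols (novel candidates for a known disease;
fully held-out "new" disease) are built in, along with a synthetic
benchmark generator with planted block structure.

## Worked example

```r
library(mdapred)

d <- generate_dataset(synthetic_spec(nm = 40, nd = 40, rank = 4, seed = 42))
cfg <- model_config(C_out = 16, f_tran = 16, L = 2, epochs = 200,
                    learning_rate = 1e-3, seed = 42)
report <- run_cross_validation(d$A, d$mirna_functional, d$disease_semantic, cfg)
print(report)
```

```
Cross-validation metrics (5 folds)
 fold    auc   aupr autpr_at_k accuracy precision recall     f1
    1 0.7640 0.7360     0.6400   0.6923    0.7778 0.5385 0.6364
    2 0.8343 0.8157     0.6757   0.7821    0.8056 0.7436 0.7733
    3 0.8652 0.8532     0.6913   0.7308    0.8000 0.6154 0.6957
    4 0.7686 0.8037     0.6424   0.6795    0.6944 0.6410 0.6667
    5 0.7495 0.7600     0.6327   0.6795    0.7500 0.5385 0.6269
mean:
       auc       aupr autpr_at_k   accuracy  precision     recall         f1
    0.7963     0.7937     0.6564     0.7128     0.7656     0.6154     0.6798
```

Each fold holds out one fifth of the known associations plus an equal
number of sampled unknown pairs; `auc`/`aupr` summarise ranking quality
on those held-out pairs, `autpr_at_k` is the normalised area under the
fraction-of-positives-recovered-in-the-top-k curve, and the threshold
metrics use a 0.5 cutoff. On this 40×40 planted-block instance the
model recovers the block signal well above chance (AUC 0.80 versus 0.5
for random scoring).

Ranking novel candidate miRNAs for one disease:

```r
case_study_novel(d$A, "disease-007", d$mirna_functional,
                 d$disease_semantic, cfg, top_n = 5)
```

```
 rank   mirna        score
    1 mir-027 0.9999993375
    2 mir-035 0.9999979618
    3 mir-019 0.9917573234
    4 mir-016 0.3009066901
    5 mir-032 0.0007724039
```

Scores are decoder probabilities for the disease's currently unknown
pairs, ranked descending; with the generator's ground truth in hand one
can check that top candidates fall in the disease's latent block.

Real data go through the same interface: a two-column TSV of known
pairs, a descriptor-DAG file, and optionally a precomputed miRNA
functional-similarity TSV (see `?load_associations`,
`?load_disease_dags`, `?run_config`). A shell entry point wrapping the
pipeline commands lives at `inst/cli/mdapred.R`
(`similarity | cv | case-study | synthetic | train | predict`).

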