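---
title: "Capsule-network text matching: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsule-network text matching: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capstm)
```

## The task and the model

Text matching here is binary classification: given two short questions,
predict 1 if they carry the same intent and 0 otherwise. The motivating
application is Chinese medical question matching, where questions are short,
unsegmented, and best handled at the character level.

`capstm` implements a five-layer siamese matcher. Both questions are padded
to one shared length `n` and pass through the *same* parameters at every
stage; only the fusion step is asymmetric (the signed difference block), so
the model is deliberately not input-symmetric.

**Input layer.** Token embeddings (trainable, or loaded from a word2vec-format
file) pass through a highway transform
\[
\hat e = \tanh(W_f e + b_f),\qquad
g = \sigma(W_g \hat e + b_g),\qquad
e' = g \odot \hat e + (1-g) \odot e .
\]
The gate lets each dimension interpolate between the raw embedding and a
learned nonlinear recombination. We initialise \(b_g = -1\) so training
starts near the carry (identity) path, the usual stabilising choice for
highway layers.

**Representation layer.** A BiLSTM produces per-token states \(h_k\)
(forward and backward halves concatenated, dimension \(2H\)). In parallel,
the attention interaction matrix \(sim_{ks} = \langle e'_{1k}, e'_{2s}\rangle\)
is normalised into weights and used to build cross-question attended
vectors: position `k` of question 1 receives
\(\hat a_{1k} = \sum_s a_{ks}\, e'_{2s}\), and the column-direction
normalisation of the same matrix gives \(\hat a_{2k}\). Two readings of the
representation exist in the literature this architecture belongs to: the
per-token hidden sequence, or only the final hidden states. We use the
per-token sequence, because the downstream aggregation BiLSTM and the
token-axis convolution both require position-wise inputs — a single sentence
vector would make them degenerate.

**Aggregation layer.** A second BiLSTM over \(c_k = [h_k : \hat a_k]\)
(encoder block first, fixed order) yields the aggregated sequence `S`.

**Capsule layer.** `I` convolution kernels of width 3 (same-padding) slide
over the token axis; masked positions are excluded outright from the
max-over-time that turns each kernel's output into one channel vector
\(u_i\). Capsule kernels then produce prediction vectors
\(\hat u_{i|j} = g(K_j u_i + b) \in \mathbb R^d\) with a bias shared across
capsules. Dynamic routing iterates \(T\) times:
couplings \(c_{i|j} = \mathrm{softmax}_j(b_{i|j})\) (so iteration 1 couples
uniformly at \(1/J\)), sums \(s_j = \sum_i c_{i|j}\hat u_{i|j}\), outputs
\(d_j = \mathrm{Squash}(s_j)\), and the logit update
\(b_{i|j} \mathrel{+}= \langle d_j, \hat u_{i|j}\rangle\). The softmax runs
over the *output-capsule* axis for each input channel, the convention of the
original routing-by-agreement procedure, which is also the only axis under
which \(\sum_i c_{i|j}\hat u_{i|j}\) is well-formed here.

**Squash.** The default squash is
\[
\mathrm{Squash}(s) = \frac{\|s\|^2}{1+\|s\|}\cdot\frac{s}{\|s\|^2}
 \;=\; \frac{s}{1+\|s\|},
\]
whose output norm is exactly \(\|s\|/(1+\|s\|) < 1\). This differs from the
canonical capsule squash \(s\|s\|/(1+\|s\|^2)\); because the two genuinely
disagree (the first is linear near the origin, the second quadratic) and
either may be intended in practice, both are implemented and selected by
`squash_variant`; the printed-style form is the default and neither is
asserted as the "true" one. Both fix 0 and bound every output capsule's norm
below 1 — properties the tests assert.

**Prediction layer.** With \(C_i\) the flattened \(J \times d\) capsule block
of sentence `i`, the head consumes
\(C = [C_1, C_2, C_1 - C_2, \cos(C_1, C_2)]\) (length \(3Jd + 1\); the
cosine of a zero vector is defined as 0), one hidden layer with the
configured activation, then a single sigmoid unit. Training minimises mean
binary cross-entropy with probabilities clipped to \([10^{-7}, 1-10^{-7}]\).
The decision threshold is fixed at 0.5.

## Parameters that matter

| Parameter | Default (full / small preset) | Meaning |
|---|---|---|
| `embedding_size` | 300 or 768 / 32 | token vector dimension `E` |
| `hidden_size` | 100 or 384 / 32 | BiLSTM units per direction `H` |
| `n_capsules`, `capsule_dim` | 6, 50 / 4, 16 | output capsules `J`, dimension `d` |
| `routing_iters` | 3 | routing iterations `T` |
| `conv_channels`, `conv_width`, `conv_dim` | 16, 3, H / 8, 3, 16 | capsule conv front end |
| `learning_rate`, `batch_size` | 0.001, 32 | Adam step and mini-batch size |
| `dropout_rate` | 0.5 (word2vec), 0.9 (contextual), 0.1 (small) | drop probability |
| `max_len` | 50 / 16 | shared padded length `n` |

Sizes without an established published value — the convolution kernel count,
width and per-channel feature dimension, the head width (100), and `max_len`
(50) — are package choices recorded here, configurable in `capstm_config()`.
`dropout_rate` is interpreted as the probability of *dropping* a unit
(applied to embeddings and both BiLSTM outputs, training only). A drop rate
of 0.9 is aggressive; older frameworks parameterised the same layer by
keep-probability, and the contextual preset keeps the printed value while
making the interpretation explicit here.

Two further switches exist because the underlying formulation is ambiguous:

* `norm_mode` — attention weights via masked softmax (default; numerically
  safe) or the literal ratio \(sim_{ks}/\sum_s sim_{ks}\), which is faithful
  to the ratio formulation but undefined for non-positive sums: the package
  errors in that case (directing the user to softmax mode) and treats an
  all-zero slice as vacuous, assigning zero weight.
* `similarity_source` — the similarity matrix is computed on highway outputs
  `e'` (default) or on hidden states `h`, the variant familiar from
  ESIM-style matchers.

## The synthetic corpus generator

The corpora this architecture targets are private clinical question sets, so
the package generates its own study conditions. `synth_config()` defaults
emulate the published class balance: positive fraction 0.39 (12,610 positive
vs 19,750 negative training pairs in the reference corpus), one shared
fraction for train/dev/test. Questions are length-10 strings of single
CJK-range characters (so character tokenization applies unchanged) built
from:

* `n_topics` (8) topic templates over 4 sentence frames, each with one
  topic-marker slot, three content slots and filler slots;
* a vocabulary (80 tokens) partitioned into topic markers, per-topic content
  synonym pairs and shared filler synonym pairs. Every substitutable token
  is drawn uniformly from its synonym pair wherever it occurs, so token
  identity alone carries no label signal;
* positives: same topic and frame, second question derived by per-token
  synonym substitution at rate `paraphrase_ops` (0.2) plus one adjacent swap
  at the same rate — rate 0 makes positives verbatim-identical;
* negatives: different topics; half are *hard negatives* that keep the frame
  and fillers and swap only the marker and content tokens, so the pair
  differs in at most 4 positions — exactly the topic-confusion case that
  makes matching hard;
* exact class counts per split (`round(fraction * n)`), split sizes 80/10/10
  by default, and full reproducibility from `seed`.

A design note: an early version of the generator drew sentences only from
the first member of each synonym pair, which made "contains a second-member
token" a perfect positive indicator — a label leak that a matcher can
exploit without comparing the questions at all (and that caps recall at the
substitution rate). The uniform-draw rule above removes it; the test suite
guards the intended difficulty by checking that a linear bag-of-tokens
classifier still solves the task (the floor) while identical pairs and
hard negatives are classified through cross-question comparison.

What the generator does **not** emulate: natural length variation, realistic
token frequency distributions (Zipfian vocabulary), annotator noise, or any
medical semantics. Passing the training contracts therefore shows that the
implementation can learn a compositional matching rule with hard negatives —
it says nothing about clinical-domain performance.

## Numerical choices

* **Masking and padding invariance.** LSTM states carry through padded
  positions unchanged and outputs are zeroed there; attention masks padded
  targets to zero weight; the convolutional max runs over valid positions
  only. Consequence (asserted to \(10^{-6}\)): appending padding to both
  questions never changes the output probability.
* **Routing backward pass.** Training differentiates *through* the unrolled
  routing iterations (not just the final couplings); the tests check the
  analytic gradient against central finite differences to relative error
  \(10^{-4}\).
* **Squash at the origin.** Both variants return 0 at 0; the printed
  variant's Jacobian tends to the identity there, the standard variant's to
  zero — both handled explicitly with an \(10^{-12}\) norm guard.
* **Max-over-time ties** route the gradient to the earliest maximising
  position.
* **Pooling ablations** (max/mean over channels) are followed by the same
  squash so ablated outputs live on the same norm scale as routed capsules.
* **Optimizer.** Only the learning rate (0.001) has an established value;
  the optimizer family does not, and Adam
  (\(\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}\)) is the de-facto
  standard choice. Early stopping (patience 5, max 50 epochs by default) is
  a package addition; the retained checkpoint maximises dev F with earliest-
  epoch ties.
* **Determinism.** All randomness (corpus, initialisation, shuffling,
  dropout) flows from configuration seeds; fitting twice with one seed gives
  bit-identical histories.

## Problem sizes used in tests

Layer-level checks run on tiny tensors (dimensions 2–6) against scalar-loop
re-implementations. The training contracts run at sizes chosen for a
single-CPU desk machine: an overfitting check (64 training pairs, reduced
model `H=16, J=4, d=8, T=3, n=12`, up to 100 epochs, training F ≥ 0.95) and
a generalization check (2000/400/400 pairs at positive fraction 0.39, the
`small` preset, test F ≥ 0.90, all three ablations trained to completion).
At these conditions the full model typically reaches test F ≈ 0.98–1.00 and
the ablations similar values — the synthetic task, once learned, is solved
almost perfectly, so ablation gaps are compressed relative to what noisy
real corpora show; we assert only that attention does not hurt on the
hard-negative slice, not a strict margin.

## Known limitations

* No GPU or parallelism; the full-size presets (E=300/768) train slowly in
  base R and are provided for completeness and for loading real pretrained
  vectors, not for large-corpus training.
* Contextual (768-dim) vectors are consumed as a static per-token file in
  word2vec text format; running a transformer to produce them is out of
  scope.
* Single capsule layer, sigmoid cross-entropy only — no margin loss,
  reconstruction regulariser, multi-layer capsule stacks or EM routing.
* Character tokenization or whitespace splitting only; no word segmentation
  or subword models.
* The comparison baselines of the matching literature (ESIM, ABCNN, BIMPM,
  DISAN, DRCN, DECOMP, BERT) are not re-implemented.
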