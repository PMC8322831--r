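# capstm

Capsule-network text matching for short question pairs.

`capstm` decides whether two short questions — typically unsegmented,
character-tokenized Chinese medical questions — ask the same thing. It
implements a five-layer siamese architecture in which the usual pooled
sentence vector is replaced by a set of *capsules*: vector-valued feature
units whose norm encodes activation strength and whose agreement is
negotiated by iterative dynamic routing. The package is aimed at NLP
practitioners who want a trainable, inspectable reference implementation of
capsule-based sentence-pair matching that runs on one CPU, with no deep
learning framework behind it: every layer and its analytic gradient is
written in vectorized base R and checked against finite differences and
scalar-loop oracles in the test suite.

## The model

Given questions `s1`, `s2` padded to a shared length `n`, with token
embeddings `e1`, `e2`:

1. **Input layer** — a highway transform gates each embedding between a
   nonlinear branch and the raw vector:
   `ê = tanh(W_f e + b_f)`, `g = sigmoid(W_g ê + b_g)`,
   `e' = g ⊙ ê + (1 − g) ⊙ e`.
2. **Representation layer** — a BiLSTM gives per-token states
   `h_k`; simultaneously an attention interaction matrix
   `sim_ks = ⟨e'_1k, e'_2s⟩` is normalized (masked softmax by default; the
   literal ratio `sim_ks / Σ_s sim_ks` is available) into weights building
   attended vectors `â_1k = Σ_s a_ks e'_2s` and, by column-direction
   normalization, `â_2k`.
3. **Aggregation layer** — a second BiLSTM over the concatenation
   `c_k = [h_k : â_k]`.
4. **Capsule layer** — `I` width-3 convolution kernels with max-over-time
   produce channel vectors `u_i`; capsule kernels map each channel to
   prediction vectors `û_{i|j} = g(K_j u_i + b)`; dynamic routing
   (couplings `c_{i|j} = softmax_j(b_{i|j})`, sums
   `s_j = Σ_i c_{i|j} û_{i|j}`, outputs `d_j = Squash(s_j)`, logit update
   `b_{i|j} += ⟨d_j, û_{i|j}⟩`, `T` iterations) yields `J` output capsules
   per sentence. The squash used is `s/(1 + ‖s‖)`; the canonical
   `s‖s‖/(1 + ‖s‖²)` is available as `squash_variant = "standard"`.
5. **Prediction layer** — the fusion vector
   `C = [C_1, C_2, C_1 − C_2, cos(C_1, C_2)]` feeds a one-hidden-layer
   sigmoid head trained with binary cross-entropy.

Ablations ship as first-class variants: routing replaced by max or mean
pooling over channels, and the attention branch removed
(`ablation_variants()`).

Because the corpora this architecture was designed for are private, the
package includes a seeded synthetic question-pair generator
(`generate_corpus()`): topic templates over single CJK characters, positive
pairs made by synonym substitution and local token swaps, and *hard
negatives* that keep the sentence frame while swapping only the
topic-defining tokens, at a configurable positive fraction (default 0.39).

## Worked example

```r
library(capstm)

corpus <- generate_corpus(synth_config(n_pairs = 1500, seed = 42))
corpus
#> <synth_corpus> train=1200 dev=150 test=150, positive_fraction=0.39, seed=42

corpus$train[1:3, c("text_a", "text_b", "label")]
#> # A tibble: 3 × 3
#>   text_a               text_b               label
#>   <chr>                <chr>                <int>
#> 1 丂乊丽丰丐乇乀丒丮丒 丂乊丽丱丐乇乀丒丮专     1
#> 2 丅乎丬丝乊乍丟丟乄丿 一乎丬下乊乍丈丈乄丿     0
#> 3 乃丌丨不乌丼乎不乊丁 乃丝丨丝乌丼乎东乊丅     0

fit <- capstm_fit(corpus$train, corpus$dev,
                  capstm_config("small", max_epochs = 20, patience = 5,
                                seed = 1))
fit
#> <capstm_model> preset small | 14 epochs trained, best epoch 9 (dev F 1.000)

capstm_evaluate(fit, corpus$test)
#> # A tibble: 1 × 7
#>   precision recall f_score    tp    fp    fn    tn
#>       <dbl>  <dbl>   <dbl> <int> <int> <int> <int>
#> 1     0.967      1   0.983    58     2     0    90
```

The fitted model holds the checkpoint with the best dev F-score (here
epoch 9). `capstm_evaluate()` scores held-out pairs at threshold 0.5 over
the positive (match) class: of 60 true matches all 58 predicted matches are
correct except 2 false positives, giving precision 0.967, recall 1 and
F 0.983.

Attention matrices for any pair can be exported or plotted:

```r
att <- capstm_attention(fit, "丄乌丵乇丛丱丨丛乄丛", "丄乍丵乇业丰丨业久业")
att
#> <capstm_attention> 10 x 10 tokens, match probability 0.916
# rows sum to 1 over the second question's (unpadded) tokens
write_attention(att, "att.tsv")  # TSV with token header row/column
autoplot(att)                    # ggplot2 heatmap
```

Training curves: `tidy(fit)` (one row per epoch), `glance(fit)` (one-row
summary), `autoplot(fit)`.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "capstm", package = "capstm"))')
$CLI synth --config synth.yaml --out data/ --seed 7
$CLI train --config cfg.yaml --train data/train.tsv --dev data/dev.tsv --out run/
$CLI eval  --checkpoint run/ --data data/test.tsv --report report.json
$CLI predict --checkpoint run/ --data pairs.tsv --out preds.tsv
$CLI attention --checkpoint run/ --text-a "..." --text-b "..." --out att.tsv
```

Full-size configuration presets for 300-dim word2vec and 768-dim
contextual vectors ship as YAML in `inst/extdata/`; pretrained vectors are
consumed in the word2vec text format via `capstm_fit(..., vectors = path)`.

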