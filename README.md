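# lnccnn

Classify transcripts as **long non-coding RNA (lncRNA)** or
**protein-coding transcript (mRNA)** directly from nucleotide sequence,
and explain every call.

Most coding-potential tools work from hand-crafted features (ORF length,
hexamer bias, Fickett score). `lnccnn` instead trains a one-dimensional
convolutional network on one-hot encoded sequence — channels (A, C, G, T),
inputs padded to a fixed length — and then attributes each prediction back
to the nucleotides that caused it, so a call like "this transcript is
coding" comes with the sequence regions that drove it.

The network is `3 × [conv1d(k = 57, s = 1) → ReLU → maxpool(2) → dropout]
→ dense(256) → dense(256) → softmax(2)`, trained with SGD (momentum 0.9,
lr 0.01) on two-class cross-entropy, lncRNA positive. Explanations are
additive attributions with respect to a background set of reference
sequences: multipliers propagate backwards through the network (exact
through linear layers, rescale rule through ReLU and the two-class
softmax, delta-conserving splits through max-pool), are averaged over the
background, and satisfy local accuracy

    Σ_ij φ_ij + E_background[f] = p_lncRNA(x)

to machine precision. Per-channel values are collapsed to one value per
nucleotide, summed into codons in all three reading frames (blue = towards
lncRNA, red = towards mRNA), and summarised as mean |attribution| per
k-mer. A synthetic-transcript generator (ORF structure with a planted,
coordinate-annotated motif vs i.i.d. background sequence) provides ground
truth for testing the whole loop, and an evaluation module covers
confusion metrics, ROC/AUC and accuracy by length bin.

## Worked example

Simulate transcripts whose mRNA-like class carries a 57-nt planted motif
inside the ORF, train the desk-scale profile, and check that the model
both classifies held-out sequences and localises the motif:

```r
library(lnccnn)

spec  <- synthetic_spec(n_per_class = 200, length_range = c(200, 600),
                        motif = default_motif(), motif_rate = 1, seed = 11)
sim   <- generate_transcripts(spec)
split <- stratified_split(sim$records, test_fraction = 0.2, seed = 12)

config    <- scaled_model_config(seed = 13)
enc_train <- encode_dataset(split$train, config$input_length)
enc_test  <- encode_dataset(split$test,  config$input_length)
model     <- train_model(build_model(config), enc_train)   # ~4 min, 1 CPU

preds <- predict(model, enc_test)
mean(preds$predicted_label == split$test$label)   # 1
roc_auc(preds$p_lncRNA, split$test$label)$auc     # 1

bg   <- select_background(enc_train, n_per_class = 20, seed = 14)
expl <- compute_shap(model, bg, enc_test)
max(abs(vapply(expl$explanations, `[[`, 1, "additivity_error")))
# 2.1e-16  — attributions + base value equal the model output exactly
```

With `motif_rate = 1`, the mean |codon attribution| inside the annotated
motif exceeded the outside mean for 40 of 40 held-out mRNA-like sequences
in this run. `plot_attribution(collapse_to_nucleotide(expl$explanations[[1]]))`
renders the three-frame colour track for a single transcript.

The evaluation module reproduces published benchmark arithmetic from raw
confusion counts:

```r
metrics(confusion_counts(TP = 20895, FP = 1204, TN = 14087, FN = 821))
#  accuracy sensitivity specificity precision    f1 auc
#     94.53       96.22       92.13     94.55 95.38  NA
```

## Command line

A thin wrapper over the same functions covers the whole workflow
(`simulate`, `preprocess`, `train`, `predict`, `explain`, `evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lnccnn.R",package="lnccnn"))')" \
    simulate --n-per-class 50 --seed 1 --out sim/
```

Each stage writes a `provenance.json` (resolved config, config hash, seed,
package version) next to its outputs; one global `--seed` fans out to
per-stage seeds.

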