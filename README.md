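# epiattn

Sequence-only prediction of enhancer–promoter interactions (EPIs), with an
interpretability pipeline that reads the model's attention back out as
motifs and transcription-factor (TF) interaction candidates.

## The problem

Whether a distal enhancer regulates a given promoter is cell-type specific
and expensive to measure (Hi-C, ChIA-PET). A useful computational surrogate
is a classifier that scores an (enhancer, promoter) pair of DNA sequences —
here 3000 bp and 2000 bp windows — for interaction. Beyond the score
itself, biologists want to know *which sequence elements* drive a predicted
interaction: that is what the attention-based interpretation in this
package provides, exporting candidate motifs in MEME format for TOMTOM and
annotating TF–TF pairs against BioGRID.

## The model

Each branch is encoded through a frozen one-hot lookup (`N` → zero row) and
convolved/pooled into a feature map:

    Eo = MaxPool(Conv(Embed(E)))        # 3000 bp -> 148 x 128
    Po = MaxPool(Conv(Embed(P)))        # 2000 bp ->  98 x 128
    M  = [Eo; Po]                       # 246 x 128, enhancer rows first

with 128 filters of width 40, pooling 20/20. One transformer block
(16-head scaled dot-product self-attention, feed-forward 255→128,
post-layer-norm residuals) yields `H = TransformerBlock(M)`; a hierarchical
attention layer pools positions,

    alpha_i = softmax_i( tanh(W_h h_i + b_h)^T u_c ),   S = sum_i alpha_i h_i,

and a sigmoid neuron on `S` outputs the interaction probability. Training
uses Adam on (optionally class-weighted) cross-entropy; the 1:20 class
imbalance of the benchmark design is addressed either by 10–50 bp shift
augmentation of positives or by balanced inverse-frequency class weights.
Performance is reported as AUROC and AUPR (the imbalance-sensitive
headline metric).

Each of the 246 merged positions has a 59-bp receptive field
(`[20r, 20r + 59)`), so every entry of a 246 × 246 attention map links two
concrete sequence windows. The interpretation pipeline captures per-head
attention on positive test samples, averages heads, ranks the
enhancer × promoter cross-blocks, extracts a position weight matrix for
each implicated region from maximally-activating convolution windows, and
joins TOMTOM motif hits (E < 0.07, p < 1e-4) and BioGRID evidence into a
TF-interaction table.

The neural network (forward, backward, Adam) is implemented in the package
itself with RcppArmadillo kernels for the hot loops; a finite-difference
gradient check in the test suite pins its correctness.

## Worked example

A synthetic dataset with a planted, interacting 8-mer pair stands in for
the real benchmark, so the whole pipeline is runnable in minutes on a
laptop. Positives carry one instance of each motif; in `"decoy"` mode half
of the negatives carry exactly one of the two motifs, so the classifier
must learn the *pairing*, not mere motif presence.

```r
library(epiattn)

cfg <- model_config(enh_len = 300, prom_len = 200, conv_filters = 16,
                    conv_kernel = 8, pool_size = 4, pool_stride = 4,
                    n_heads = 4, ffn_dense1 = 32, dropout = 0,
                    batch_size = 32, learning_rate = 0.01)

ds <- generate_dataset(500, 5, enh_len = 300, prom_len = 200,
                       enh_motif  = planted_motif("enh8",  "TGACGTCA", 0.05),
                       prom_motif = planted_motif("prom8", "CACGTGAC", 0.05),
                       seed = 101, negative_mode = "decoy")
sp <- split_records(ds$records, seed = 101)

model <- train_model(build_model(cfg, seed = 101), sp$train, sp$val,
                     mode = "augment", max_epochs = 15, patience = 15,
                     n_starts = 2, burn_in = 4, seed = 101)
ev <- evaluate_predictions(predict(model, sp$test), sp$test$label)
cat(sprintf("test AUROC %.3f, AUPR %.3f\n", ev$auroc, ev$aupr))
#> test AUROC 0.969, AUPR 0.909

# read the attention back: top region pairs for one positive test sample
pos1 <- sp$test[sp$test$label == 1, ][1, ]
avg  <- average_heads(capture_attention(model, pos1))
head(top_region_pairs(avg, cfg, k = 5), 3)
#>   enh_region prom_region merged_enh merged_prom     score
#> 1         61          42         61         115 0.3400914
#> 2         71          42         71         115 0.2673085
#> 3         54          42         54         115 0.2186939

# this sample's ground truth: enhancer plant at 244, promoter plant at 169
region_window(61, cfg)[c("start", "end")]    # enhancer window [244, 255)
region_window(115, cfg)[c("start", "end")]   # promoter window [168, 179)
extract_region_pwm(model, pos1, 61)
#> Region PWM enh_r61 (merged index 61, enhancer): 8 bp from 1 sequences
#>   consensus of frequencies: TGACGTCA
```

The test AUROC of 0.969 exceeds the 0.75 ceiling of a single-motif
detector under decoy negatives, showing the pairing was learned; the
top-ranked region pair points at this sample's planted windows exactly
(enhancer motif planted at 244, promoter motif at 169), and the PWM
extracted at the implicated enhancer region reads back the planted
consensus `TGACGTCA` (column-wise correlation 1.0 with the true motif PWM).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/epiattn.R gen-data --n-pos 500 --neg-per-pos 5 --seed 1 --out data/
Rscript inst/cli/epiattn.R train --data data/pairs.tsv --seed 1 --out run/
Rscript inst/cli/epiattn.R evaluate --model run/model.rds --data data/pairs.tsv --out run/
Rscript inst/cli/epiattn.R interpret --model run/model.rds --data data/pairs.tsv --top-k 8 --out run/
```

Every CLI run writes a `run_manifest.json` (config, seeds, input checksums,
timings) sufficient to reproduce it.

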