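# crisprot

Sequence-only prediction of CRISPR-Cas9 off-target propensity. Given a
guide RNA (sgRNA) and a candidate genomic site — a pair of 23-nt sequences
(20-nt protospacer + NGG PAM) differing by 1–5 mismatches — `crisprot`
scores how likely, and how strongly, Cas9 cleaves that site. It is written
for people benchmarking off-target predictors or building guide-design
pipelines who want a self-contained, inspectable implementation that runs
at desk scale on one core.

## The model

Each aligned position of a pair is one of 4 × 4 = 16 ordered base
combinations, so a pair becomes a length-23 token vector
(`token(r, d) = 4·ord(r) + ord(d)`, A=0 C=1 G=2 T=3). Token vectors are
embedded with GloVe trained on the paired-sequence corpus itself, by
weighted least squares on log co-occurrences:

    J = Σ_{x_ij>0} f(x_ij) (w_i'c_j + b_i + b̃_j − log x_ij)²,
    f(x) = min{(x/x_max)^α, 1}

The classifier stacks: embedding (16 × 100, GloVe-initialised) →
bidirectional LSTM (standard f/i/C̃/o gates per direction, outputs combined
as y = tanh(V·A + V′·A′)) → five 1-D convolutions → dense(20) → dense(2) →
softmax, with batch normalization and dropout (0.3) between stages; the
regression head ends in dense(1)/sigmoid and predicts cleavage frequency.
Training uses Adam (lr 0.01, batch parameter m = 256) with an
imbalance-aware sampler: each epoch the M negatives are shuffled and cut
into N = ⌊M/m⌋ disjoint subsets of m, each joined by m positives drawn
with replacement. Ablation variants (`no_lstm`, `conv_lstm`,
`no_batchnorm`, `no_dropout`) are built from the same spec for structural
comparison. A multiplicative CFD (Cutting Frequency Determination)
baseline — product of one per-mismatch table score over the protospacer —
and a synthetic dataset generator with a planted multiplicative signal
complete the pipeline. Details and design rationale are in
`vignettes/offtarget-model.Rmd`.

## Worked example

```r
library(crisprot)

d <- simulate_offtarget_dataset(n_sgrnas = 4, sites_per_sgrna = 400,
                                imbalance_ratio = 25, seed = 42)
table(d$label)
#>    0    1
#> 1540   60

sp  <- split_train_test(d, 0.2, seed = 42)
fit <- otnet(sp$train, epochs = 5, m = 64, seed = 42,
             validation_fraction = 0)
fit
#> Off-target propensity network (variant 'full', classification head)
#>   trained on 1280 pairs (43 positive, 4 sgRNAs)
#>   123612 parameters; stages: embedding > bilstm > batchnorm > dropout > conv > ...
#>   final training loss 0.0483 over 95 batches

scores <- predict(fit, sp$test)
evaluate_predictions(sp$test$label, scores, sp$test$frequency)
#> recall 1.000 | auROC 1.000 | auPRC 1.000 | pearson 0.952 | spearman 0.389 (n+ 17, n- 303)
```

The report reads: every one of the 17 held-out planted off-target sites is
recovered at the 0.5 threshold (recall), ranking separates the classes
perfectly on this easy 320-pair test set (auROC/auPRC), predicted
probabilities track planted cleavage frequencies linearly (Pearson), and
the Spearman value is low because 303 of 320 true frequencies are
tied at zero — the expected behaviour under heavy imbalance.

The CFD baseline reproduces its textbook arithmetic — a pair whose only
mismatches are rG-dA at protospacer position 6 (score 0.67) and rC-dT at
position 10 (score 0.87) multiplies out to:

```r
tab <- load_cfd_table(system.file("extdata", "cfd_example_table.tsv",
                                  package = "crisprot"))
cfd_score(paste0(c(rep("A",5),"G",rep("A",3),"C",rep("A",10),"TGG"), collapse=""),
          paste0(c(rep("A",5),"A",rep("A",3),"T",rep("A",10),"TGG"), collapse=""),
          tab)
#> [1] 0.5829
```

A command-line wrapper over the same functions lives at
`inst/scripts/crisprot-cli.R` (subcommands `simulate`, `encode`,
`fit-embedding`, `train`, `predict`, `evaluate`, `loso`, `score-cfd`).

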