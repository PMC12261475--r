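# amyloscan

Proteome-scale detection of **amyloid signaling motifs (ASMs)** — short
(~11–40 residue) segments that seed a self-propagating cross-β amyloid fold
used for signal transduction between Nod-like receptors (NLRs) and their
effector proteins in bacteria and fungi. ASM families are short, degenerate
and diverse beyond recognizable homology, which defeats alignment-based
profile searches; `amyloscan` instead trains a discriminative model of
generalized ASMs and scans sequences with it.

The package is aimed at computational biologists who want to (i) train a
motif detector from a set of motif positives and background negatives,
(ii) scan FASTA files and obtain per-sequence detection scores with
best-window localization, (iii) evaluate detectors with the metrics used
for highly imbalanced motif retrieval, and (iv) inspect what the model
learned via penultimate-layer embeddings.

## The model

The core is a deliberately lightweight bidirectional LSTM over fixed
40-residue windows:

```
tokens (40) → embedding ℝ^8 → dropout 10%
            → BiLSTM, 8 units/direction, final states concatenated (ℝ^16)
            → dropout 10%
            → LSTM, 4 units (ℝ^4)
            → dropout 10%
            → dense sigmoid → P(window contains an ASM)
```

With one bias per gate the trainable-parameter total is

  V·d + 2·[4·u₁(d+u₁+1)] + 4·u₂(2·u₁+u₂+1) + (u₂+1) = **1,637**

for the default (V, d, u₁, u₂) = (26, 8, 8, 4); this count is enforced as a
contract between the closed form and the tensors actually allocated.
Training positives shorter than 40 residues are prepadded with random
Swiss-Prot-frequency residues; scan inputs shorter than 40 are
zero-postpadded (PAD positions are masked in the recurrent layers). Longer
sequences are scanned with a window of size 40 and step 1; a 6-fold
cross-validation ensemble averages per-window probabilities and the
per-sequence score is the maximum window mean (max-pooling).

Forward pass, backpropagation through time and the Adam loop are
implemented in RcppArmadillo inside the package; gradients are verified
against finite differences in the test suite.

## Worked example

Train on a bundled synthetic benchmark (8 motif families with conserved
anchor positions over Swiss-Prot background, 20,000 background negatives)
and scan held-out domains:

```r
library(amyloscan)

bench <- generate_benchmark(synthetic_benchmark_config(seed = 1))
ens <- asm_train(bench$train_pos, bench$train_neg, k = 6,
                 train_config = train_config(epochs = 10, seed = 7))
glance(ens)
#> # A tibble: 1 × 5
#>       k n_params epochs mean_val_loss sd_val_loss
#>   <int>    <int>  <int>         <dbl>       <dbl>
#> 1     6     1637     10         0.104     0.00799
```

`n_params` is the 1,637-weight architecture above; `mean_val_loss` is the
final-epoch binary cross-entropy averaged over the six validation folds.
Now scan domain-embedded motifs against motif-free background domains:

```r
hits <- scan_sequences(ens, bench$test_same_dom)    # 320 domains with motifs
negs <- scan_sequences(ens, bench$domain_neg)       # 200 background domains
evaluate_scores(hits$max_prob, negs$max_prob, fpr_targets = c(1e-1, 1e-2))
#> # A tibble: 1 × 6
#>   n_pos n_neg    ap auroc `recall_at_1e-01` `recall_at_1e-02`
#>   <int> <int> <dbl> <dbl>             <dbl>             <dbl>
#> 1   320   200 0.915 0.889             0.625             0.138
```

The one-row tibble reports average precision (`ap` — here 0.915: most
motif-bearing domains rank above the motif-free ones), area under the ROC
curve, and recall read off the ROC curve at each false-positive rate by
linear interpolation (62.5% of motif domains are recovered before 10% of
background domains score as high). Each hit row records the best-scoring
window, so localization quality can be checked against the generator's
annotations:

```r
ann <- dplyr::filter(bench$annotations, split == "same")
shifts <- motif_shifts(hits, ann)
plot_motif_shifts(shifts)        # begin/end shift histograms
```

Proteome-scan accounting against an evidenced motif set uses
`prf_vs_evidenced()`; e.g. 16 evidenced motifs among 124 hits with 25
evidenced in total:

```r
prf_vs_evidenced(16, 124, 25)[, c("recall_2dp", "precision_2dp", "f1_2dp")]
#> # A tibble: 1 × 3
#>   recall_2dp precision_2dp f1_2dp
#>        <dbl>         <dbl>  <dbl>
#> 1       0.64          0.13   0.21
```

A thin CLI over the same functions ships in `inst/cli/amyloscan.R`
(`simulate`, `train`, `scan`, `eval`, `embed` subcommands).

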