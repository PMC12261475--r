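---
title: "Detecting amyloid signaling motifs with a lightweight BiLSTM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting amyloid signaling motifs with a lightweight BiLSTM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloscan)
```

## The problem

Amyloid signaling motifs (ASMs) are short (roughly 11--40 residue) protein
segments that seed a self-propagating cross-beta amyloid fold used for
signal transduction in innate-immunity pathways of bacteria, fungi and
animals. They sit at the N-termini of Nod-like receptors (NLRs) and the
C-termini of cooperating effectors. ASM families are extremely diverse --
conserved patterns are short, degenerate, and share little beyond a bias
toward amyloid-prone residues (Q, N, G, S, ...) -- which makes them hard
targets for alignment-based profile methods. `amyloscan` implements a
discriminative alternative: a very small bidirectional LSTM that classifies
fixed 40-residue windows, combined with a sliding-window scan and
max-pooling so that arbitrary-length sequences get a single detection
score.

## The per-window classifier

The model is deliberately tiny:

* embedding of the 26-token alphabet (PAD + 25 residue letters) into 8
  dimensions;
* 10% dropout;
* a bidirectional LSTM with 8 units per direction (tanh), whose two final
  states are concatenated to a 16-dimensional summary;
* 10% dropout;
* a unidirectional LSTM with 4 units refining that summary;
* 10% dropout;
* one sigmoid output unit -- the probability that the window contains an
  ASM.

With one bias per gate this totals
$Vd + 2\,[4u_1(d+u_1+1)] + 4u_2(2u_1+u_2+1) + (u_2+1) = 1637$
trainable parameters for the defaults $(V,d,u_1,u_2) = (26,8,8,4)$. The
count is enforced as an architectural contract: `count_trainable_params()`
(closed form) must equal the number of weights `build_model()` actually
allocates. The 26-row embedding is itself part of that contract -- with the
default layer sizes, 26 is the only vocabulary size that yields 1,637
parameters, which pins the tokenizer to PAD + 20 canonical residues +
B, Z, X, U, O with no start/end tokens.

```{r params}
count_trainable_params(model_config())
n_params(build_model(model_config(), seed = 1))
```

### Readout of the bidirectional layer

A genuinely open design point is what the 4-unit LSTM consumes. The package
supports both constructions behind `model_config(readout = )`:

* `"final"` (default): the concatenated final states of the two directions,
  processed as a one-step input;
* `"sequence"`: the per-position concatenated outputs, processed as a
  40-step sequence (the classic stacked-recurrent construction).

Both have exactly the same trainable-parameter total. On the packaged
benchmark the two are statistically indistinguishable in average precision,
while the final-state readout trains several-fold faster because
backpropagation through the second layer covers one step instead of forty;
it is therefore the default.

### PAD masking

Sequences shorter than the window are zero-postpadded at scan time. PAD
positions (token 0) are masked in every recurrent layer: the state is
carried through unchanged, so a postpadded window is scored identically to
the bare residue sequence. Without masking, the untrained PAD embedding
would inject noise into the recurrent states of every short sequence.

### Initialization and optimization

Input kernels are Glorot-uniform, recurrent kernels are random orthogonal
(stacked per gate), biases are zero except the forget gate (set to 1), the
embedding is uniform on $(-0.05, 0.05)$. Training uses Adam
(learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) on binary cross-entropy, batch size 32, for a fixed
number of epochs with no early stopping; 30 epochs is the default regime.
The gradient is computed by exact backpropagation through time (verified
against central finite differences in the test suite). All randomness --
initialization, shuffling, dropout masks, padding -- flows from the
training seed through R's RNG, so runs are bitwise reproducible.

## Sequence processing

Two deliberately asymmetric padding rules:

* **training positives** shorter than 40 residues are *prepadded* with
  random residues drawn i.i.d. from the Swiss-Prot background composition
  (packaged in `inst/extdata/swissprot_freqs.tsv`), emulating upstream
  sequence noise;
* **scan inputs** shorter than 40 residues are *zero-postpadded* (and
  masked, see above).

Pads are drawn once per training run by default;
`train_config(resample_pads_each_epoch = TRUE)` redraws them every epoch.
Longer sequences are processed with a sliding window of size 40 and step 1;
each window is scored by every fold model, fold probabilities are averaged
per window (`combine_probs()`), and the per-sequence score is the maximum
window mean (max-pooling), ties broken toward the smallest start.
Coordinates are 0-based half-open internally and 1-based inclusive in
written tables.

## Cross-validation ensemble

`asm_train()` splits positives and negatives separately into six
near-equal blocks (sizes differ by at most one), trains one model per fold
on five blocks, and keeps the final-epoch weights (best-validation-loss
checkpointing is available behind `train_config(checkpoint_best = TRUE)`;
the validation fold is purely monitored by default). The resulting
`asm_ensemble` -- the *combined model* -- scores a window with the
arithmetic mean of the six sigmoid probabilities. Probabilities (not
logits) are averaged; per-fold probabilities are retained in hit tables for
auditability.

Class imbalance is left as-is by default (`neg_per_pos = "all"`, no class
weights), the natural regime for a small positive set against a
large general negative set; `neg_per_pos = <ratio>` subsamples negatives
for desk-scale experiments.

## Evaluation protocol

`roc_curve()` sweeps distinct scores descending (ties collapse to one
operating point) and always includes (0,0) and (1,1). `recall_at_fpr()`
reads the ROC staircase at a target FPR by linear interpolation; when the
target coincides with a vertical segment, the maximum TPR there is
returned (the optimistic convention natural for "recall at FPR"
reporting); between attained FPRs the interpolation follows the actual
staircase segment. `average_precision()` uses the step-function
(non-interpolated) retrieval definition, the standard in retrieval
evaluation. Precision with zero hits is defined as 0 so threshold sweeps
never crash. `prf_vs_evidenced()` implements proteome-scan accounting
against an evidenced motif set: recall = true hits / evidenced, precision
= true hits / hits, F1 the harmonic mean of the unrounded values, with
2-decimal companions for table display. `retention_rate()` is the detected
fraction of a score set at a threshold.

## Embedding introspection

`best_window_embeddings()` extracts, for each sequence, the 4-dimensional
final state of the unidirectional layer (the representation feeding the
sigmoid, taken at the inactive final-dropout position) for the
best-scoring window, from every fold. Fold vectors are concatenated
(6 x 4 = 24 dimensions; concatenation preserves all information), or
averaged via `combine = "mean"`. `project_2d()` maps the vectors to two
dimensions with principal components (default) or classical MDS -- both
deterministic, order-preserving linear projections chosen for
introspection of a 24-dimensional space; `autoplot()` renders the
dot-vs-cross (detected vs not) scatter and `retention_by_group()` the
per-family retention summaries.

## The synthetic benchmark

Real ASM collections cannot be bundled, so `generate_benchmark()` creates
a statistically analogous, fully seeded benchmark:

* **families**: 8 training families (motif lengths 21--40, effector-side
  style) and 2 held-out families (lengths 11--30, receptor-side style).
  A family is a set of 8 anchors -- conserved positions at fixed *relative*
  locations, each emitting a dominant residue with probability 0.9 --
  over Swiss-Prot background. Anchor density (~8 of >=21 positions) echoes
  real conserved ASM patterns, where roughly 40% of positions are
  conserved. Dominant residues are drawn from an amyloid-prone pool
  (Q, N, G, S, Y, F) shared across families: this shared compositional
  bias, mirroring the Q/N/G-richness of real ASMs, is what gives a model
  trained on some families any purchase on held-out ones.
* **training data**: 120 motifs per training family; 20,000 background
  40-mers (the role of a general negative set approximating all protein
  space).
* **test data**: 40 fresh motifs per training family (same-family
  generalization) and 40 per held-out family (novel-family
  generalization), each provided rigorously cut (env0), with 5- and
  10-residue envelopes, and implanted in 100-residue background domains
  with true coordinates in an annotation table; plus 2,000 fresh
  evaluation 40-mers and 200 motif-free background domains.

With 8 anchors at dominant mass 0.9 over ~5--9% background residue
frequencies, the chance of a spurious full anchor-pattern match in a
background 40-mer is far below $10^{-3}$ per sequence, so negatives are
clean by construction (a contamination knob is deliberately absent; the
real general negative set may contain true ASMs, the synthetic one does
not). Every component draws from a named substream of one root seed, so
regeneration is byte-identical and components are independently
reproducible.

### What the benchmark does and does not emulate

It reproduces the *statistical design* -- family structure with conserved
positions, length variation, envelope and domain variants, clean
i.i.d. background negatives -- not real sequence content: no homology, no
phylogenetic redundancy, no real effector domains, no repeat structure.
Within-family identity is ~25%, considerably more diverse than real
nr70-clustered motif families. Passing results therefore demonstrate that
the pipeline learns and localizes conserved short motifs under realistic
noise, not that it reaches any particular performance on real ASM data.

## Observed behavior at the packaged scale

At the desk scale used in the tests (the default benchmark above; 6 folds
at 10 epochs, roughly two minutes of training on one CPU), the combined
model separates domain-embedded motifs from background domains very well
(average precision above 0.9; the README's worked example prints this
comparison) and detects held-out novel families at many times the
prevalence baseline, but average precision on
*rigorously cut* same-family motifs plateaus around 0.8, short of the 0.9
the end-to-end suite asserts. The weakest setting being the zealously
excised motif is expected for this construction: the train-time
prepadding/scan-time postpadding asymmetry and the model's small capacity
both act against bare short inputs, and enlarging the extraction envelope
or scanning the full domain recovers performance.

Localization shows the complementary signature of suffix-aligned
(prepadded) training: on domain-embedded 25-residue motifs the
best-scoring window tends to end near the motif end while extending
upstream, so it usually covers the whole motif but in a minority of
detected cases covers less than 80% of it, slightly below the 90%-of-cases
bar the end-to-end suite asserts. We report these plateaus as-is rather
than enlarging the generator's conservation parameters, which were fixed
a priori to the realistic density above.

## Numerical choices and degenerate inputs

* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside the loss
  only; raw sigmoid outputs are reported.
* Ties in max-pooling break toward the smallest window start; ties in the
  ROC sweep collapse to one point.
* Empty sequences, single-class training data, inverted motif intervals,
  over-length training sequences and non-40 windows are rejected with
  informative errors.
* `combine_probs()` validates that fold probabilities lie in [0, 1];
  the window mean is guaranteed to lie within the fold range.
* Scanning is pure inference: dropout is disabled and repeated scans are
  bitwise identical.

## Problem sizes in the test suite

The suite trains full 6-fold ensembles on the default benchmark (960
positives, 20,000 negatives, 10 epochs) for the end-to-end checks, and
miniature ensembles (tens of sequences, 2--4 epochs) elsewhere; property
checks use $10^5$ padding draws, 2,000-point score sets, and brute-force
ROC enumeration up to n = 50. These sizes were chosen so the whole suite
completes in minutes on a single CPU while still exercising every
component at meaningful scale.

## Known limitations

* The scorer-adapter seam accepts any external per-window probability
  function, but no transformer-based scorer ships with the package.
* No confidence intervals on metrics; no redundancy reduction of inputs
  (assumed preprocessed); no genomic-neighborhood analysis of hits.
* The 2-D projections are linear; nonlinear neighbor-embedding methods may
  reveal finer cluster structure in the 24-dimensional fold-concatenated
  space.
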