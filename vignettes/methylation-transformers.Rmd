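---
title: "Predicting DNA methylation sites with transformer language-model ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA methylation sites with transformer language-model ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

N6-methyladenine (6mA), N4-methylcytosine (4mC) and
5-hydroxymethylcytosine (5hmC) are DNA base modifications with regulatory
roles across bacteria and eukaryotes. Given a 41-nucleotide window centered
on a candidate base (A for 6mA, C for 4mC/5hmC), the task is to decide
whether the center base is methylated. Because methylation grammar differs
between organisms, each window is annotated with the organism's 8-rank
taxonomic lineage (species through domain), and the lineage is part of the
model input rather than a stratification variable — one classifier per
methylation type serves all lineages.

## Input encoding

A window is turned into text in two parts:

1. **DNA words.** A sliding window of length 6 over the 41-mer yields
   exactly 36 overlapping 6-mers (41 − 6 + 1), written as space-separated
   words. Overlap matters: adjacent words share five bases, which gives a
   masked-language model local context from which masked words can be
   reconstructed.
2. **Lineage clause.** The fixed template "For this organism, its species
   is S, its genus is G, ..., its domain is D." with the 8 rank names
   substituted; missing ranks carry the literal placeholder "unknown".

The concatenated sentence is tokenized and padded to exactly 100 tokens:
`[CLS]`, the sentence pieces, `[SEP]`, then `[PAD]`s. If a sentence
overflows (very long rank names), words are dropped from the tail of the
taxonomy clause, never from the DNA part, which always fits. Sequences
containing N are accepted by the data container but rejected at sentence
encoding, because the 6-mer vocabulary is defined over ACGT only.

## Tokenizers

Each model family trains its own tokenizer on the corpus: the processed
training sentences plus one lineage sentence for every extra lineage (for
example from a pre-extracted NCBI/GTDB table) whose 8-tuple is not already
present. Two subword algorithms cover the five families:

* **word-piece** (BERT, DistilBERT, ELECTRA): frequency-ranked whole words
  plus character fallback pieces with `##` continuations, greedy
  longest-match encoding;
* **unigram** (ALBERT, XLNet): the same inventory scored by log relative
  frequency with Viterbi maximum-likelihood segmentation.

Both are implemented in the package (no tokenizer library exists for R)
and both guarantee the property the pipeline relies on: at the default
25,000-token vocabulary target every corpus word above the frequency
threshold — in particular each of the at most 4096 distinct 6-mers — is a
single token. Word-piece tokens are word-aligned, which is why the
interpretability layer averages only the word-piece families.

## Models and pretraining

The encoder is a standard post-layer-norm transformer (multi-head scaled
dot-product self-attention, GELU feed-forward, residual connections,
learned absolute positions, tied input/output embeddings), written in R
matrix code with explicit backpropagation and AdamW, since no deep
learning framework is available for R; the per-sample attention blocks,
which are many small matrix products, run through RcppArmadillo kernels,
with a pure-R reference path kept for attention extraction and for the
oracle tests. Two presets exist:

* `paper`: 12 layers, 768 hidden units, 12 heads (6 layers for
  DistilBERT; ALBERT shares layer parameters and factorizes the
  embedding), the scale of the published architecture;
* `tiny` (default): 2 layers, 64 hidden units, 4 heads, feed-forward
  width 128 (2x hidden, rather than BERT's 4x: at this scale the FFN
  dominates the arithmetic and the narrower width halves it without
  measurable loss on the synthetic tasks) — the desk scale at which every
  mechanism in this package is exercised end to end on one CPU.

Pretraining objectives follow the families: masked language modeling for
BERT, DistilBERT and ALBERT — 15% of non-special tokens are selected as
candidates, of which 80% become `[MASK]`, 10% a random vocabulary token
and 10% stay unchanged — replaced-token detection for ELECTRA, and a
permutation language model for XLNet. Two desk-scale simplifications are
documented here deliberately: the ELECTRA corruptor samples replacements
from the corpus unigram distribution instead of a jointly trained
generator network, and the XLNet objective is the one-stream approximation
(the last ~15% of a sampled factorization order are predicted, their
inputs replaced by a learned placeholder, with an attention mask hiding
each target from itself and from later-in-order targets) rather than
two-stream attention. Next-sentence prediction is not used.

Default pretraining hyperparameters are 8 epochs, batch size 64, learning
rate 5e-4 reached after 100 warmup steps; fine-tuning uses at most 32
epochs, batch size 64, learning rate 1e-5 with the same warmup.

### Numerical choices

* **Initialization.** Weights are N(0, 0.02) as usual, with one
  exception: at 64 hidden units the query/key products of a 0.02
  initialization are numerically ~0, the attention softmax starts uniform,
  and gradient descent happily converges to a bag-of-words solution in
  which attention never becomes content-selective — which silences the
  attention-based interpretability. The tiny preset therefore initializes
  the query/key projections at sd 0.4 (`qk_init_range`), giving heads
  initial content preferences that training can amplify; the paper preset
  keeps 0.02 throughout. `pos_init_range` exposes the same choice for the
  position embeddings.
* **Optimizer.** AdamW with decoupled weight decay 0.01 on weight
  matrices (never on biases or layer-norm parameters). Besides its usual
  regularizing role, the decay shrinks attention preferences that receive
  no gradient — loss-neutral directions inherited from the initialization
  — which keeps the importance profiles clean.
* **Softmax and GELU.** Attention softmax is stabilized by subtracting the
  global maximum (masked entries sit at −1e9 and underflow to exactly 0);
  GELU uses the sigmoid approximation `x · σ(1.702x)`.
* **Selection is Bernoulli.** Masking candidates are selected per token
  with probability 0.15 rather than as an exact 15% count, matching the
  reference implementations of the objective; `[CLS]`, `[SEP]`, `[PAD]`
  are never candidates.
* **Reproducibility.** All training is single-threaded and seeds flow
  from `train_config(seed=)` through shuffling, masking and
  initialization; two runs with the same seed are bit-identical.

## Fine-tuning cascade and ensemble

A tanh pooler plus softmax classifier sits on the final-layer `[CLS]`
state. Fine-tuning is cascaded in order of decreasing subset size:
6mA from the pretrained model, 4mC from the 6mA model, 5hmC from the 4mC
model, so the smaller subsets start from an already specialised model.
Each stage splits its subset 8:2 (stratified — balanced data should stay
balanced in both parts) and applies early stopping on validation loss with
patience 3 evaluations; the best-validation checkpoint is returned, and
checkpoint hashes record the provenance chain. Validation loss (rather
than a ranking metric) is monitored as the least-assumption default.

The ensemble is deliberately simple: the prediction is the unweighted
arithmetic mean of the five per-family probabilities, thresholded at 0.5
with `p ≥ t` called positive (the benchmark design is balanced, so the
symmetric default is appropriate). If a member is unavailable the average
runs over the remaining members with a warning.

## Interpretability

`Attention = softmax(QK^T/√d_k)` rows are extracted per layer and head
(the row-softmax is part of the canonical definition; without it the rows
could not be read as weights that sum to one). Token importance is the
attention linking each token to `[CLS]`, summed over heads and, by
default, over all encoder layers. Two readings of "the attention between
token and [CLS]" exist; the default takes the `[CLS]`-as-Query row — the
distribution actually consumed by the classifier head — and
`direction = "cls-key"` provides the transposed reading. Summing over all
layers rather than only the last is a deliberate choice: the classifier
reads the final `[CLS]` state, but content reaches that state through the
residual stream via the attention of every layer, and in small models the
content-selective head may sit in any of them — on planted-motif data we
observe it in the first layer about as often as in the last, where a
last-layer-only reading would miss it entirely. `layers = "last"` (or
explicit indices) restricts the sum. The DNA-to-taxonomy matrix uses the
final layer, where the token representations that feed the classifier are
formed.

Word scores aggregate token scores by source word; the framework-level
profile averages the word-piece members (BERT, DistilBERT, ELECTRA) word
by word. Per-position scores over the 41-mer merge the 1–6 covering
6-mers by mean (sum available via `merge = "sum"`). Motif tables rank
distinct 6-mers by mean score over their occurrences in a positive sample
set. DNA-to-taxonomy attention sums final-layer weights from each DNA
word's tokens to each rank name's tokens, giving a 36 × 8 matrix.

## Genome scanning

For a long sequence, candidate windows are extracted around every
occurrence of the target base at positions 21..L−20, classified by the
ensemble, and threshold-passing calls are filtered by the center-max rule:
a call is retained only if its 41-position importance profile attains its
maximum at the window center. Ties retain the site (a plateau including
the center should not reject it); `strict = TRUE` demands a unique
maximum. On phase-randomized synthetic motifs this filter is
conservative: the importance peak tracks the middle of the planted motif
rather than the methylated base itself, so true sites whose motif phase
shifts the peak off-center are rejected along with the false calls — the
scanning tests therefore bound the classifier stage's recall and report
the post-filter recall. The reverse strand is not scanned automatically — samples are
single-stranded windows — but `both_strands = TRUE` additionally scans
the reverse complement and reports reverse-strand calls in forward
coordinates with a strand column; overlapping calls receive no
suppression beyond the center-max filter. BED output uses 0-based half-open
single-base intervals.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` emulates the structure of the public 41-nt
methylation benchmarks: balanced positives and negatives, positives
centered on the methylatable base and carrying a plantable consensus motif
(exact copies by default; `sub_prob` adds per-position substitution
noise), negatives rejection-sampled to exclude the exact consensus but
not degenerate matches, lineages assigned round-robin, uniform background
base composition. The motif is written at an offset sampled uniformly
among the center-overlapping placements whose consensus base over the
center is the methylation target, so the planted copy survives forcing
the center base. The default consensus CATACA offers three such phases
for 6mA and two for 4mC/5hmC; randomized phase matters because a motif
pinned to one offset lets a sequence model solve the task purely
positionally, whereas phase variation forces it to key on motif content —
which is the mechanism the attention analyses measure.
`generate_genome()` plants non-overlapping motif-bearing windows in a
random chromosome with recorded truth.

What passing tests on these data do **not** show: performance on real
genomes (no GC bias, no repeat structure, no lineage-specific motif
families, single planted motif rather than a motif distribution), and
nothing about the published benchmark numbers, which require the external
training corpus and full-scale models. The synthetic suite validates the
mechanisms — encoding, masking statistics, training dynamics, averaging,
attention-derived localization, scanning — not biological accuracy.

## Problem sizes used by the test suite

The suite trains tiny models on a few hundred samples: pretraining runs a
few epochs on a corpus of a few hundred sentences; fine-tuning uses
400-sample planted-motif datasets; motif-recovery properties run ten
seeded fine-tuning replicates over shared pretrained bases (pretraining
once and fine-tuning per task mirrors the method's own structure); the
scanning check uses a 5,000-nt synthetic chromosome with 10 planted
sites. These sizes were chosen as the smallest at which the mechanisms
express themselves reliably.

## Known limitations

* The transformer is a faithful but minimal encoder: no dropout (training
  is deterministic), absolute positions for XLNet (no relative encodings),
  no two-stream attention, no learned ELECTRA generator.
* Tokenizer training is frequency-based rather than likelihood-trained
  WordPiece/SentencePiece; for this corpus (whole 6-mers plus a small
  taxonomy vocabulary) the resulting vocabularies coincide with what the
  reference trainers produce at the same budget.
* The `paper` preset instantiates the full-scale architectures but CPU
  training at that scale is impractical; it exists for structural
  fidelity, not for reproducing published benchmark scores.
* Attention-derived importance at tiny scale retains positional
  preferences; the motif-recovery properties quantify how reliably the
  planted signal still dominates.
```
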