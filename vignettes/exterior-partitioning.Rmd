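---
title: "Exterior-loop partitioning: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exterior-loop partitioning: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
definitions, the model and its assumptions, the tunable parameters, what the
synthetic generator does and does not emulate, the numerical choices, and
the known limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The decomposition

A base *k* of a secondary structure belongs to an **exterior loop** when it
is unpaired and no pair *(i, j)* satisfies *i < k < j*. Bases in
non-canonical pairs, base triples and pseudoknotted pairs all count as
paired, and the *open interval* of every pair shields what it encloses, so
with crossing pairs the shielded region is the union of all intervals.
`label_exterior()` computes this with a difference-array interval union in
O(n + p); the test suite keeps an all-pairs brute-force check as an
independent oracle.

The maximal runs of non-exterior bases are the **independent fragments**.
Two facts make them useful, and both are enforced as testable identities:

* *Fragment closure*: the closed interval of any pair is entirely
  non-exterior, so every pair lies inside exactly one fragment. A pair that
  straddled a fragment boundary would contradict the labels, and
  `extract_substructure()` raises an error rather than dropping it.
* *Lossless round trip*: `assemble()` ∘ `extract()` ∘ `partition()` ∘
  `label_exterior()` is the identity on pair sets.

Coordinates are 1-based and closed throughout the package, because R is
1-based everywhere else; CT and BPSEQ files are 1-based by convention and
dot-bracket has no coordinates, so nothing needs translating at the I/O
boundary. (BED output is the standard 0-based half-open exception.)

A fully unpaired RNA partitions into *zero* fragments: the whole molecule
is one exterior loop and there is nothing to fold.

## The labeler

The sequence-only labeler predicts the exterior labels from windows of the
sequence alone. Architecture (per window of length `L`):

1. four 1D convolutions, kernel `K` (odd, so they stay centered), `C`
   channels, relu;
2. one bidirectional LSTM with `U` units per direction (tanh cell);
3. batch normalization;
4. two residual layers: each is two fully-connected layers of width `N`
   (relu) whose outputs are joined by a shortcut (`out = h1 + h2`);
5. batch normalization, then a per-position two-node softmax.

Dropout (rate 0.1 by default) acts inside the conv, LSTM and residual
blocks. Windows are one-hot encoded over five channels in the fixed order
`(-, U, G, C, A)` — `'-'` is `10000`, `A` is `00001` — and padding is
handled by masks: padded positions are zeroed at the input and after every
block, excluded from batch-norm statistics, and excluded from the loss, so
the *content* of a padding column can never influence any real position
(the suite asserts this by mutating padding and comparing outputs
bit-for-bit). A zero column is still distinguishable from any real base, so
the network can see where a sequence ends without seeing what the padding
"says".

Windowing uses offsets `1, 1+step, 1+2·step, …` for every offset not past
the sequence end, the tail right-padded with `'-'`. Dataset construction
defaults to non-overlapping windows (`step = L`); inference defaults to a
half-window step, and `stitch_predictions()` averages every base over the
windows that cover it. Averaging is the natural combination rule here and
is idempotent on constants; the default `L` is 200 with 60/120/280
supported, and the shorter 120 is used in the package's own desk-scale
experiments to keep runtimes modest.

### Training

The engine is part of the package: analytic backpropagation through the
stack above, Adam (default learning rate 1e-3, configurable), masked
cross-entropy, early stopping on validation base-level MCC with patience 10
(default) and best-epoch weight restoration, plus an optional
reduce-on-plateau schedule (halve the rate after 2 non-improving epochs)
that stabilises the late phase of training. A finite-difference gradient
check on a small configuration guards the implementation; a linearly
separable toy task (exterior ≔ runs of A) must reach validation MCC ≥ 0.95,
which catches wiring bugs that gradient checks alone would not.

Two-stage **transfer training** (`transfer_train()`) first fits the model
on a large, noisily labeled corpus, then continues *from those weights* on
a smaller accurately labeled corpus with identical hyper-parameters — no
layer freezing, no learning-rate drop between stages. The premise is that
noisy labels teach the general shape of the problem and the clean labels
recalibrate it; the acceptance suite checks the direction (trans-trained
MCC ≥ pre-trained MCC) rather than any absolute value.

Hyper-parameter search (`tune_hyperparameters()`) is sequential model-based
optimization over the (K, C, U, N) box: a few random trials, then a random
forest surrogate whose mean-plus-spread acquisition picks each next
configuration from a random candidate pool. The default budget is 20
trials; `labeler_ensemble()` keeps the top 3 by validation MCC and averages
their per-base probabilities. The positive-class threshold is 0.5 with ties
going to "exterior"; it is exposed, not hard-coded.

## Metrics

Three confusion modes share one report format (SEN, PRE, ACC, MCC, F1):

* **base** — per-base counts over unmasked positions, positive class =
  exterior;
* **segment** — maximal runs of the *truth* labels; an exterior segment is
  a TP when any base inside it is predicted positive (else FN), a
  non-exterior segment is an FP when any base inside it is predicted
  positive (else TN). This scores whether partition boundaries are found at
  all, which is what matters downstream: one found base inside a linker is
  enough to split the fragments;
* **pair** — set algebra over base pairs, with TN the remaining unordered
  position pairs.

A zero denominator makes a metric *undefined* (`NA`), which is reported
distinctly from 0 and excluded (with a count) from macro averages.
Dataset-level metrics pool counts by default (micro); per-sequence
macro-averaging and a seeded bootstrap standard error over per-sequence
values (default 100 resamples) are provided because per-sequence spread is
the quantity of interest when corpora mix lengths.

## The synthetic generator

`generate_structure()` draws alternating exterior linkers and fragments.
Each fragment is a nested stem-loop domain from a small grammar: an outer
helix (2–10 bp) always spans the whole fragment, and each loop interior
either ends as a hairpin (≥ 3 nt), continues through an internal
loop/bulge, or branches into two sub-domains; interiors longer than three
minimal domains always keep structuring, since bare hairpin loops of tens
of nucleotides do not occur in real structures. A grammar — rather than
thermodynamic sampling — is used deliberately: the ground-truth labels must
be *exact by construction*, and the grammar guarantees that every fragment
begins and ends paired, so the true labels equal `label_exterior()` of the
emitted structure (asserted for every generated case in the tests). With a
small probability a fragment gains one crossing pair between two unpaired
positions, exercising the pseudoknot path without breaking
CT-representability.

Sequence composition: paired positions are complementary with a GC/AU/GU
mix of 0.55/0.35/0.10 (GC-rich stems, as in thermodynamically stable
helices); unpaired bases follow region-specific G+C fractions, 0.2 in
exterior loops versus 0.6 inside fragments. The GC depletion of exterior
loops is the compositional signal a sequence-only labeler can exploit, and
the generator makes it explicit and controllable.

Architecture defaults are anchored to the fragment statistics of curated
secondary-structure corpora: fragment lengths lognormal with mean ≈ 130 nt
(shortest clamped at 12), fragment counts mostly 1–2 with ~17% of RNAs
above 2 (geometric tail to 10), internal linkers geometric with mean 20 nt
(minimum 1), dangling ends geometric with mean 15 nt. Those linker/end
means follow from two corpus observations: mean fragment length ~129 nt at
~1.5 fragments per RNA with most RNAs under 400 nt implies roughly 15–20%
of bases exterior; and the coexistence of high base-level sensitivity with
much lower segment-level sensitivity in exterior-loop prediction implies
that exterior bases sit mostly in long runs (short linkers are the ones
that get missed). The defaults realise ≈ 17% exterior bases in runs of
10–20 nt. A per-base `label_noise` flip rate produces the "coarse" variant
of generated datasets, emulating training corpora whose structures are only
approximately correct.

What the generator does **not** emulate: thermodynamic plausibility of
specific families, non-canonical pair geometries, base triples (off by
default so CT always applies), sequence motifs, or conservation signal.
Passing tests on this corpus therefore show that the *machinery* works and
that composition-plus-context signal is learnable at the stated contrast —
not that any particular accuracy transfers to real corpora.

## Numerical and design choices

* "Between two paired bases" is read as the strict interior of any single
  pair, implemented as interval-union coverage; the brute-force reading is
  kept as a test oracle. This is the only reading consistent with treating
  pseudoknotted bases as paired.
* The maximum-pairing folder (`nussinov_fold()`) is the deterministic
  built-in fragment predictor: O(n³) dynamic programming with hairpin
  loops ≥ 3 nt and fully specified tie-breaks (unpaired beats paired on
  equal score; among equal partners the 5'-most wins), so output is
  reproducible and is checked against exhaustive enumeration for short
  sequences. It is a combinatorial stand-in with a pluggable interface —
  external engines attach as `function(sequence, ...) -> structure`
  adapters, and nothing in the test suite requires one.
* Predicted exterior runs of any length (≥ 1) split fragments; an optional
  minimum-run smoothing width exists for experimentation and defaults to
  off.
* Bracket-layer assignment when writing dot-bracket is greedy first-fit
  over the layer order `() [] {} <> Aa Bb`; structures needing more than
  six layers, or containing triples, are refused rather than mangled.
* Checkpoints are a JSON manifest plus flat text weight files, so saved
  models survive in plain-text form and reload bit-exactly.
* Desk-scale problem sizes: the package's own experiments and acceptance
  checks use L = 120 windows, corpora of roughly 450–1100 RNAs
  (≈ 1000–2000 windows), models around 50k parameters, and training budgets
  of 8–12 epochs with patience 3–4 at batch 128 — sizes chosen so a full
  verification runs on a single CPU in minutes while still exercising every
  stage at realistic signal levels.

## Limitations

* True cross-fragment base pairs cannot be represented after partitioning:
  a false-positive exterior call that splits a real fragment converts its
  internal pairs into unrecoverable false negatives. The pipeline reports
  these in pair-level FN counts and makes no post-assembly repair attempt.
* Very short exterior linkers (a few nt) between stems are close to
  indistinguishable from multiloop junction bases on composition alone;
  base-level recall on such runs is intrinsically limited, which is why
  segment-level metrics are reported alongside base-level ones.
* The training engine is single-threaded CPU code. It is fast enough for
  the desk-scale corpora above (seconds per epoch), not a platform for
  full-scale training runs.
* `fragment_stats()` correlations are undefined (reported `NA`) on
  degenerate corpora, e.g. identical RNAs.
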