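---
title: "Weight-capsule sequence classification of heartbeats: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-capsule sequence classification of heartbeats: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wcapseq)
```

## The problem

Ambulatory ECG recordings contain thousands of heartbeats, the overwhelming
majority of which are normal. Clinically interesting beats — supraventricular
ectopic (S), ventricular ectopic (V), fusion (F) — are rare, often below 5%
of beats, and a classifier evaluated within-patient can simply memorise each
patient's morphology. `wcapseq` implements an *inter-patient* heartbeat
classifier: training and test beats come from disjoint patients (the
standard DS1/DS2 partition of the MIT-BIH arrhythmia database), and the
model is designed to hold up under heavy class imbalance without resampling
or synthetic oversampling.

The classifier works on sequences of beats rather than isolated beats,
labelling each beat of a window with one of the five AAMI EC57 classes
(N, S, V, F, Q).

## Preprocessing

The pipeline follows the common inter-patient protocol and deliberately does
no filtering or denoising:

1. min–max normalize the whole record to [0, 1] (`normalize_signal()`);
2. take R-peak positions from the annotation file (no detection);
3. segment each beat from its R-peak to the next R-peak — the beat
   boundaries are never stated more precisely in the protocol's sources, so
   the R-to-next-R convention is the default and a fixed pre/post window
   around the R-peak is available via `extract_beats(segmentation =
   "window")`; the record's last annotated beat has no following R-peak and
   is dropped;
4. resample each segment to 280 samples, by default with linear
   interpolation (deterministic, endpoint-preserving; a Fourier resampler is
   available).

Beat symbols map to AAMI classes by the EC57 table (N←{N,L,R,e,j},
S←{A,a,J,S}, V←{V,E}, F←{F}, Q←{/,f,Q}); anything else (rhythm marks,
artifacts) is skipped. Annotation indices are treated as 0-based sample
positions. A constant signal cannot be rescaled; `normalize_signal()`
returns zeros with a warning rather than failing, so degenerate synthetic
edge cases do not abort a pipeline.

Beats are grouped per record into consecutive non-overlapping windows of
`seq_len` beats (default 10 — the protocol sources do not fix a value; ten
beats is a few seconds of rhythm context). A final short window is padded
and the padded positions carry zero loss weight and are dropped from
evaluation.

## The model

`MWCapsuleNets` is the default of nine constructible variants
(`model_variants()`): a *frontend* producing a 20×28 feature map per beat,
a *beat-embedding stage*, and a shared *sequence-to-sequence head*.

### MLP patch-mixing block

Each 280-sample beat is folded row-major into a 10×28 grid of patches ×
channels. A fully connected layer with 10 units mixes the patch axis,
identically and independently for each channel (the token-mixing reading:
the stated 10 units match the 10 patches; mixing the channel axis instead
is available behind a configuration flag). The layer is linear — the
defining equation shows no activation — and is followed by inverted dropout
(default rate 0.8, the reference protocol's value; inverted scaling makes
evaluation parameter-free). The block output is the concatenation of the
mixed grid with its input: a 20×28 map, so the raw beat always survives the
(aggressive) dropout through the skip half.

### Weight-capsule layer

The primary capsule layer is a single 1-D convolution along the length-20
axis (28 output channels, kernel 3, stride 1, no padding) followed by ReLU;
each of the 18 output positions is a capsule with a 28-dimensional pose
vector. Prediction vectors $\hat u_{j|i} = W_{ij} u_i$ connect every primary
capsule $i$ to each of 128 output capsules $j$ (routing is fully connected;
whether the output layer performs its own convolutional grouping first is
not specified by the architecture's description, so the simpler fully
connected routing is used).

Routing is iterative (3 iterations, the usual convention):

$$c_{ij} = \mathrm{softmax}_j(b_{ij} f_{ij}), \qquad
  s_j = k_j \sum_i c_{ij} \hat u_{j|i}, \qquad
  v_j = \mathrm{squash}(s_j), \qquad
  b_{ij} \mathrel{+}= \hat u_{j|i} \cdot v_j .$$

Logits start at zero, so initially every input couples to all outputs with
equal probability. Two ingredients distinguish the *weight* capsule from the
textbook one:

* **per-connection weights** $f_{ij}$ inside the softmax. Their exact
  published form lives in supplementary material that is not available
  here; the package default $f_{ij} = 1/(1+\lVert\hat u_{j|i}\rVert)$
  implements the stated intent — damping the dominance of large-norm
  predictions in the couplings — and the interface is pluggable
  (`f_form`), with invariants that hold for any positive bounded choice.
* **per-output weights** $k_j$, learnable and kept positive through a
  softplus reparameterisation (again a substitute for an unavailable
  supplementary formula).

With `f_form = "one"`, `k = 1` and the standard squash, the implementation
reduces *exactly* to textbook routing-by-agreement; the test suite pins this
equivalence against an independently coded reference on random instances.

**Sigmoid-squash.** Capsule norms are compressed by

$$v = \frac{g(\lVert s\rVert^2) + \alpha\lVert s\rVert}
           {1 + \alpha\lVert s\rVert + g(\lVert s\rVert^2)}
      \cdot \frac{s}{\lVert s\rVert}, \qquad \alpha = 0.1 .$$

The rendering of $g$ in the available text is ambiguous; the package uses
$g(x) = 2\sigma(x) - 1$, the sigmoid-derived form with $g(0)=0$, so that a
zero input maps to a zero output (a pure sigmoid would give a zero-input
activation of 1/3, violating the "no entity, no activation" contract);
$\tanh$ is available as an alternative gate. The profile is strictly
increasing, bounded below 1, and its slope at large norms exceeds the
standard squash's — the saturation-relief property that motivates the
variant. Both properties are asserted numerically on dense grids.

The output capsules are reduced to a 128-dimensional beat embedding by
taking each capsule's maximum component ("maximum over the time
dimension"); reduction by capsule norm is selectable.

### Sequence-to-sequence head

A bidirectional recurrent encoder (LSTM cells by default — the prose
description governs over the schematic vanilla-RNN update equations, which
remain available via `encoder_cell = "rnn"`) runs forward over $t=1..T$ and
backward over $t=T..1$; a learned linear map combines the two hidden states
of each step into the per-step output $y_t$. Encoder initial states are
zero. The decoder is an LSTM whose initial hidden state is a learned map of
the concatenated final encoder states; during training it is teacher-forced
(input = target sequence shifted right, prefixed by a learned `<GO>`
vector), at inference it feeds back its own greedy argmax and never sees
targets. A softmax converts each step's output to class probabilities.

**Per-step decoder context.** The decoder input at step $t$ concatenates
the label embedding with the encoder output $y_t$. The alternative —
passing the sequence only through the final encoder state — is
constructible (`decoder_context = FALSE`) but demonstrably untrainable at
desk scale: a single 256-dimensional state must then carry the identities
of all ten beats, and both the capsule and capsule-free variants stall at
the majority-class solution within the 30-epoch budget of the synthetic
study. The per-step context consumes the $y_t$ that the encoder equations
define (and that otherwise would have no consumer), stays attention-free,
and leaves the many-to-one encoder / many-to-many decoder structure intact.

## Training

Adam (learning rate 0.001), masked sequence cross-entropy, up to 500 epochs
in the reference protocol; the package default is 30 epochs, sized for the
synthetic study. Batch size defaults to 16 sequences: at desk scale (about
100 training sequences) this gives enough optimiser steps per epoch, and it
bounds the routing tensors (d·128·N·18 doubles) on a single CPU. Training
is deterministic for a fixed seed under single-threaded BLAS. An optional
`stop_loss` threshold and early-stopping `patience` are off by default.

All gradients come from a small reverse-mode automatic-differentiation
engine built into the package (dense numeric arrays, a tape of operations,
vector–Jacobian products for each primitive). Finite-difference checks on
toy versions of every block — mixing layer, convolution + routing stack,
bidirectional encoder — are part of the test suite (relative error below
1e-4).

### Numerical choices and initialisation

* Norms are computed as $\sqrt{x + 10^{-12}}$ to keep the squash smooth at
  the origin; the zero-capsule limit is exact (zero in, zero out).
* Softmaxes subtract the row maximum; softplus switches to identity above
  30 to avoid overflow. Argmax ties break to the first index.
* Weights are Glorot/He-initialised by layer type; LSTM forget-gate biases
  start at 1.
* $k_j$ is initialised at $J/\sqrt{I}$ (≈ 30 for $J=128$ output and $I=18$
  input capsules), not at 1: with uniform couplings $1/J$, the coupled sum
  of $I$ incoherent prediction vectors has norm about $\sqrt I/J$ times a
  prediction norm, and the S-S small-signal gain is only $\alpha$; starting
  $k$ at the calibrated scale puts pre-squash norms at order 1, without
  which the embeddings reach the recurrent head at ~1e-3 and training
  stalls at the class prior (measured). $k$ remains free to move during
  training.
* Output capsule dimension defaults to 4. The architecture description
  never states it ("size 3×1" describes the capsule count/kernel, not the
  pose length); the routing tensors scale linearly in it and dominate CPU
  time, and 4 keeps the full study inside desk-scale budgets.

## The synthetic study

`synth_beats()` emulates the *structure* of an annotated arrhythmia
database, not its physiology: each beat is a sum of Gaussian bumps imitating
a P-QRS-T complex with class-dependent parameters (V wide/tall without P, S
early and narrow with a shifted P, F intermediate, Q low-amplitude and
broad), each patient carries a fixed random warp of bump centres, widths
and amplitudes shared across all its beats, labels are i.i.d. from an
N-dominant distribution (defaults 0.90/0.03/0.05/0.015/0.005, mirroring the
imbalance regime of real Holter data), and i.i.d. Gaussian amplitude noise
(sd 0.03) is added before clipping to [0, 1]. The patient-level warp makes
the inter-patient split genuinely harder than a pooled split; with noise
and warp at zero, a nearest-template classifier is perfect, which anchors
the difficulty scale.

What the generator does **not** emulate: baseline wander, electrode noise,
rhythm (RR-interval) structure, label noise, or any correlation between
consecutive beat classes. Tests passing on this data therefore demonstrate
that the implementation can extract class-dependent morphology under
patient shift and imbalance — not that it reaches any particular accuracy
on real ECG. Reproducing the published MIT-BIH results requires downloading
the database and training to the full 500-epoch protocol; the pipeline
supports it (`extract_split_beats()`, `validate_mitbih_counts()` checks the
class-S beat counts of DS1_3 and DS2 against the published 941 and 1836),
but it is an optional integration run, not part of the test suite.

Problem sizes used by the test suite and the acceptance script: the
end-to-end study trains on 10 patients × 100 beats and evaluates on 5 × 100
(about 1,500 beats) for up to 30 epochs; oracle and invariant suites use
randomised small instances (routing up to 6×5×4, 50–100 replicates);
gradient checks run on toy blocks. The ablation comparison
(MWCapsuleNets vs the MLP variant within 2 accuracy points) runs at reduced
scale over three seeds.

## Known limitations

* Single lead only (MLII with a configurable fallback); no multi-lead
  fusion.
* The exact supplementary forms of $f_{ij}$, $k_j$ and the routing
  pseudo-code were not available; the defaults are documented substitutes
  behind pluggable interfaces, not assertions about the published forms.
* Greedy decoding only — no beam search, no attention, per the protocol's
  scope.
* The training loop is single-threaded R; it is sized for desk-scale
  studies, and a full MIT-BIH 500-epoch run, while functional, would be
  slow.
* The parameter count of the default model differs from the published
  252,980 because several widths (capsule pose dimension, decoder sizes)
  are unstated in the source description; the count is logged at build
  time (`build_variant()$n_params`).
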