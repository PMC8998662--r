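---
title: "Feedback-gated Wasserstein GAN for promoter-tuned DNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-gated Wasserstein GAN for promoter-tuned DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(promogan)
```

## The problem

Genomic training data is scarce and often confidential, which motivates
generating synthetic nucleic-acid sequences that carry specific functional
signals — here, bacterial promoter elements and a protein-binding motif.
`promogan` implements a Wasserstein GAN with gradient penalty (WGAN-GP) whose
generated sequences are filtered through two frozen "feedback" networks
before the critic ever sees them: a convolutional promoter classifier and an
explicit position-weight-matrix (PWM) motif scorer. The selection pressure
this gating exerts tunes the generator toward sequences that are
simultaneously (a) indistinguishable from real data to the critic and
(b) carriers of the desired promoter/motif signal.

## Sequence representation

Sequences are one-hot encoded as L x 4 matrices with the fixed channel order
**A, T, C, G** — A = (1,0,0,0), T = (0,1,0,0), C = (0,0,1,0), G = (0,0,0,1).
This ordering (not alphabetical) is the package-wide convention: the
generator's softmax output, the critic input, the predictor input and every
PWM all share it. Ambiguous bases (`N`) are rejected during training and
encoded as the uniform row (0.25, 0.25, 0.25, 0.25) for metric computation;
both policies are explicit arguments of `one_hot_encode()`.

## The adversarial model

The generator maps latent vectors `z ~ N(0, I)` (dimension 100 by default)
through `Linear -> reshape(L, C) -> residual blocks -> Conv1d(C -> 4) ->
position-wise softmax`; each residual block computes `x + r * F(x)` with
`F = ReLU -> Conv1d -> ReLU -> Conv1d` and `r <= 1` (default 0.3). The critic
mirrors it (`Conv1d(4 -> C) -> residual blocks -> flatten -> Linear -> 1`)
and outputs an unbounded real score — no terminal sigmoid, as required by the
Wasserstein formulation. Channel count, block count and kernel length are
deliberately configurable (defaults 64, 5, 5): the architecture family is
fixed, the capacity is not.

Minimized losses:

* critic: `mean(D(fake)) - mean(D(real)) + lambda * mean((||grad_xhat
  D(xhat)|| - 1)^2)` with `xhat = eps * real + (1 - eps) * fake`, one
  `eps ~ U(0, 1)` per batch item, and `lambda = 12`;
* generator: `-mean(D(fake))`.

Five critic updates are performed per generator update. The optimizer is
Adam with learning rate 1e-4 and moment coefficients (0, 0.9), the
conventional setting for gradient-penalty critics. The classical saturating
log-loss GAN objective appears in the documentation only as background; it
is never trained.

### Differentiating the gradient penalty

The penalty's *value* uses the exact input gradient `g = grad_x D(x)`
obtained from one reverse pass. Its gradient with respect to the critic's
weights is a second-order quantity; rather than implementing
double-backpropagation, the package uses the identity
`d/dtheta ||g|| = d/dtheta (ghat . grad_x D)` with `ghat = g / ||g||` held
fixed, and evaluates the directional derivative as a central finite
difference in input space with step `h = 1e-4`:
`(D(x + h ghat) - D(x - h ghat)) / (2h)`. Because the critic is a
composition of convolutions, ReLUs and linear maps, `D` is piecewise linear
in its input, so this difference is *exact* whenever the segment
`[x - h ghat, x + h ghat]` does not straddle an activation kink — a
measure-zero event that at worst perturbs a single step. The resulting
parameter gradients are validated against numerical differentiation in the
test suite (agreement to ~1e-5 on random critics).

### The critic sees soft sequences

The critic consumes the generator's softmax output directly (a continuous
relaxation of a sequence) rather than a sampled hard sequence: this keeps
the generator update differentiable end-to-end. Gating decisions, in
contrast, are made on hard argmax decodings — the objects a downstream user
would actually receive. Ties in the argmax resolve toward the first base in
(A, T, C, G) order.

## The promoter gate

The classifier is a fixed "layered CNN": `[Conv1d -> ReLU -> MaxPool(6) ->
Dropout(0.5)] x 2 -> Flatten -> FullyConnected -> softmax` over four classes
(`none`, `sigma24`, `sigma32`, `sigma54`). A single 4-class head covers both
questions the gate must answer — "is this a promoter?" (argmax != `none`)
and "which sigma subtype?" — without a second hierarchical stage. Pooling is
non-overlapping (stride = window) and keeps a short final window, so no
trailing sequence positions are silently discarded; the input must be at
least 36 long so both stages see one full window. Dropout is active only in
training mode, making inference deterministic. Convolution channels and
kernels default to (32, 64) and (7, 5).

Training minimizes cross-entropy with standard Adam (0.9, 0.999) at learning
rate 1e-2 for 20 epochs by default — on the synthetic task below this
reaches a stable optimum in well under a minute per fold. The predictor is
trained *before* GAN training and frozen throughout it; the package never
fine-tunes the gates against the generator, which would let the generator
corrupt its own referee.

## The motif gate

The evaluator slides a `Len x 4` PWM (rows are per-position base
distributions) along the sequence, takes the inner product with each
window's one-hot encoding — a one-dimensional convolution with the PWM as
the filter — and max-pools over offsets. The raw best-window score is
normalized by the *maximum achievable* window score (the sum of per-position
column maxima), giving a score in (0, 1] for hard sequences that is
comparable across motifs of different lengths and sharpnesses; the fixed
threshold 0.75 is applied to this normalized score with a strict `>`.
The probability-matrix inner product is used as-is (no log-odds transform),
matching the convolutional reading of the scorer. A grid search utility
evaluates thresholds 0.65–0.90 in steps of 0.05 against simulation-known
embedding labels. Reverse-complement scanning exists behind a flag and is
off by default (single-strand scan).

## The feedback step

One feedback step performs, per critic update: draw a real batch; draw
latents and generate a soft batch; hard-decode it; apply the promoter gate,
then the motif gate, *in that order* (a sequence rejected by the predictor
never reaches the evaluator); assemble the critic's fake batch from the soft
outputs whose hard decodings passed both gates. Early in training few or no
sequences pass, so the batch is padded by a fallback: rejected sequences
ranked by `promoter probability x normalized motif score`, recycled if
necessary. The critic must always receive a full batch, and this ranking
preserves the tuning pressure even at a 0% pass rate. After the critic
updates, one generator update maximizes the critic score of its own gated
(and padded) output.

"Training until equilibrium" is operationalized as a plateau rule: stop when
the absolute change between the means of two consecutive
`stop_patience`-step windows of the critic loss falls below 1e-3, capped by
`max_steps`. Real sequences whose length differs from the generator's L are
rejected outright — an explicit error beats silent padding or truncation.

With the predictor and PWM absent (or an accept-all predictor and threshold
0), a feedback step is algebraically — and, by test, bit-for-bit — a plain
WGAN-GP step. All randomness (weight initialization, latent draws, epsilon
draws, batch subsampling, dropout) flows from explicit seeds through named
substreams, so every training run is exactly reproducible.

## Synthetic data

No training corpus ships with the package; `simulate_dataset()` generates
the study conditions instead:

* **background DNA** with a configurable per-base composition (uniform by
  default);
* **motif-bearing sequences**: one PWM-sampled motif instance embedded at a
  uniform random offset with probability `motif_embed_prob`;
* **the 4-class promoter task**: balanced labels over `none`/`sigma24`/
  `sigma32`/`sigma54`, each promoter class embedding its own 12-mer
  consensus (loosely patterned on sigma-factor -35/-10 and -24/-12 box
  elements) with a per-base mutation rate of 0.05 — chosen so the task is
  learnable but not trivially solvable by exact string matching.

What this emulates is the *signal structure* of promoter/motif data: a short
deterministic pattern at an unknown offset in an i.i.d. background. What it
does not emulate: positional preferences of real promoters, correlated
background composition (isochores, repeats), multiple motif copies, or
sequencing noise. Tests passing on these simulations therefore demonstrate
that the machinery works — recovery of planted signal, correct gating,
tuning pressure — not that the models would reach the same accuracy on real
genomic data.

## Evaluation metrics

Original and synthetic sequence sets are vectorized before comparison —
by default into 4 x L per-position base-frequency matrices, optionally into
4^k k-mer frequency vectors (the vectorization is a package choice; both
modes are exposed and reported with their provenance). On the flattened
vectors the package computes the standard Pearson correlation, MAE,
PRD (`100 * sqrt(sum((Or - Sn)^2) / sum(Or^2))`) and RMSE
(`sqrt(mean((Or - Sn)^2))`). Mirror column association is the mean
per-column Pearson correlation between the two matrices, skipping (and
counting) zero-variance columns. The Fréchet distance between the two
column-profile curves is the *discrete* Fréchet distance — minimum over
monotone couplings of the maximum pointwise Euclidean distance — computed by
O(nm) dynamic programming and tested against the exponential recursive
definition. Accuracy, sensitivity and specificity are reported on the 0–100
percent scale and the MCC on [-1, 1]; a zero factor in the MCC denominator
defines the MCC as 0, while a zero sensitivity/specificity denominator is an
error. ROC curves sweep all unique score thresholds with trapezoid-rule
areas.

## Latent-space analyses

* `interpolate()` decodes the affine path between two latent points; the
  endpoints reproduce the unperturbed generations exactly.
* `latent_search()` finds latent preimages of a fixed target sequence by
  Adam descent on the per-position cross-entropy (nats) through the frozen
  generator; restarts above the tolerance (0.1 nats/position by default, 200
  iterations) are discarded.
* `reflect()` negates a latent vector through the origin — the natural
  reflection for a standard-normal prior, and a norm-preserving involution.
  `complementation_report()` tallies, position-wise, which base `G(-z)`
  produces for each base of `G(z)` into a row-stochastic 4 x 4 matrix. A
  generator that has internalized Watson–Crick pairing concentrates mass on
  A<->T and G<->C; this biological claim is a stochastic research finding
  and is reported as a diagnostic, never asserted as a hard test.

## Validation problem sizes

The test suite validates the classifier at its study condition — 10-fold
cross-validation on n = 2000 sequences of length 60 with mutation rate 0.05,
where it is required to exceed 90% accuracy — and demonstrates the feedback
tuning effect on a compact run: L = 20, a sharp 8-mer consensus PWM
(column maximum 0.97), motif-bearing real data, batch 32, 500 steps, one
residual block of 24 channels, learning rate 5e-4. At that scale the mean
normalized motif score of generated batches and the evaluator pass fraction
both rise severalfold between the first and last 50 steps. A 1-position
frequency-matching toy (target 0.7/0.1/0.1/0.1) checks that plain WGAN-GP
training drives the generated base distribution within total-variation 0.1
of the target. These sizes were chosen as the smallest that exhibit the
qualitative regime of interest; all are re-run from scratch by
`scripts/acceptance.R`.

## Known limitations

* The neural-network engine is plain R on BLAS; it is exact and
  reproducible but not fast. Practical runs are tens of channels and
  hundreds of steps, not ImageNet-scale.
* The gradient-penalty weight gradient is exact only away from ReLU kinks
  of the interpolated inputs (see above); empirically this is
  indistinguishable from exact double-backpropagation at h = 1e-4.
* Generated-sequence length is a free parameter (default 50); nothing in
  the method fixes it, and the promoter gate needs L >= 36.
* The evaluator scans one strand by default and scores at most the single
  best window; multiple motif copies earn no extra credit.
* Training small GANs on small data is noisy; seeds are exposed everywhere
  precisely so that runs can be pinned down.
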