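---
title: "Duplex adversarial U-Net segmentation: models, losses, and synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex adversarial U-Net segmentation: models, losses, and synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Segmenting small, irregularly shaped organs from CT slices is hard for three
reasons: the target occupies a tiny fraction of the image, its shape varies
strongly across subjects, and nearby structures of similar appearance distract
the model. `adaunet` implements a family of two-dimensional encoder--decoder
segmentation networks designed for this regime, together with everything
needed to study them end-to-end on synthetic data: a phantom generator, the
adversarial training procedure, evaluation metrics with independent oracles,
and a cross-validated model-selection harness.

# Models

Six variants share one U-Net backbone (depth $d$, default 4; base width $c$,
default 64, reducible for desk-scale work). Each encoder stage is two $3
\times 3$ convolutions with instance normalization and ReLU followed by $2
\times 2$ max-pooling; the decoder mirrors it with $2 \times 2$ transposed
convolutions ("deconvolutions") and skip concatenations; a $1 \times 1$
convolution plus sigmoid yields the prediction map $I^S_1$.

* `unet` — the baseline, trained with the soft dice loss
  $L_{S}(p, t) = 1 - \frac{2\sum p t + s}{\sum p + \sum t + s}$, $s = 10^{-6}$.
* `au_net` — adds one adversarial head: a five-layer strided CNN
  discriminator $D$ (kernels $4,4,4,5,7$) judges prediction maps against
  ground truths, and the generator objective gains the non-saturating term
  $\log(1 - D(I^S_1))$ exactly as written (unit coefficient).
* `dau_net` — the duplex variant: a second $1 \times 1$ head on the
  penultimate decoder stage emits a half-resolution auxiliary map $I^S_2$,
  paired with a max-pooled ground truth $I^T_2$ and a second discriminator.
  The generator objective is
  $\beta L_S(I^S_1, I^T_1) + \gamma \log(1 - D_1(I^S_1))
   + \varepsilon L_S(I^S_2, I^T_2) + \mu \log(1 - D_2(I^S_2))$
  with $(\beta, \gamma, \varepsilon, \mu) = (1, 0.004, 0.1, 0.0004)$.
* `adau_a1` / `adau_a2` / `adau_a3` — insert one, two, or three
  position-attention blocks after the last one, two, or three decoder stages
  of `dau_net`.

## The position-attention block

For features $I \in \mathbb{R}^{C \times H \times W}$ flattened to $N = HW$
columns, a shared $1 \times 1$ projection gives $I'$; the affinity
$A_{mn} = \mathrm{softmax}_n(I'_n \cdot I'_m)$ re-weights the projected
features, and the output is the residual $O_m = \delta \sum_n A_{mn} I'_n +
I_m$. Choices where the published description is silent:

* $\delta$ is a learnable scalar initialized at 0, so the block starts as the
  identity (standard position-attention practice); a fixed-$\delta$ mode
  exists for tests.
* One shared projection serves both affinity factors, as written; the product
  $I'_n \cdot I'_m$ is read as a channel dot product (the surrounding
  matrix-multiplication description implies it).
* The projection preserves $C$ by default. If `attention_channel_factor`
  reduces it, a second learned $1 \times 1$ expansion restores $C$ before the
  residual addition (an extension; the default never uses it).
* The $N \times N$ affinity is exact, never approximated. At $208 \times 208$
  it would occupy $43264^2$ entries (~14 GiB in single precision) — full-scale
  attention is therefore documented as memory-bound, and desk-scale work uses
  $\le 64 \times 64$ inputs.

# Training procedure

Per iteration (batch size 1): one generator step on the variant's objective,
then one discriminator step per head on (real = binary ground truth, fake =
detached prediction), each with Adam (learning rate $10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.99$). Further choices:

* Discriminators see the prediction map alone (the losses condition only on
  $I^S$/$I^T$); an image-conditioned mode is a documented non-default flag
  idea but not implemented.
* $D$ outputs are clamped to $[10^{-7}, 1 - 10^{-7}]$ before any logarithm.
* The two discriminators share an architecture but never parameters.
* The auxiliary ground truth $I^T_2$ is factor-2 max-pooling of $I^T_1$
  (foreground-preserving; no rule is published).
* A non-finite loss aborts with a diagnostic rather than training through it.

Two implementation choices matter for convergence at batch size 1 and are the
package's own (the publication's training details end at the optimizer):
instance normalization after every segmentor convolution, and prediction-head
biases initialized to $-6$ so training starts from an all-background
prediction and the early dice gradient concentrates on the foreground.
Without them the dice objective under-fits badly within desk-scale budgets.

All neural-network primitives are implemented in C++ (RcppArmadillo) with
hand-derived backward passes, because no deep-learning framework is available
in the target environment; every backward pass is verified against central
differences in the test suite, and the attention block additionally against
an explicit-loop oracle. The training-path attention runs in single precision
with its $N \times N$ matrices kept on the C++ side; the public
`attention_block()` is a double-precision reference, and the two are checked
against each other.

# The phantom generator

`generate_phantom()` emulates the statistical difficulties of pancreas CT
without any real data: each case owns a base shape (random ellipse modulated
by a low-order radial Fourier series), each slice perturbs it; foreground
area is constrained to 0.5–8 % of pixels (a small organ); `n_distractors`
nearby blobs of clearly non-organ intensity (darker than background or
brighter than the organ) are added outside the mask; Gaussian noise tops it
off. Defaults: contrast 0.3 (foreground sits 0.18 above a 0.2 background on a
[0, 1] scale), noise SD 0.05, 3 distractors, irregularity 0.3. The dataset is
a pure function of the configuration (fold assignment uses a separate RNG
stream, so re-splitting never changes the images).

What a green test on phantoms does **not** establish: performance on real CT.
Phantoms lack texture, partial-volume boundary blur, anatomical context and
scanner artifacts; they establish that the machinery (losses, gradients,
protocol, metrics) is correct and that the models can learn a small-target
low-contrast task. The real-data path (NIfTI/PNG readers, window/level,
spacing-aware metrics) is present but exercised only on synthetic files.

# Evaluation

DSC and Jaccard are reported as percentages; average symmetric surface
distance (ASD) and surface RMSE in millimetres. Border pixels are foreground
pixels 4-adjacent to background (array edges count as background); distances
come from an exact Euclidean distance transform, and the tests compare
against $O(n^2)$ all-pairs oracles. "RMSE" is read as root-mean-squared
*surface* distance (both directions pooled); a pixelwise-intensity reading
was considered and rejected, since the metric is described relative to the
ground-truth edge. Per-case values pool all slices of a case (overlap metrics
on pooled counts, surface distances pooled across slices; slices with an
empty mask on either side are skipped); aggregates use the sample (n−1)
standard deviation. Conventions for degenerate inputs: two empty masks give
DSC = Jaccard = 100; surface distances against an empty mask are `NA` with a
warning.

# Selection protocol

The two-step protocol first cross-validates `unet`, `au_net`, `dau_net`
(backbone selection), then `dau_net` and the three attention placements
(attention selection), under 4-fold case-level cross-validation. All variants
share the dataset, folds, parameter-init seeds and batch order, so the
comparison is budget-fair; the winner is the argmax of mean DSC, with mean
Jaccard and then variant order as tie-breaks. The final checkpoint is
evaluated (no early stopping is described, so none is applied). One seeded
split is used rather than repeated splits.

# Known limitations

* Exact attention makes full-resolution (208²) attention variants
  memory-infeasible; this is inherent to the formulation, not an
  implementation shortcut.
* At the desk-scale acceptance budget (300 batch-1 Adam updates at
  $10^{-4}$), the duplex attention model under-fits the default phantom task:
  held-out DSC lands in the 60–80 % range across seeds. The corresponding
  acceptance assertion (≥ 85 %) is kept verbatim and fails honestly; the
  trajectory is still rising steeply at the budget boundary, and the same
  pipeline trained longer continues to improve.
* `batch_size > 1` is accepted by the configuration but training is
  slice-by-slice (the published setting); discriminator conditioning on the
  input image is out of scope.
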