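# adaunet

Segmenting small, irregular, low-contrast structures — the pancreas in
abdominal CT being the canonical case — strains plain encoder–decoder
networks: the target covers a tiny fraction of each slice, its shape varies
strongly between cases, and nearby structures distract the model. `adaunet`
implements, as a tested R library with a CLI, a family of 2-D segmentation
networks built for this regime:

- **U-Net** baseline trained with the soft dice loss
  `L_S(p, t) = 1 − (2·Σpt + s) / (Σp + Σt + s)`;
- **AU-Net**: U-Net + one adversarial head — a five-layer strided CNN
  discriminator `D` (kernels 4, 4, 4, 5, 7) scores prediction maps against
  ground truths, adding `log(1 − D(I1S))` to the generator objective;
- **DAU-Net** (duplex): a second 1×1 head on the penultimate decoder stage
  emits a half-resolution auxiliary map judged by a second discriminator; the
  generator minimizes
  `β·L_S(I1S, I1T) + γ·log(1 − D1(I1S)) + ε·L_S(I2S, I2T) + μ·log(1 − D2(I2S))`
  with `(β, γ, ε, μ) = (1, 0.004, 0.1, 0.0004)`;
- **ADAU-Net-A1/A2/A3**: DAU-Net with 1/2/3 position-attention blocks after
  the last 1/2/3 decoder stages. Each block forms the row-stochastic spatial
  affinity `A[m, n] = softmax_n(I'_n · I'_m)` from 1×1-projected features and
  adds back `δ·Σ_n A[m, n]·I'_n` as a residual (`δ` learnable, init 0).

Because no deep-learning framework exists in the target environment, all
network primitives (convolution, transposed convolution, max-pooling,
instance norm, position attention, Adam) are implemented in
C++/RcppArmadillo with hand-derived backward passes, each verified against
numerical gradients and explicit-loop oracles in the test suite.

The package also provides:

- a **synthetic phantom generator** reproducing the statistical difficulties
  above (per-case base shape = random ellipse + radial Fourier perturbation,
  per-slice variation, 0.5–8 % foreground area, nearby distractor blobs,
  Gaussian noise), fully determined by its seed;
- **evaluation metrics** — DSC and Jaccard (%), average symmetric surface
  distance and surface RMSE (mm) via an exact Euclidean distance transform,
  with per-case pooling and mean ± sd [min, max] aggregation;
- a **4-fold cross-validation harness** for the two-step selection protocol
  (backbone selection among U-Net/AU-Net/DAU-Net, then attention placement),
  with budget-fair seeding and deterministic reports;
- **I/O** for PNG image/mask pairs (16-bit images) and NIfTI-1 volumes, plus
  YAML-driven CLI subcommands (`synth`, `train`, `eval`, `select-backbone`,
  `select-attention`, `report`).

## Worked example

Train the final duplex-attention model on 64×64 phantoms (12 cases × 8
slices, three folds for training, one held out) under the desk-scale budget —
300 batch-1 Adam iterations at learning rate 1e-4 — and evaluate per held-out
case (~5 min on one CPU):

```r
library(adaunet)

pc <- phantom_config(image_size = 64L, n_cases = 12L, slices_per_case = 8L, seed = 11)
ds <- generate_dataset(pc)
cases      <- vapply(ds$slices, function(s) s$case_id, 1L)
test_cases <- as.integer(names(ds$folds)[ds$folds == 0])
train <- ds$slices[!cases %in% test_cases]
test  <- ds$slices[cases %in% test_cases]

model <- build_segmentor(segmentor_config("adau_a2", base_channels = 16L), seed = 21)
discs <- list(build_discriminator(seed = 22), build_discriminator(seed = 23))
hist  <- train_segmentor(model, discs, train, train_config(iterations = 300L, seed = 31))

evaluate_segmentation(
  lapply(test, function(s) seg_forward(model, s$image)$main_map),
  lapply(test, function(s) s$mask),
  vapply(test, function(s) s$case_id, 1L))
#> <eval_report> 3 case(s)
#>   dsc      78.79 +/-  4.87 [ 75.55,  84.39]%
#>   jaccard  65.19 +/-  6.79 [ 60.71,  73.00]%
#>   asd       1.52 +/-  0.33 [  1.15,   1.75] mm
#>   rmse      3.36 +/-  1.20 [  2.29,   4.66] mm
```

Reading the report: each row of `per_case` pools all slices of one held-out
case; `dsc`/`jaccard` are overlap percentages (100 = perfect), `asd`/`rmse`
measure how far the predicted border sits from the true border in mm
(0 = perfect). The aggregate line is mean ± sample sd over cases with
[min, max]. The training history (`hist`) logs every loss component
(`L_S1`, `L_adv1`, `L_S2`, `L_adv2`, `L_D1`, `L_D2`) per iteration.

The attention block is also exposed directly:

```r
x <- array(rnorm(6 * 6 * 8, sd = 0.5), c(6, 6, 8))
out <- attention_block(x, delta = 0.5, return_attention = TRUE)
range(rowSums(attr(out, "attention")))   # each of the 36 rows sums to 1
#> [1] 1 1
```

## CLI

```sh
Rscript inst/cli/adaunet synth --config cfg.yaml --out run/data --format png
Rscript inst/cli/adaunet select-backbone --config cfg.yaml --out run/backbone
Rscript inst/cli/adaunet eval --pred run/pred --truth run/truth --out report.csv
```

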