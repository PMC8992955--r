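## Synthetic low-contrast phantoms emulating what makes pancreas CT hard:
## a small, irregularly shaped foreground (random ellipse plus low-order
## radial Fourier perturbation, different base shape per case, perturbed per
## slice), nearby brighter/darker distractor blobs that are NOT part of the
## mask, and additive Gaussian noise.  Everything is a pure function of
## (config, case_seed, slice index).

#' Phantom dataset configuration
#'
#' @param image_size Side length of the square slices (default 208).
#' @param n_cases Number of synthetic cases (volumes).
#' @param slices_per_case Slices generated per case.
#' @param contrast Foreground/background intensity gap scale in `(0, 1]`
#'   (default 0.3: low contrast).
#' @param noise_sd Additive Gaussian noise standard deviation (default 0.05).
#' @param n_distractors Number of nearby non-target blobs (default 3).
#' @param shape_irregularity Amplitude of the radial Fourier boundary
#'   perturbation (default 0.3).
#' @param area_bounds Allowed foreground area fraction interval
#'   (default 0.005 to 0.08, i.e. a small organ).
#' @param seed Master seed; fully determines the dataset.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 208L, n_cases = 12L,
                           slices_per_case = 8L, contrast = 0.3,
                           noise_sd = 0.05, n_distractors = 3L,
                           shape_irregularity = 0.3,
                           area_bounds = c(0.005, 0.08), seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop("image_size must be >= 16")
  if (contrast <= 0 || contrast > 1)
    stop("contrast must be in (0, 1]: a zero gap would make the mask unlearnable")
  stopifnot(n_cases >= 1L, slices_per_case >= 1L, noise_sd >= 0,
            n_distractors >= 0L, shape_irregularity >= 0,
            length(area_bounds) == 2L, area_bounds[1] > 0,
            area_bounds[2] > area_bounds[1], area_bounds[2] < 1)
  structure(list(image_size = image_size, n_cases = as.integer(n_cases),
                 slices_per_case = as.integer(slices_per_case),
                 contrast = contrast, noise_sd = noise_sd,
                 n_distractors = as.integer(n_distractors),
                 shape_irregularity = shape_irregularity,
                 area_bounds = area_bounds, seed = as.integer(seed)),
            class = "phantom_config")
}

BG_LEVEL <- 0.2
FG_GAIN <- 0.6   # foreground = BG_LEVEL + FG_GAIN * contrast

## deterministic sub-stream seed, kept below 2^31
substream_seed <- function(seed, a, b = 0L) {
  ((as.double(seed) %% 65536) * 31657 + a * 131 + b * 7 + 11) %% 2147483647
}

## radial boundary: ellipse radius modulated by Fourier terms k = 2..5
blob_mask <- function(n, center, axes, angle, four_a, four_b, scale) {
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- (jj - center[2])
  dy <- (ii - center[1])
  rx <- cos(angle) * dx + sin(angle) * dy
  ry <- -sin(angle) * dx + cos(angle) * dy
  th <- atan2(ry / axes[2], rx / axes[1])
  mod <- rep(1, length(th))
  for (k in seq_along(four_a))
    mod <- mod + four_a[k] * cos((k + 1) * th) + four_b[k] * sin((k + 1) * th)
  mod <- pmax(mod, 0.3)
  r <- sqrt((rx / axes[1])^2 + (ry / axes[2])^2)
  m <- (r <= scale * mod) * 1
  dim(m) <- c(n, n)
  m
}

## bisect the global radial scale until the discrete area fraction is in bounds
fit_blob <- function(n, center, axes, angle, four_a, four_b, target_frac,
                     bounds) {
  scale <- 1
  m <- blob_mask(n, center, axes, angle, four_a, four_b, scale)
  for (i in 1:12) {
    f <- sum(m) / n^2
    if (f >= bounds[1] && f <= bounds[2]) return(m)
    scale <- scale * sqrt(target_frac / max(f, 1 / n^2))
    m <- blob_mask(n, center, axes, angle, four_a, four_b, scale)
  }
  ## fall back: binary search against the lower bound
  lo <- 0; hi <- scale * 4
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    m <- blob_mask(n, center, axes, angle, four_a, four_b, mid)
    f <- sum(m) / n^2
    if (f < bounds[1]) lo <- mid else if (f > bounds[2]) hi <- mid else break
  }
  m
}

case_params <- function(config, case_seed) {
  set.seed(substream_seed(config$seed, case_seed, 1L))
  n <- config$image_size
  list(center = c(stats::runif(1, 0.35, 0.65), stats::runif(1, 0.35, 0.65)) * n,
       aspect = stats::runif(1, 0.5, 1),
       angle = stats::runif(1, 0, pi),
       four_a = stats::rnorm(4, 0, config$shape_irregularity / 3),
       four_b = stats::rnorm(4, 0, config$shape_irregularity / 3),
       target_frac = stats::runif(1, config$area_bounds[1] * 1.5,
                                  config$area_bounds[2] * 0.85))
}

#' Generate one phantom slice
#'
#' The per-case base shape comes from `(config$seed, case_seed)`; each slice
#' adds a small seeded perturbation of center, size and boundary, distractor
#' blobs of distinct intensity near (but outside) the target, and Gaussian
#' noise. Identical `(config, case_seed, slice)` reproduce identical output.
#'
#' @param config A [phantom_config()].
#' @param case_seed Integer case identifier/seed.
#' @param slice Slice index within the case.
#' @return A `phantom_slice` list: `image` (H x W in `[0, 1]`), binary
#'   `mask`, `case_id`, `slice_id`.
#' @export
generate_phantom <- function(config, case_seed, slice = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  cp <- case_params(config, case_seed)
  set.seed(substream_seed(config$seed, case_seed, 100L + slice))
  n <- config$image_size
  center <- cp$center + stats::rnorm(2, 0, 0.02 * n)
  center <- pmin(pmax(center, 0.25 * n), 0.75 * n)
  target_frac <- cp$target_frac * stats::runif(1, 0.85, 1.15)
  target_frac <- min(max(target_frac, config$area_bounds[1] * 1.2),
                     config$area_bounds[2] * 0.9)
  ## axes from the target area: pi*a*b = frac*n^2, b = aspect*a
  a0 <- sqrt(target_frac * n^2 / (pi * cp$aspect))
  axes <- c(a0, a0 * cp$aspect)
  four_a <- cp$four_a + stats::rnorm(4, 0, config$shape_irregularity / 10)
  four_b <- cp$four_b + stats::rnorm(4, 0, config$shape_irregularity / 10)
  mask <- fit_blob(n, center, axes, cp$angle, four_a, four_b, target_frac,
                   config$area_bounds)
  fg <- BG_LEVEL + FG_GAIN * config$contrast
  img <- BG_LEVEL + (fg - BG_LEVEL) * mask
  if (config$n_distractors > 0L) {
    for (d in seq_len(config$n_distractors)) {
      off_dir <- stats::runif(1, 0, 2 * pi)
      off_len <- stats::runif(1, 0.15, 0.35) * n
      dc <- center + off_len * c(cos(off_dir), sin(off_dir))
      dc <- pmin(pmax(dc, 3), n - 2)
      da <- max(2, sqrt(stats::runif(1, 0.3, 1) * target_frac * n^2 / pi))
      dm <- blob_mask(n, dc, c(da, da * stats::runif(1, 0.6, 1)),
                      stats::runif(1, 0, pi),
                      stats::rnorm(3, 0, 0.1), stats::rnorm(3, 0, 0.1), 1)
      dm <- dm * (1 - mask)                  # never part of the organ
      ## distractors sit clearly outside the organ's intensity band (darker
      ## than background or brighter than the organ by >= one contrast gap)
      lvl <- if (stats::runif(1) < 0.5) -0.75 else 2
      img <- img + lvl * FG_GAIN * config$contrast * dm
    }
  }
  if (config$noise_sd > 0)
    img <- img + stats::rnorm(n * n, 0, config$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(n, n)
  structure(list(image = img, mask = mask, case_id = as.integer(case_seed),
                 slice_id = as.integer(slice)),
            class = "phantom_slice")
}

#' Assign cases to 4 folds
#'
#' Case-level random partition into 4 folds of as-equal-as-possible size; the
#' fold RNG stream is separate from the phantom stream, so resplitting never
#' changes the images.
#'
#' @param case_ids Integer case ids.
#' @param seed Seed for the fold shuffle.
#' @return Named integer vector case_id -> fold in 0..3.
#' @export
assign_folds <- function(case_ids, seed = 1L) {
  if (length(case_ids) < 4L)
    stop("4-fold cross-validation needs at least 4 cases")
  set.seed(substream_seed(seed, 999983L))
  perm <- sample(case_ids)
  stats::setNames(rep(0:3, length.out = length(perm)), perm)
}

#' Generate a full phantom dataset with fold assignment
#'
#' @param config A [phantom_config()] with `n_cases >= 4`.
#' @return A `phantom_dataset` list: `slices` (length
#'   `n_cases * slices_per_case`), `folds` (case -> fold), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_cases < 4L)
    stop("insufficient cases for 4-fold CV (need n_cases >= 4)")
  slices <- vector("list", config$n_cases * config$slices_per_case)
  i <- 1L
  for (cs in seq_len(config$n_cases)) {
    for (sl in seq_len(config$slices_per_case)) {
      slices[[i]] <- generate_phantom(config, cs, sl)
      i <- i + 1L
    }
  }
  folds <- assign_folds(seq_len(config$n_cases), config$seed)
  structure(list(slices = slices, folds = folds, config = config),
            class = "phantom_dataset")
}

#' Label-guided crop
#'
#' Crops a `target x target` window centered on the mask's bounding box
#' (clamped to the image bounds) from both image and mask; the whole
#' foreground is contained whenever it fits in the window. An empty mask
#' falls back to a center crop with a warning.
#'
#' @param image,mask Equal-shaped matrices.
#' @param target Output side length, `<= min(dim)`.
#' @param method `"crop"` (default) or `"resize"` (bilinear image / nearest
#'   mask interpolation to `target x target`).
#' @return List with cropped `image` and `mask`.
#' @export
crop_resize <- function(image, mask, target, method = c("crop", "resize")) {
  method <- match.arg(method)
  stopifnot(identical(dim(image), dim(mask)))
  if (method == "resize") {
    return(list(image = resize_bilinear(image, target),
                mask = (resize_nearest(mask, target) > 0.5) * 1))
  }
  H <- nrow(image); W <- ncol(image)
  if (target > min(H, W)) stop("target larger than image")
  if (sum(mask) == 0) {
    warning("crop_resize: empty mask, falling back to center crop")
    ctr <- c(H, W) / 2
  } else {
    rr <- range(which(rowSums(mask) > 0))
    cc <- range(which(colSums(mask) > 0))
    ctr <- c(mean(rr), mean(cc))
  }
  r0 <- min(max(round(ctr[1] - target / 2) + 1L, 1L), H - target + 1L)
  c0 <- min(max(round(ctr[2] - target / 2) + 1L, 1L), W - target + 1L)
  idx_r <- r0:(r0 + target - 1L)
  idx_c <- c0:(c0 + target - 1L)
  list(image = image[idx_r, idx_c], mask = mask[idx_r, idx_c])
}

resize_bilinear <- function(x, target) {
  H <- nrow(x); W <- ncol(x)
  ri <- (seq_len(target) - 0.5) * H / target + 0.5
  ci <- (seq_len(target) - 0.5) * W / target + 0.5
  r0 <- pmin(pmax(floor(ri), 1L), H); r1 <- pmin(r0 + 1L, H)
  c0 <- pmin(pmax(floor(ci), 1L), W); c1 <- pmin(c0 + 1L, W)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a <- x[r0, c0]; b <- x[r1, c0]; cc <- x[r0, c1]; d <- x[r1, c1]
  a * outer(1 - fr, 1 - fc) + b * outer(fr, 1 - fc) +
    cc * outer(1 - fr, fc) + d * outer(fr, fc)
}

resize_nearest <- function(x, target) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(round((seq_len(target) - 0.5) * H / target + 0.5), 1L), H)
  ci <- pmin(pmax(round((seq_len(target) - 0.5) * W / target + 0.5), 1L), W)
  x[ri, ci]
}
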