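## Discriminators and the adversarial training procedure.  The discriminator
## is a five-layer strided CNN (kernels 4,4,4,5,7 by default) reducing a
## prediction/truth map to a single probability; the segmentor plays the
## generator of a GAN.  Losses follow the non-saturating log(1 - D) form as
## printed; D outputs are clamped away from {0, 1} before any log.

D_CLAMP <- 1e-7

#' Discriminator configuration
#'
#' @param kernel_sizes Convolution kernel sizes (5 stride-2 layers by
#'   default: 4, 4, 4, 5, 7).
#' @param channels Output channels per layer; the final layer must have 1.
#' @param strides Strides per layer.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(kernel_sizes = c(4L, 4L, 4L, 5L, 7L),
                                 channels = c(64L, 128L, 256L, 512L, 1L),
                                 strides = rep(2L, 5L)) {
  stopifnot(length(kernel_sizes) == length(channels),
            length(strides) == length(channels),
            channels[length(channels)] == 1L)
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 channels = as.integer(channels),
                 strides = as.integer(strides)),
            class = "discriminator_config")
}

#' Build a discriminator network
#'
#' @param config A [discriminator_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An `adaunet_disc` object.
#' @export
build_discriminator <- function(config = discriminator_config(), seed = 1L) {
  stopifnot(inherits(config, "discriminator_config"))
  set.seed(as.integer(seed))
  nl <- length(config$channels)
  prev <- 1L
  layers <- vector("list", nl)
  for (i in seq_len(nl)) {
    layers[[i]] <- nn_conv(prev, config$channels[i], config$kernel_sizes[i],
                           stride = config$strides[i])
    prev <- config$channels[i]
  }
  d <- new.env(parent = emptyenv())
  d$config <- config
  d$layers <- layers
  class(d) <- "adaunet_disc"
  d
}

## forward with cache; scalar output = sigmoid(mean(last feature map))
disc_forward_full <- function(d, x) {
  nl <- length(d$layers)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- as_chw(x)
  pre <- vector("list", nl)
  for (i in seq_len(nl)) {
    z <- conv_fwd(d$layers[[i]], acts[[i]])
    pre[[i]] <- z
    acts[[i + 1L]] <- if (i < nl) lrelu_fwd(z) else z
  }
  u <- mean(acts[[nl + 1L]])
  list(p = sigmoid(u), u = u, acts = acts, pre = pre)
}

#' Discriminator probability for a map
#' @param disc An `adaunet_disc`.
#' @param x H x W map (matrix) to judge.
#' @return Scalar probability that `x` is a ground truth.
#' @export
disc_forward <- function(disc, x) disc_forward_full(disc, x)$p

## backward from dL/dp; returns gradient w.r.t. the input map and accumulates
## parameter gradients
disc_backward <- function(d, fw, g_p, params = TRUE) {
  nl <- length(d$layers)
  g_u <- g_p * fw$p * (1 - fw$p)
  last <- fw$acts[[nl + 1L]]
  gx <- array(g_u / length(last), dim(last))
  for (i in rev(seq_len(nl))) {
    if (i < nl) gx <- lrelu_bwd(fw$pre[[i]], gx)
    gx <- conv_bwd(d$layers[[i]], fw$acts[[i]], gx, params = params)
  }
  gx[, , 1L]
}

#' Composite-loss weights
#'
#' The four coefficients of the duplex generator objective: `beta` on the main
#' dice term, `gamma` on the main adversarial term, `epsilon` on the auxiliary
#' dice term and `mu` on the auxiliary adversarial term (defaults 1, 0.004,
#' 0.1, 0.0004).
#'
#' @param beta,gamma,epsilon,mu Nonnegative reals.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(beta = 1, gamma = 0.004, epsilon = 0.1,
                         mu = 0.0004) {
  stopifnot(beta >= 0, gamma >= 0, epsilon >= 0, mu >= 0)
  structure(list(beta = beta, gamma = gamma, epsilon = epsilon, mu = mu),
            class = "loss_weights")
}

DICE_SMOOTH <- 1e-6

#' Soft dice loss
#'
#' `1 - (2 * sum(pred * truth) + s) / (sum(pred) + sum(truth) + s)` with
#' smoothing `s = 1e-6` in numerator and denominator (so identical masks give
#' exactly 0 and the empty/empty case is defined as 0).
#'
#' @param pred Probability map in `[0, 1]`.
#' @param truth Binary map of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("dice_loss: shape mismatch")
  den <- sum(pred) + sum(truth) + DICE_SMOOTH
  1 - (2 * sum(pred * truth) + DICE_SMOOTH) / den
}

## gradient of dice_loss w.r.t. pred
dice_loss_grad <- function(pred, truth) {
  den <- sum(pred) + sum(truth) + DICE_SMOOTH
  num <- 2 * sum(pred * truth) + DICE_SMOOTH
  -(2 * truth * den - num) / den^2
}

clamp01 <- function(p) pmin(pmax(p, D_CLAMP), 1 - D_CLAMP)

#' Generator-side adversarial term
#'
#' `mean(log(1 - d))` over a batch of discriminator outputs on fakes (the
#' expectation over the generator distribution); outputs are clamped to
#' `[1e-7, 1 - 1e-7]` first.
#'
#' @param d_out Discriminator probabilities on generated maps.
#' @return Scalar (nonpositive).
#' @export
adversarial_gen_term <- function(d_out) {
  mean(log(1 - clamp01(d_out)))
}

#' Discriminator loss
#'
#' `-mean(log(d_real)) - mean(log(1 - d_fake))`; the same formula serves both
#' duplex heads.
#'
#' @param d_real Discriminator outputs on ground truths.
#' @param d_fake Discriminator outputs on predictions.
#' @return Scalar, nonnegative, minimized at (1, 0).
#' @export
discriminator_loss <- function(d_real, d_fake) {
  -mean(log(clamp01(d_real))) - mean(log(1 - clamp01(d_fake)))
}

#' Duplex generator loss
#'
#' `beta * dice(I1S, I1T) + gamma * mean(log(1 - d1_fake)) +
#'  epsilon * dice(I2S, I2T) + mu * mean(log(1 - d2_fake))`.
#'
#' @param out A `segmentor_output` with both heads.
#' @param gt A [ground_truth_pair()].
#' @param d1_fake,d2_fake Discriminator outputs on the two prediction maps.
#' @param w A [loss_weights()].
#' @return List with `total` and the four components
#'   (`L_S1`, `L_adv1`, `L_S2`, `L_adv2`).
#' @export
duplex_generator_loss <- function(out, gt, d1_fake, d2_fake,
                                  w = loss_weights()) {
  if (is.null(out$aux_map)) stop("duplex_generator_loss: missing aux head")
  L_S1 <- dice_loss(out$main_map, gt$full)
  L_adv1 <- adversarial_gen_term(d1_fake)
  L_S2 <- dice_loss(out$aux_map, gt$half)
  L_adv2 <- adversarial_gen_term(d2_fake)
  list(total = w$beta * L_S1 + w$gamma * L_adv1 +
               w$epsilon * L_S2 + w$mu * L_adv2,
       L_S1 = L_S1, L_adv1 = L_adv1, L_S2 = L_S2, L_adv2 = L_adv2)
}

#' Downsample a ground-truth mask for the auxiliary head
#'
#' Factor-2 max-pooling: a half-resolution cell is foreground iff any of its
#' four source pixels is (foreground-preserving).
#'
#' @param full Binary matrix with even side lengths.
#' @return Binary matrix of half the size.
#' @export
downsample_gt <- function(full) {
  H <- nrow(full); W <- ncol(full)
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("downsample_gt: side lengths must be even")
  y <- maxpool2_fwd_cpp(array(full, c(H, W, 1L)))$y[, , 1L]
  (y > 0.5) * 1
}

#' Ground-truth pair for duplex training
#' @param full Binary H x W mask.
#' @return List with `full` and its max-pooled `half`.
#' @export
ground_truth_pair <- function(full) {
  list(full = full, half = downsample_gt(full))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param adam_beta1,adam_beta2 Adam momentum coefficients (0.9, 0.99).
#' @param batch_size Currently 1 (slice-by-slice updates).
#' @param iterations Number of generator updates.
#' @param seed RNG seed driving batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.99, batch_size = 1L,
                         iterations = 300L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, iterations >= 0L)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "train_config")
}

mean_val_dsc <- function(model, slices, threshold = 0.5) {
  mean(vapply(slices, function(s) {
    p <- seg_forward(model, s$image)$main_map
    dsc((p >= threshold) * 1, s$mask)
  }, 1.0))
}

#' Train a segmentor (optionally adversarially)
#'
#' Alternates, per iteration, a generator step on the variant's objective
#' (dice for `unet`; dice + log(1 - D) for `au_net`; the four-term duplex
#' loss for all duplex variants) with one discriminator step per head on
#' (real = ground truth, fake = detached prediction). Fully seeded: the batch
#' order is a pure function of `tc$seed`.
#'
#' @param model An `adaunet_model`.
#' @param discs List of `adaunet_disc` (0, 1 or 2, matching the variant).
#' @param data List of `phantom_slice` records (training set).
#' @param tc A [train_config()].
#' @param w A [loss_weights()].
#' @param val_data Optional held-out slices for periodic validation DSC.
#' @param val_every Validation period in iterations.
#' @return A `train_history` data frame (iteration, loss components,
#'   `val_DSC`, `NA` between validation points).
#' @export
train_segmentor <- function(model, discs = list(), data, tc = train_config(),
                            w = loss_weights(), val_data = NULL,
                            val_every = 50L) {
  stopifnot(length(data) >= 1L)
  nh <- model$config$n_adv_heads
  if (length(discs) != nh)
    stop("variant ", model$config$variant, " needs ", nh, " discriminator(s)")
  gl <- model_layers(model)
  dl <- lapply(discs, function(d) d$layers)
  set.seed(tc$seed)
  order_pool <- integer(0)
  hist <- data.frame(iteration = seq_len(tc$iterations),
                     L_S1 = NA_real_, L_adv1 = NA_real_, L_S2 = NA_real_,
                     L_adv2 = NA_real_, L_D1 = NA_real_, L_D2 = NA_real_,
                     val_DSC = NA_real_)
  duplex <- model$config$duplex
  for (it in seq_len(tc$iterations)) {
    if (length(order_pool) == 0L) order_pool <- sample.int(length(data))
    s <- data[[order_pool[1L]]]
    order_pool <- order_pool[-1L]
    gt <- if (duplex) ground_truth_pair(s$mask) else list(full = s$mask)

    ## ---- generator step ----
    fw <- seg_forward_full(model, s$image)
    p1 <- sigmoid(fw$logit1)
    L_S1 <- dice_loss(p1, gt$full)
    g_p1 <- dice_loss_grad(p1, gt$full)
    d_fw1 <- NULL; d_fw2 <- NULL
    if (nh >= 1L) {
      d_fw1 <- disc_forward_full(discs[[1L]], p1)
      la1 <- log(1 - clamp01(d_fw1$p))
      hist$L_adv1[it] <- la1
      wa1 <- if (duplex) w$gamma else 1     # the AU-Net loss has no weight
      g_d1 <- -wa1 / (1 - clamp01(d_fw1$p))
      g_p1 <- (if (duplex) w$beta else 1) * g_p1 +
        disc_backward(discs[[1L]], d_fw1, g_d1, params = FALSE)
    }
    g_logit1 <- g_p1 * p1 * (1 - p1)
    g_logit2 <- NULL
    if (duplex) {
      p2 <- sigmoid(fw$logit2)
      L_S2 <- dice_loss(p2, gt$half)
      hist$L_S2[it] <- L_S2
      g_p2 <- w$epsilon * dice_loss_grad(p2, gt$half)
      d_fw2 <- disc_forward_full(discs[[2L]], p2)
      hist$L_adv2[it] <- log(1 - clamp01(d_fw2$p))
      g_p2 <- g_p2 + disc_backward(discs[[2L]], d_fw2,
                                   -w$mu / (1 - clamp01(d_fw2$p)),
                                   params = FALSE)
      g_logit2 <- g_p2 * p2 * (1 - p2)
    }
    hist$L_S1[it] <- L_S1
    ## discriminator parameter grads picked up during the G step are discarded
    zero_grads(gl)
    seg_backward(model, fw, g_logit1, g_logit2)
    adam_step(gl, tc$learning_rate, tc$adam_beta1, tc$adam_beta2, it)

    ## ---- discriminator step(s); the fake branch reuses the pre-update
    ## forward pass (predictions are detached either way) ----
    if (nh >= 1L) {
      hist$L_D1[it] <- disc_step(discs[[1L]], gt$full, d_fw1, tc, it)
      if (nh >= 2L)
        hist$L_D2[it] <- disc_step(discs[[2L]], gt$half, d_fw2, tc, it)
    }

    bad <- c(hist$L_S1[it], hist$L_adv1[it], hist$L_S2[it], hist$L_adv2[it],
             hist$L_D1[it], hist$L_D2[it])
    if (any(!is.finite(bad) & !is.na(bad)))
      stop("non-finite loss at iteration ", it, ": ",
           paste(sprintf("%.4g", bad), collapse = ", "))
    if (!is.null(val_data) && (it %% val_every == 0L || it == tc$iterations))
      hist$val_DSC[it] <- mean_val_dsc(model, val_data)
  }
  structure(hist, class = c("train_history", "data.frame"))
}

disc_step <- function(disc, real, ff, tc, t) {
  zero_grads(disc$layers)
  fr <- disc_forward_full(disc, real)
  L <- discriminator_loss(fr$p, ff$p)
  disc_backward(disc, fr, -1 / clamp01(fr$p))
  disc_backward(disc, ff, 1 / (1 - clamp01(ff$p)))
  adam_step(disc$layers, tc$learning_rate, tc$adam_beta1, tc$adam_beta2, t)
  L
}
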