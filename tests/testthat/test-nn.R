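# Gradient correctness of every hand-derived backward pass, checked against
# central differences on tiny tensors.

loss_of <- function(y) sum(sin(y))
gy_of <- function(y) cos(y)

test_that("convolution gradients match numerical differentiation", {
  set.seed(1)
  for (case in list(list(k = 3L, s = 1L, H = 5L, W = 4L),
                    list(k = 4L, s = 2L, H = 8L, W = 8L),
                    list(k = 7L, s = 2L, H = 8L, W = 8L))) {
    l <- ns$nn_conv(2L, 3L, case$k, stride = case$s)
    x <- array(rnorm(case$H * case$W * 2), c(case$H, case$W, 2L))
    y <- ns$conv_fwd(l, x)
    ns$zero_grads(list(l))
    gx <- ns$conv_bwd(l, x, gy_of(y))
    expect_lt(max(abs(gx - num_grad(function(z) loss_of(ns$conv_fwd(l, z)), x))),
              1e-6)
    W0 <- l$Wm + 0
    gW_num <- num_grad(function(w) {
      l$Wm <- w; on.exit(l$Wm <- W0)
      loss_of(ns$conv_fwd(l, x))
    }, W0)
    expect_lt(max(abs(l$gWm - gW_num)), 1e-6)
  }
})

test_that("transposed-convolution gradients match numerical differentiation", {
  set.seed(2)
  l <- ns$nn_tconv(3L, 2L)
  x <- array(rnorm(3 * 4 * 3), c(3L, 4L, 3L))
  y <- ns$tconv_fwd(l, x)
  expect_identical(dim(y), c(6L, 8L, 2L))
  ns$zero_grads(list(l))
  gx <- ns$tconv_bwd(l, x, gy_of(y))
  expect_lt(max(abs(gx - num_grad(function(z) loss_of(ns$tconv_fwd(l, z)), x))),
            1e-6)
  M0 <- l$M + 0
  gM_num <- num_grad(function(w) {
    l$M <- w; on.exit(l$M <- M0)
    loss_of(ns$tconv_fwd(l, x))
  }, M0)
  expect_lt(max(abs(l$gM - gM_num)), 1e-6)
})

test_that("instance-norm gradients match numerical differentiation", {
  set.seed(3)
  l <- ns$nn_instnorm(3L)
  l$gamma <- runif(3, 0.5, 1.5)
  l$beta <- rnorm(3)
  x <- array(rnorm(5 * 5 * 3), c(5L, 5L, 3L))
  fw <- ns$in_fwd(l, x)
  ns$zero_grads(list(l))
  gx <- ns$in_bwd(l, fw, gy_of(fw$y))
  expect_lt(max(abs(gx - num_grad(function(z) loss_of(ns$in_fwd(l, z)$y), x))),
            1e-5)
  g0 <- l$gamma + 0
  gg_num <- num_grad(function(g) {
    l$gamma <- g; on.exit(l$gamma <- g0)
    loss_of(ns$in_fwd(l, x)$y)
  }, g0)
  expect_lt(max(abs(l$ggamma - gg_num)), 1e-5)
})

test_that("attention gradients match numerical differentiation (both paths)", {
  set.seed(4)
  for (factor in c(1L, 2L)) {
    l <- ns$nn_attention(4L, factor = factor)
    l$delta <- 0.6
    x <- array(rnorm(3 * 3 * 4, sd = 0.5), c(3L, 3L, 4L))
    fw <- ns$att_fwd(l, x)         # single-precision training path
    ref <- adaunet:::attention_fwd_cpp(ns$as_chw(x), l$Wp, l$We, l$delta)
    expect_lt(max(abs(fw$out - ref$out)), 1e-4)
    ns$zero_grads(list(l))
    gx <- ns$att_bwd(l, x, fw$cache, gy_of(fw$out))
    gx_ref <- adaunet:::attention_bwd_cpp(ns$as_chw(x), l$Wp, l$We, l$delta,
                                          ref$Fp, ref$A, ref$att, ref$att2,
                                          ns$as_chw(gy_of(ref$out)))
    # double-precision reference against numerical gradients
    expect_lt(max(abs(gx_ref$gx -
      num_grad(function(z) loss_of(
        adaunet:::attention_fwd_cpp(ns$as_chw(z), l$Wp, l$We, l$delta)$out),
        x))), 1e-5)
    # float path agrees with the double reference
    expect_lt(max(abs(gx - gx_ref$gx)), 1e-3)
    expect_lt(max(abs(l$gWp - gx_ref$gWp)), 1e-3)
  }
})

test_that("full segmentor parameter gradients match numerical differentiation", {
  set.seed(5)
  cfg <- segmentor_config("adau_a1", depth = 2L, base_channels = 4L)
  m <- build_segmentor(cfg, seed = 6)
  img <- matrix(runif(64), 8L, 8L)
  msk <- matrix(0, 8L, 8L); msk[3:5, 4:6] <- 1
  gt <- ground_truth_pair(msk)
  lossfun <- function() {
    fw <- ns$seg_forward_full(m, img)
    dice_loss(ns$sigmoid(fw$logit1), gt$full) +
      0.1 * dice_loss(ns$sigmoid(fw$logit2), gt$half)
  }
  fw <- ns$seg_forward_full(m, img)
  p1 <- ns$sigmoid(fw$logit1); p2 <- ns$sigmoid(fw$logit2)
  ls <- ns$model_layers(m)
  ns$zero_grads(ls)
  ns$seg_backward(m, fw,
                  ns$dice_loss_grad(p1, gt$full) * p1 * (1 - p1),
                  0.1 * ns$dice_loss_grad(p2, gt$half) * p2 * (1 - p2))
  set.seed(7)
  worst <- 0
  for (l in ls) {
    for (p in l$par) {
      v <- l[[p]]
      for (i in if (length(v) > 3) sample(length(v), 3) else seq_along(v)) {
        orig <- v[i]
        l[[p]][i] <- orig + 1e-5; up <- lossfun()
        l[[p]][i] <- orig - 1e-5; dn <- lossfun()
        l[[p]][i] <- orig
        worst <- max(worst, abs((up - dn) / 2e-5 - l[[paste0("g", p)]][i]))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("discriminator input gradients match numerical differentiation", {
  set.seed(8)
  d <- build_discriminator(discriminator_config(channels = c(4L, 8L, 8L, 8L, 1L)),
                           seed = 9)
  x <- matrix(runif(32 * 32), 32L, 32L)
  fw <- ns$disc_forward_full(d, x)
  ns$zero_grads(d$layers)
  gx <- ns$disc_backward(d, fw, 1)
  # numerical check on a subset of pixels (full 32x32 would be slow)
  set.seed(10)
  idx <- sample(length(x), 6)
  for (i in idx) {
    orig <- x[i]
    x[i] <- orig + 1e-5; up <- ns$disc_forward_full(d, x)$p
    x[i] <- orig - 1e-5; dn <- ns$disc_forward_full(d, x)$p
    x[i] <- orig
    expect_lt(abs((up - dn) / 2e-5 - gx[i]), 1e-6)
  }
})
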