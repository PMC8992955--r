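## Minimal neural-network layer toolkit with hand-derived backward passes.
## Layers are environments holding parameters (`Wm`, `b`, ...), their gradient
## accumulators (`gWm`, ...), and Adam moment state.  All convolution weights
## are stored pre-flattened for the C++ kernels; `layer$par` lists the
## trainable slots so the optimizer and checkpointing stay generic.

#' @useDynLib adaunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_chw <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

he_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

new_layer <- function(type, params, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- params                       # character vector of parameter slots
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  for (p in params) {
    e[[p]] <- e[[p]] + 0          # force a fresh allocation: params are
                                  # updated in place by the C++ optimizer
    e[[paste0("g", p)]] <- e[[p]] * 0
    e[[paste0("m", p)]] <- e[[p]] * 0
    e[[paste0("v", p)]] <- e[[p]] * 0
  }
  e
}

## kernel kh x kw convolution, stride/pad as given; weight flattening
## r = ki + kh*(kj + kw*ci) matches the C++ im2col ordering.
nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  K <- k * k * in_ch
  Wm <- matrix(he_init(K, out_ch * K), nrow = out_ch, ncol = K)
  new_layer("conv", c("Wm", "b"),
            Wm = Wm, b = numeric(out_ch),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch)
}

conv_fwd <- function(l, x) {
  conv2d_fwd_cpp(as_chw(x), l$Wm, l$b, l$k, l$k, l$stride, l$pad)
}

## params = FALSE skips the weight-gradient GEMM (used when a frozen
## discriminator only relays gradients to its input during a generator step)
conv_bwd <- function(l, x, gy, params = TRUE) {
  r <- conv2d_bwd_cpp(as_chw(x), l$Wm, as_chw(gy), l$k, l$k, l$stride, l$pad,
                      params)
  if (params) {
    axpy_cpp(l$gWm, r$gW)
    axpy_cpp(l$gb, as.numeric(r$gb))
  }
  r$gx
}

## 2x2 stride-2 transposed convolution ("deconvolutional" upsampling).
nn_tconv <- function(in_ch, out_ch) {
  M <- matrix(he_init(in_ch, 4L * out_ch * in_ch), nrow = 4L * out_ch)
  new_layer("tconv", c("M", "b"),
            M = M, b = numeric(out_ch), in_ch = in_ch, out_ch = out_ch)
}

tconv_fwd <- function(l, x) tconv2_fwd_cpp(as_chw(x), l$M, l$b)

tconv_bwd <- function(l, x, gy) {
  r <- tconv2_bwd_cpp(as_chw(x), l$M, as_chw(gy))
  axpy_cpp(l$gM, r$gM)
  axpy_cpp(l$gb, as.numeric(r$gb))
  r$gx
}

## Position-attention block: delta is a learnable scalar initialized at 0 so
## the block starts as the identity; `fixed_delta` freezes it for tests.
nn_attention <- function(channels, factor = 1L, fixed_delta = NULL) {
  cp <- max(1L, channels %/% factor)
  Wp <- diag(1, cp, channels) + matrix(stats::rnorm(cp * channels, sd = 0.02),
                                       cp, channels)
  if (cp != channels) {
    We <- matrix(he_init(cp, channels * cp), nrow = channels)
    l <- new_layer("attention", c("Wp", "delta", "We"), Wp = Wp, delta = 0,
                   We = We, channels = channels, cp = cp)
  } else {
    l <- new_layer("attention", c("Wp", "delta"), Wp = Wp, delta = 0,
                   channels = channels, cp = cp)
  }
  if (!is.null(fixed_delta)) {
    l$delta <- fixed_delta
    l$par <- setdiff(l$par, "delta")
  }
  l
}

## training path: single-precision kernels, N x N work stays on the C++ side
att_fwd <- function(l, x) {
  attention_fwd_fast_cpp(as_chw(x), l$Wp, l$We, l$delta)
}

att_bwd <- function(l, x, cache, gy) {
  r <- attention_bwd_fast_cpp(cache, l$Wp, l$We, l$delta, as_chw(gy))
  axpy_cpp(l$gWp, r$gWp)
  if ("delta" %in% l$par) l$gdelta <- l$gdelta + r$gdelta
  if (!is.null(l$We)) axpy_cpp(l$gWe, r$gWe)
  r$gx
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(y, gy) gy * (y > 0)
lrelu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(x, gy, slope = 0.2) gy * ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

## NOTE: grads, Adam moments and parameters are updated IN PLACE (C++); these
## objects are package-internal and never handed out, so no aliasing occurs.
zero_grads <- function(layers) {
  for (l in layers) for (p in l$par) fill0_cpp(l[[paste0("g", p)]])
  invisible(NULL)
}

## one Adam step over every trainable slot of every layer, fixed order
adam_step <- function(layers, lr, beta1, beta2, t, eps = 1e-8) {
  for (l in layers) {
    for (p in l$par) {
      adam_step_cpp(l[[p]], l[[paste0("g", p)]], l[[paste0("m", p)]],
                    l[[paste0("v", p)]], lr, beta1, beta2, t, eps)
    }
  }
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, function(p)
    length(l[[p]]), 1L)), 1L))
}

layer_state <- function(l) {
  s <- lapply(l$par, function(p) l[[p]] + 0)   # copy: params mutate in place
  names(s) <- l$par
  s
}

## instance normalization (per-channel over the spatial plane, batch size 1)
nn_instnorm <- function(channels) {
  new_layer("instnorm", c("gamma", "beta"),
            gamma = rep(1, channels), beta = numeric(channels))
}

in_fwd <- function(l, x) instnorm_fwd_cpp(as_chw(x), l$gamma, l$beta)

in_bwd <- function(l, cache, gy) {
  r <- instnorm_bwd_cpp(as_chw(gy), cache$xhat, cache$inv_sd, l$gamma)
  axpy_cpp(l$ggamma, as.numeric(r$ggamma))
  axpy_cpp(l$gbeta, as.numeric(r$gbeta))
  r$gx
}
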