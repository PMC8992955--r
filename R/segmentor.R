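## Segmentation architectures: a baseline U-Net encoder--decoder with skip
## connections, its duplex variant (auxiliary 1x1 prediction head on the
## penultimate decoder stage), and attention-augmented versions that insert
## position-attention blocks after the last k decoder stages.

SEG_VARIANTS <- c("unet", "au_net", "dau_net", "adau_a1", "adau_a2", "adau_a3")

#' Segmentor configuration
#'
#' Describes one of the six segmentation model variants: the baseline U-Net,
#' the single-adversarial `au_net`, the duplex-adversarial `dau_net`, and the
#' attention-augmented duplex models `adau_a1`/`adau_a2`/`adau_a3` carrying
#' one, two and three position-attention blocks after the last one, two and
#' three decoder (deconvolutional) stages.
#'
#' @param variant Model variant name.
#' @param depth Number of down/up-sampling stages (default 4).
#' @param base_channels Channel width of the first encoder stage (default 64;
#'   reduce for desk-scale experiments).
#' @param in_channels Number of input channels (grayscale slices: 1).
#' @param attention_channel_factor Channel reduction factor of the attention
#'   1x1 projection (default 1 = the single shared projection preserves C).
#' @return A `segmentor_config` list.
#' @export
segmentor_config <- function(variant = "unet", depth = 4L, base_channels = 64L,
                             in_channels = 1L, attention_channel_factor = 1L) {
  variant <- match.arg(variant, SEG_VARIANTS)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  stopifnot(depth >= 2L, base_channels >= 4L, in_channels == 1L,
            attention_channel_factor >= 1L)
  n_att <- c(unet = 0L, au_net = 0L, dau_net = 0L,
             adau_a1 = 1L, adau_a2 = 2L, adau_a3 = 3L)[[variant]]
  if (n_att >= depth)
    stop("variant ", variant, " needs depth > ", n_att)
  structure(list(variant = variant, depth = depth,
                 base_channels = base_channels, in_channels = 1L,
                 attention_channel_factor = as.integer(attention_channel_factor),
                 n_attention = n_att,
                 n_adv_heads = if (variant == "unet") 0L
                               else if (variant == "au_net") 1L else 2L,
                 duplex = !variant %in% c("unet", "au_net")),
            class = "segmentor_config")
}

#' Build a segmentation model
#'
#' Instantiates the encoder--decoder network described by `config`. Parameters
#' are drawn from R's RNG, so a fixed `seed` reproduces the weights exactly.
#'
#' @param config A [segmentor_config()].
#' @param seed Integer seed for parameter initialization.
#' @param fixed_delta Optional fixed value for the attention residual scale
#'   (by default delta is a learnable scalar initialized at 0).
#' @return An `adaunet_model` object.
#' @export
build_segmentor <- function(config, seed = 1L, fixed_delta = NULL) {
  stopifnot(inherits(config, "segmentor_config"))
  set.seed(as.integer(seed))
  d <- config$depth
  ch <- config$base_channels * 2L^(0:(d - 1L))   # encoder stage widths
  bott <- config$base_channels * 2L^d
  ## conv pair: conv -> instance norm -> ReLU, twice (norm is essential for
  ## convergence at batch size 1)
  conv_pair <- function(in_ch, out_ch) {
    list(conv1 = nn_conv(in_ch, out_ch, 3L), n1 = nn_instnorm(out_ch),
         conv2 = nn_conv(out_ch, out_ch, 3L), n2 = nn_instnorm(out_ch))
  }
  enc <- vector("list", d)
  prev <- config$in_channels
  for (k in seq_len(d)) {
    enc[[k]] <- conv_pair(prev, ch[k])
    prev <- ch[k]
  }
  bottleneck <- conv_pair(ch[d], bott)
  ## decoder stage j = 1..d goes from resolution H/2^(d-j+1) up to H/2^(d-j);
  ## stage d is the last ("output-resolution") deconvolutional stage.
  dec <- vector("list", d)
  up_in <- bott
  for (j in seq_len(d)) {
    out_ch <- ch[d - j + 1L]
    att <- NULL
    if (config$n_attention > 0L && j > d - config$n_attention)
      att <- nn_attention(out_ch, config$attention_channel_factor, fixed_delta)
    dec[[j]] <- c(list(up = nn_tconv(up_in, out_ch)),
                  conv_pair(2L * out_ch, out_ch), list(att = att))
    up_in <- out_ch
  }
  head1 <- nn_conv(ch[1L], 1L, 1L)
  head1$b[] <- -6                  # strong background prior: concentrates early
                                   # dice gradient on the foreground
  head2 <- if (config$duplex) nn_conv(ch[2L], 1L, 1L) else NULL
  if (!is.null(head2)) head2$b[] <- -6
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$enc <- enc; m$bottleneck <- bottleneck; m$dec <- dec
  m$head1 <- head1; m$head2 <- head2
  class(m) <- "adaunet_model"
  m
}

model_layers <- function(m) {
  pair <- c("conv1", "n1", "conv2", "n2")
  ls <- list()
  for (s in m$enc) ls <- c(ls, s[pair])
  ls <- c(ls, m$bottleneck[pair])
  for (s in m$dec) {
    ls <- c(ls, s["up"], s[pair])
    if (!is.null(s$att)) ls <- c(ls, s["att"])
  }
  ls <- c(ls, list(m$head1))
  if (!is.null(m$head2)) ls <- c(ls, list(m$head2))
  ls
}

#' Count attention blocks in a model
#' @param model An `adaunet_model`.
#' @return Integer number of position-attention blocks.
#' @export
n_attention_blocks <- function(model) {
  sum(vapply(model$dec, function(s) !is.null(s$att), logical(1)))
}

concat_c <- function(a, b) {
  out <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

## Full forward pass; returns head logits plus every cached activation needed
## by seg_backward.  `image` is an H x W matrix.
seg_forward_full <- function(m, image) {
  d <- m$config$depth
  H <- nrow(image); W <- ncol(image)
  if (H %% 2L^d != 0L || W %% 2L^d != 0L)
    stop("image side lengths must be divisible by 2^depth = ", 2L^d,
         " (got ", H, "x", W, ")")
  x <- array(image, c(H, W, 1L))
  ## conv -> IN -> ReLU, twice; returns activations + norm caches
  pair_fwd <- function(s, xin) {
    i1 <- in_fwd(s$n1, conv_fwd(s$conv1, xin))
    a1 <- relu_fwd(i1$y)
    i2 <- in_fwd(s$n2, conv_fwd(s$conv2, a1))
    list(c1in = xin, i1 = i1, a1 = a1, i2 = i2, a2 = relu_fwd(i2$y))
  }
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  for (k in seq_len(d)) {
    st <- pair_fwd(m$enc[[k]], x)
    mp <- maxpool2_fwd_cpp(st$a2)
    st$idx <- mp$idx
    cache$enc[[k]] <- st
    x <- mp$y
  }
  cache$bott <- pair_fwd(m$bottleneck, x)
  x <- cache$bott$a2
  for (j in seq_len(d)) {
    s <- m$dec[[j]]
    upin <- x
    up <- tconv_fwd(s$up, upin)
    skip <- cache$enc[[d - j + 1L]]$a2
    cat_in <- concat_c(up, skip)
    st <- pair_fwd(s, cat_in)
    st$upin <- upin
    a2 <- st$a2
    if (!is.null(s$att)) {
      af <- att_fwd(s$att, a2)
      st$att_cache <- af$cache
      x <- af$out
      st$out <- x
    } else {
      x <- a2
    }
    cache$dec[[j]] <- st
  }
  logit1 <- conv_fwd(m$head1, x)[, , 1L]
  cache$final <- x
  out <- list(logit1 = logit1, cache = cache)
  if (m$config$duplex) {
    pen <- cache$dec[[d - 1L]]
    pen_out <- if (!is.null(pen$out)) pen$out else pen$a2
    out$logit2 <- conv_fwd(m$head2, pen_out)[, , 1L]
    cache$pen_out <- pen_out
    out$cache <- cache
  }
  out
}

## Backward pass from head-logit gradients; accumulates parameter gradients in
## the layer environments and returns nothing.
seg_backward <- function(m, fw, g_logit1, g_logit2 = NULL) {
  d <- m$config$depth
  cache <- fw$cache
  gx <- conv_bwd(m$head1, cache$final, array(g_logit1, c(dim(g_logit1), 1L)))
  g_pen <- NULL
  if (!is.null(g_logit2)) {
    g_pen <- conv_bwd(m$head2, cache$pen_out,
                      array(g_logit2, c(dim(g_logit2), 1L)))
  }
  ## backward through conv -> IN -> ReLU, twice
  pair_bwd <- function(s, st, gx) {
    gx <- relu_bwd(st$a2, gx)
    gx <- in_bwd(s$n2, st$i2, gx)
    gx <- conv_bwd(s$conv2, st$a1, gx)
    gx <- relu_bwd(st$a1, gx)
    gx <- in_bwd(s$n1, st$i1, gx)
    conv_bwd(s$conv1, st$c1in, gx)
  }
  gskip <- vector("list", d)        # gradients flowing into encoder skips
  for (j in rev(seq_len(d))) {
    s <- m$dec[[j]]
    st <- cache$dec[[j]]
    if (j == d - 1L && !is.null(g_pen)) gx <- gx + g_pen
    if (!is.null(s$att)) gx <- att_bwd(s$att, st$a2, st$att_cache, gx)
    gcat <- pair_bwd(s, st, gx)
    nup <- s$up$out_ch
    gup <- gcat[, , seq_len(nup), drop = FALSE]
    gskip[[d - j + 1L]] <- gcat[, , nup + seq_len(dim(gcat)[3] - nup),
                                drop = FALSE]
    gx <- tconv_bwd(s$up, st$upin, gup)
  }
  gx <- pair_bwd(m$bottleneck, cache$bott, gx)
  for (k in rev(seq_len(d))) {
    st <- cache$enc[[k]]
    gx <- maxpool2_bwd_cpp(as_chw(gx), st$idx)
    gx <- gx + gskip[[k]]
    gx <- pair_bwd(m$enc[[k]], st, gx)
  }
  invisible(NULL)
}

#' Run a segmentor on one image
#'
#' Applies the network and the terminal sigmoid; deterministic (the models
#' have no stochastic layers).
#'
#' @param model An `adaunet_model`.
#' @param image Numeric H x W matrix with side lengths divisible by
#'   `2^depth`.
#' @return A `segmentor_output` list with `main_map` (H x W probabilities) and,
#'   for duplex variants, `aux_map` at half resolution.
#' @export
seg_forward <- function(model, image) {
  fw <- seg_forward_full(model, image)
  out <- list(main_map = sigmoid(fw$logit1),
              aux_map = if (!is.null(fw$logit2)) sigmoid(fw$logit2))
  structure(out, class = "segmentor_output")
}

#' @export
print.adaunet_model <- function(x, ...) {
  cat("<adaunet_model> variant=", x$config$variant,
      " depth=", x$config$depth,
      " base_channels=", x$config$base_channels,
      " attention_blocks=", n_attention_blocks(x),
      " params=", n_params(model_layers(x)), "\n", sep = "")
  invisible(x)
}

#' Stand-alone position-attention block
#'
#' Computes the spatial affinity map `A[m, n] = softmax_n(I'_n . I'_m)` from
#' the 1x1-projected features `I'`, aggregates `I'` with the affinities, and
#' adds the result back to the input scaled by `delta`. With the default
#' identity projection this is the pure attention operator used by the tests'
#' loop-based oracle.
#'
#' @param x Feature map, array `H x W x C` (R layout) of finite values.
#' @param delta Residual scale; `delta = 0` returns `x` unchanged.
#' @param proj Optional projection matrix (`Cp x C`); default identity.
#' @param return_attention If `TRUE`, attach the `N x N` row-stochastic
#'   affinity matrix as attribute `"attention"`.
#' @return Array of the same shape as `x`.
#' @export
attention_block <- function(x, delta, proj = NULL, return_attention = FALSE) {
  x <- as_chw(x)
  if (!all(is.finite(x))) stop("attention_block: non-finite input")
  C <- dim(x)[3]
  if (is.null(proj)) proj <- diag(C)
  r <- attention_fwd_cpp(x, proj, NULL, delta)
  out <- r$out
  if (return_attention) attr(out, "attention") <- r$A
  out
}

#' Save / load a model checkpoint
#'
#' Weights are written with [saveRDS()] and the configuration as a JSON
#' sidecar (`<path>.json`).
#'
#' @param model An `adaunet_model`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  state <- lapply(model_layers(model), layer_state)
  saveRDS(list(config = unclass(model$config), state = state), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(segmentor_config, ck$config[c("variant", "depth",
          "base_channels", "in_channels", "attention_channel_factor")])
  m <- build_segmentor(cfg, seed = 0L)
  ls <- model_layers(m)
  stopifnot(length(ls) == length(ck$state))
  for (i in seq_along(ls))
    for (p in names(ck$state[[i]])) ls[[i]][[p]] <- ck$state[[i]][[p]] + 0
  m
}
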