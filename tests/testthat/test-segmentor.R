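test_that("variants carry the stated attention blocks and adversarial heads", {
  want_att <- c(unet = 0L, au_net = 0L, dau_net = 0L,
                adau_a1 = 1L, adau_a2 = 2L, adau_a3 = 3L)
  want_heads <- c(unet = 0L, au_net = 1L, dau_net = 2L,
                  adau_a1 = 2L, adau_a2 = 2L, adau_a3 = 2L)
  for (v in names(want_att)) {
    cfg <- segmentor_config(v, base_channels = 4L)
    expect_identical(cfg$n_adv_heads, want_heads[[v]])
    m <- build_segmentor(cfg, seed = 1)
    expect_identical(n_attention_blocks(m), want_att[[v]])
    expect_identical(is.null(m$head2), v %in% c("unet", "au_net"))
  }
  expect_error(segmentor_config("resnet"))
  expect_error(segmentor_config("adau_a3", depth = 3L), "depth")
})

test_that("attention blocks sit after the last k decoder stages", {
  m <- build_segmentor(segmentor_config("adau_a2", base_channels = 4L), seed = 1)
  has_att <- vapply(m$dec, function(s) !is.null(s$att), logical(1))
  expect_identical(has_att, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("two builds with the same config and seed have identical parameters", {
  cfg <- segmentor_config("adau_a1", depth = 3L, base_channels = 4L)
  s1 <- lapply(ns$model_layers(build_segmentor(cfg, seed = 5)), ns$layer_state)
  s2 <- lapply(ns$model_layers(build_segmentor(cfg, seed = 5)), ns$layer_state)
  expect_identical(s1, s2)
  s3 <- lapply(ns$model_layers(build_segmentor(cfg, seed = 6)), ns$layer_state)
  expect_false(identical(s1, s3))
})

test_that("forward obeys shape contracts and is deterministic", {
  m <- build_segmentor(segmentor_config("dau_net", base_channels = 4L), seed = 2)
  img <- matrix(runif(64 * 64), 64L, 64L)
  o1 <- seg_forward(m, img)
  expect_identical(dim(o1$main_map), c(64L, 64L))
  expect_identical(dim(o1$aux_map), c(32L, 32L))
  expect_true(all(o1$main_map >= 0 & o1$main_map <= 1))
  expect_true(all(o1$aux_map >= 0 & o1$aux_map <= 1))
  expect_identical(o1, seg_forward(m, img))
  expect_error(seg_forward(m, matrix(0, 50, 50)), "divisible by 2\\^depth")

  mu <- build_segmentor(segmentor_config("unet", base_channels = 4L), seed = 2)
  expect_null(seg_forward(mu, img)$aux_map)
})

test_that("a zeroed final head yields the constant 0.5 map", {
  m <- build_segmentor(segmentor_config("unet", depth = 2L,
                                        base_channels = 4L), seed = 3)
  m$head1$Wm[] <- 0
  m$head1$b[] <- 0
  out <- seg_forward(m, matrix(runif(16 * 16), 16L, 16L))
  expect_equal(out$main_map, matrix(0.5, 16L, 16L), tolerance = 0)
})

test_that("attention_block is row-stochastic, identity at delta 0, and
           permutation-covariant", {
  set.seed(11)
  x <- array(rnorm(4 * 3 * 5, sd = 0.5), c(4L, 3L, 5L))
  expect_identical(attention_block(x, delta = 0), x)
  out <- attention_block(x, delta = 0.7, return_attention = TRUE)
  A <- attr(out, "attention")
  expect_identical(dim(A), c(12L, 12L))
  expect_true(all(A >= 0))
  expect_lt(max(abs(rowSums(A) - 1)), 1e-5)

  # uniform rows when all positions share one feature vector
  xc <- array(rep(c(1, -2, 0.5), each = 12), c(4L, 3L, 3L))
  Ac <- attr(attention_block(xc, 0.3, return_attention = TRUE), "attention")
  expect_lt(max(abs(Ac - 1 / 12)), 1e-12)

  # flipping rows permutes spatial positions; output must flip identically
  xf <- x[4:1, , , drop = FALSE]
  of <- attention_block(xf, delta = 0.7)
  expect_equal(unclass(of), unclass(out)[4:1, , , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("checkpoints round-trip weights and configuration", {
  m <- build_segmentor(segmentor_config("adau_a1", depth = 3L,
                                        base_channels = 4L), seed = 4)
  img <- matrix(runif(32 * 32), 32L, 32L)
  before <- seg_forward(m, img)
  f <- file.path(withr::local_tempdir(), "model.rds")
  save_checkpoint(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- load_checkpoint(f)
  expect_identical(m2$config, m$config)
  expect_identical(seg_forward(m2, img), before)
})
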