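test_that("phantom generation is deterministic and respects the noise-free limit", {
  cfg <- phantom_config(image_size = 32L, seed = 7)
  s1 <- generate_phantom(cfg, 3L, 2L)
  s2 <- generate_phantom(cfg, 3L, 2L)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_true(all(s1$mask %in% c(0, 1)))
  expect_identical(dim(s1$image), dim(s1$mask))

  # different slice or case changes the output
  expect_false(identical(s1$mask, generate_phantom(cfg, 3L, 3L)$mask))
  expect_false(identical(s1$mask, generate_phantom(cfg, 4L, 2L)$mask))

  # noise-free, distractor-free, full-contrast: image is a two-level image
  # equal to the mask mapped onto {background, foreground} exactly
  cfg0 <- phantom_config(image_size = 32L, contrast = 1, noise_sd = 0,
                         n_distractors = 0L, seed = 7)
  s <- generate_phantom(cfg0, 1L, 1L)
  fg <- unique(as.vector(s$image[s$mask == 1]))
  bg <- unique(as.vector(s$image[s$mask == 0]))
  expect_length(fg, 1L)
  expect_length(bg, 1L)
  expect_equal(s$image, bg + (fg - bg) * s$mask, tolerance = 0)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(contrast = 0), "unlearnable")
  expect_error(phantom_config(image_size = 8L), ">= 16")
})

test_that("every generated mask's area fraction lies in the configured bounds", {
  cfg <- phantom_config(image_size = 64L, n_cases = 50L,
                        slices_per_case = 20L, seed = 13)
  fr <- numeric(0)
  for (cs in seq_len(cfg$n_cases))
    for (sl in seq_len(cfg$slices_per_case))
      fr <- c(fr, mean(generate_phantom(cfg, cs, sl)$mask))
  expect_length(fr, 1000L)
  expect_true(all(fr >= cfg$area_bounds[1]))
  expect_true(all(fr <= cfg$area_bounds[2]))

  # also at the full default resolution
  cfg208 <- phantom_config(seed = 13)
  fr208 <- vapply(1:25, function(cs)
    mean(generate_phantom(cfg208, cs, 1L)$mask), 1.0)
  expect_true(all(fr208 >= cfg208$area_bounds[1] &
                  fr208 <= cfg208$area_bounds[2]))
})

test_that("datasets partition cases into 4 folds at the case level", {
  ds <- tiny_phantoms(n_cases = 8L, slices = 3L)
  expect_length(ds$slices, 24L)
  expect_identical(as.integer(table(ds$folds)), rep(2L, 4L))
  expect_setequal(names(ds$folds), as.character(1:8))

  # 82 cases: fold sizes in {20, 21} summing to 82; each case in one fold
  f82 <- assign_folds(1:82, seed = 5)
  expect_length(f82, 82L)
  expect_true(all(table(f82) %in% c(20L, 21L)))
  expect_identical(sum(table(f82)), 82L)
  expect_false(any(duplicated(names(f82))))

  expect_error(generate_dataset(phantom_config(n_cases = 3L)), "4-fold")

  # fold RNG is separate from phantom RNG: same config seed, same images
  cfg <- phantom_config(image_size = 16L, n_cases = 4L,
                        slices_per_case = 1L, seed = 9)
  expect_identical(generate_dataset(cfg)$slices[[1]]$image,
                   generate_phantom(cfg, 1L, 1L)$image)
})

test_that("label-guided crop contains the mask and clamps at borders", {
  img <- matrix(runif(96 * 96), 96, 96)
  msk <- matrix(0, 96, 96)
  msk[40:52, 45:60] <- 1
  cr <- crop_resize(img, msk, 64L)
  expect_identical(dim(cr$image), c(64L, 64L))
  expect_identical(sum(cr$mask), sum(msk))   # whole foreground contained

  # bbox touching the border: window clamped, still target x target
  msk2 <- matrix(0, 96, 96); msk2[1:5, 1:5] <- 1
  cr2 <- crop_resize(img, msk2, 64L)
  expect_identical(dim(cr2$mask), c(64L, 64L))
  expect_identical(sum(cr2$mask), 25)
  expect_identical(cr2$image, img[1:64, 1:64])

  # single-pixel mask: crop centered up to clamping, mask sum 1
  msk3 <- matrix(0, 96, 96); msk3[50, 30] <- 1
  cr3 <- crop_resize(img, msk3, 20L)
  expect_identical(sum(cr3$mask), 1)
  expect_identical(which(cr3$mask == 1, arr.ind = TRUE)[1, ],
                   c(row = 10L, col = 10L))

  expect_warning(cr4 <- crop_resize(img, msk * 0, 64L), "empty mask")
  expect_identical(dim(cr4$image), c(64L, 64L))
  expect_error(crop_resize(img, msk, 200L), "larger")

  # interpolating mode
  cr5 <- crop_resize(img, msk, 48L, method = "resize")
  expect_identical(dim(cr5$image), c(48L, 48L))
  expect_true(all(cr5$mask %in% c(0, 1)))
})
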