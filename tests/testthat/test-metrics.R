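test_that("overlap metrics match counting oracles and their identity", {
  set.seed(4)
  for (i in 1:40) {
    a <- random_mask(16); b <- random_mask(16)
    D <- dsc(a, b); J <- jaccard(a, b)
    expect_equal(D, dsc_oracle(a, b), tolerance = 1e-9)
    expect_equal(J, jaccard_oracle(a, b), tolerance = 1e-9)
    expect_equal(J, 100 * D / (200 - D), tolerance = 1e-9)
  }
  m <- random_mask(16)
  expect_identical(dsc(m, m), 100)
  expect_identical(jaccard(m, m), 100)
  z <- matrix(0, 8L, 8L)
  expect_identical(dsc(z, z), 100)      # both-empty convention
  expect_error(dsc(m, m * 2), "0/1")
})

test_that("surface metrics match brute-force oracles and simple geometry", {
  a1 <- matrix(0, 12L, 12L); a1[4L, 3L] <- 1
  b1 <- matrix(0, 12L, 12L); b1[4L, 6L] <- 1
  expect_equal(asd(a1, b1), 3, tolerance = 1e-12)
  expect_equal(surface_rmse(a1, b1), 3, tolerance = 1e-12)
  expect_equal(asd(a1, b1, spacing = 0.5), 1.5, tolerance = 1e-12)
  expect_identical(asd(a1, a1), 0)
  expect_identical(surface_rmse(a1, a1), 0)

  set.seed(5)
  for (i in 1:25) {
    a <- random_mask(14); b <- random_mask(14)
    expect_equal(asd(a, b), asd_oracle(a, b), tolerance = 1e-9)
    expect_equal(surface_rmse(a, b), rmse_oracle(a, b), tolerance = 1e-9)
    # exact symmetry
    expect_identical(asd(a, b), asd(b, a))
    expect_identical(surface_rmse(a, b), surface_rmse(b, a))
    # pooled RMS >= pooled mean (Jensen)
    d <- c(directed_oracle(a, b), directed_oracle(b, a))
    expect_gte(surface_rmse(a, b) + 1e-12, mean(d))
  }

  expect_warning(v <- asd(matrix(0, 6L, 6L), a1[1:6, 1:6]), "empty")
  expect_true(is.na(v))
})

test_that("metrics are invariant under joint translation away from borders", {
  set.seed(6)
  a <- matrix(0, 20L, 20L); a[5:8, 6:9] <- random_mask(4) * 0 + 1
  b <- matrix(0, 20L, 20L); b[6:9, 5:8] <- 1
  shift <- function(m, di, dj) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1:nrow(m)) + di, (1:ncol(m)) + dj] <- m[1:nrow(m), 1:ncol(m)]
    out[1:nrow(m), 1:ncol(m)]
  }
  a2 <- matrix(0, 20L, 20L); a2[10:13, 11:14] <- 1
  b2 <- matrix(0, 20L, 20L); b2[11:14, 10:13] <- 1
  expect_identical(dsc(a, b), dsc(a2, b2))
  expect_identical(jaccard(a, b), jaccard(a2, b2))
  expect_identical(asd(a, b), asd(a2, b2))
  expect_identical(surface_rmse(a, b), surface_rmse(a2, b2))
})

test_that("evaluation pools slices per case and aggregates correctly", {
  # two single-slice cases engineered to DSC 80 and 90
  t1 <- matrix(0, 12L, 12L); t1[2L, 1:10] <- 1
  p1 <- matrix(0, 12L, 12L); p1[2L, 3:12] <- 1     # overlap 8 -> DSC 80
  t2 <- matrix(0, 12L, 12L); t2[5L, 1:10] <- 1
  p2 <- matrix(0, 12L, 12L); p2[5L, 2:11] <- 1     # overlap 9 -> DSC 90
  rep <- evaluate_segmentation(list(p1, p2), list(t1, t2), c(1L, 2L))
  expect_equal(rep$per_case$dsc, c(80, 90), tolerance = 1e-9)
  agg <- rep$aggregate
  expect_equal(agg$mean[agg$metric == "dsc"], 85, tolerance = 1e-9)
  expect_equal(agg$sd[agg$metric == "dsc"], stats::sd(c(80, 90)),
               tolerance = 1e-9)                    # sample (n-1) convention
  expect_equal(agg$min[agg$metric == "dsc"], 80, tolerance = 1e-9)

  # pooled-count case metric: two slices of one case pooled before the ratio
  rep2 <- evaluate_segmentation(list(p1, matrix(0, 12L, 12L)),
                                list(t1, t2), c(7L, 7L))
  expect_equal(rep2$per_case$dsc, 100 * 2 * 8 / (10 + 20), tolerance = 1e-9)

  # perfect predictions
  rep3 <- evaluate_segmentation(list(t1, t2), list(t1, t2), c(1L, 2L))
  expect_equal(rep3$aggregate$mean[rep3$aggregate$metric == "dsc"], 100)
  expect_equal(rep3$aggregate$mean[rep3$aggregate$metric == "asd"], 0)

  # aggregate recomputable from per-case rows
  set.seed(7)
  preds <- lapply(1:6, function(i) matrix(runif(144), 12L))
  tr <- lapply(1:6, function(i) random_mask(12))
  rep4 <- evaluate_segmentation(preds, tr, rep(1:3, each = 2L))
  expect_equal(rep4$aggregate$mean[rep4$aggregate$metric == "jaccard"],
               mean(rep4$per_case$jaccard), tolerance = 1e-9)

  expect_error(evaluate_segmentation(preds[1:2], tr, rep(1L, 6L)), "length")

  f <- file.path(withr::local_tempdir(), "report.csv")
  write_eval_report(rep4, f)
  expect_identical(nrow(utils::read.csv(f)), 3L)
  expect_true(file.exists(sub("\\.csv$", "_aggregate.csv", f)))
})
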