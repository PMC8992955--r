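## Evaluation metrics: overlap (DSC, Jaccard, as percentages) and surface
## distances (ASD, surface RMSE, in mm).  Border pixels are foreground pixels
## 4-adjacent to background (image edges count as background); the production
## path uses an exact Euclidean distance transform, while the test suite
## compares against O(n^2) all-pairs oracles.

as_bin <- function(x) {
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1))) stop("mask values must be 0/1")
  x
}

#' Dice similarity coefficient (percent)
#'
#' `100 * 2|A intersect B| / (|A| + |B|)`; two empty masks score 100 by
#' convention (nothing to find, nothing found).
#'
#' @param a,b Binary masks (equal-shaped arrays).
#' @return Percentage in `[0, 100]`.
#' @export
dsc <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  as_bin(a); as_bin(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(100)
  100 * 2 * sum(a * b) / (sa + sb)
}

#' Jaccard index (percent)
#'
#' `100 * |A intersect B| / |A union B|`; linked to DSC by
#' `J = 100 * D / (200 - D)`.
#'
#' @inheritParams dsc
#' @return Percentage in `[0, 100]`.
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  as_bin(a); as_bin(b)
  inter <- sum(a * b)
  uni <- sum(pmax(a, b))
  if (uni == 0) return(100)
  100 * inter / uni
}

#' Border pixels of a binary mask
#'
#' Foreground pixels with at least one 4-neighbor in the background (pixels on
#' the array edge always qualify).
#'
#' @param m Binary matrix.
#' @return Logical matrix marking border pixels.
#' @export
mask_border <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb_min <- pmin(pad[1:H, 2:(W + 1L)], pad[3:(H + 2L), 2:(W + 1L)],
                 pad[2:(H + 1L), 1:W], pad[2:(H + 1L), 3:(W + 2L)])
  core == 1 & nb_min == 0
}

## directed nearest-border distances (pixels): from each border pixel of `a`
## to the border of `b`, via the exact distance transform of b's border
directed_surface_dists <- function(a, b) {
  bb <- mask_border(b)
  d <- edt_cpp(bb * 1)
  d[mask_border(a)]
}

#' Average symmetric surface distance (mm)
#'
#' Mean of the nearest-border distances from A's border to B's border and
#' vice versa, the two directional means averaged; `spacing` converts pixels
#' to mm. Empty masks make the distance undefined (`NA` with a warning).
#'
#' @inheritParams dsc
#' @param spacing Isotropic pixel size in mm (default 1).
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
asd <- function(a, b, spacing = 1) {
  stopifnot(identical(dim(a), dim(b)))
  if (sum(a) == 0 || sum(b) == 0) {
    warning("asd undefined for an empty mask")
    return(NA_real_)
  }
  dab <- directed_surface_dists(a, b)
  dba <- directed_surface_dists(b, a)
  spacing * (mean(dab) + mean(dba)) / 2
}

#' Root-mean-squared surface distance (mm)
#'
#' Square root of the mean squared nearest-border distance, both directions
#' pooled into one sample.
#'
#' @inheritParams asd
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
surface_rmse <- function(a, b, spacing = 1) {
  stopifnot(identical(dim(a), dim(b)))
  if (sum(a) == 0 || sum(b) == 0) {
    warning("surface_rmse undefined for an empty mask")
    return(NA_real_)
  }
  dd <- c(directed_surface_dists(a, b), directed_surface_dists(b, a))
  spacing * sqrt(mean(dd^2))
}

## pooled (multi-slice) surface distances for one case; slices where either
## mask is empty are skipped
case_surface_metrics <- function(pred_slices, truth_slices, spacing) {
  dab <- numeric(0); dba <- numeric(0)
  for (i in seq_along(pred_slices)) {
    p <- pred_slices[[i]]; t <- truth_slices[[i]]
    if (sum(p) == 0 || sum(t) == 0) next
    dab <- c(dab, directed_surface_dists(p, t))
    dba <- c(dba, directed_surface_dists(t, p))
  }
  if (length(dab) == 0)
    return(c(asd = NA_real_, rmse = NA_real_))
  c(asd = spacing * (mean(dab) + mean(dba)) / 2,
    rmse = spacing * sqrt(mean(c(dab, dba)^2)))
}

#' Evaluate predictions against ground truths
#'
#' Binarizes prediction maps at `threshold`, pools all slices of a case
#' (overlap metrics on pooled pixel counts; surface distances pooled over
#' per-slice 2-D borders) and aggregates per-case rows as mean, sample
#' standard deviation (n - 1), min and max.
#'
#' @param pred_maps List of probability maps, aligned with `truths`.
#' @param truths List of binary masks.
#' @param case_ids Integer case id per slice.
#' @param threshold Binarization threshold in `(0, 1)`, default 0.5.
#' @param spacing Isotropic pixel size in mm.
#' @return An `eval_report`: `per_case` data frame
#'   (case_id, dsc, jaccard, asd, rmse) and `aggregate` data frame.
#' @export
evaluate_segmentation <- function(pred_maps, truths, case_ids,
                                  threshold = 0.5, spacing = 1) {
  if (length(pred_maps) != length(truths) ||
      length(truths) != length(case_ids))
    stop("pred_maps, truths and case_ids must have equal length")
  stopifnot(threshold > 0, threshold < 1)
  bins <- lapply(pred_maps, function(p) (p >= threshold) * 1)
  ids <- sort(unique(case_ids))
  rows <- lapply(ids, function(cid) {
    sel <- which(case_ids == cid)
    inter <- sum(vapply(sel, function(i) sum(bins[[i]] * truths[[i]]), 1.0))
    sp <- sum(vapply(sel, function(i) sum(bins[[i]]), 1.0))
    st <- sum(vapply(sel, function(i) sum(truths[[i]]), 1.0))
    uni <- sp + st - inter
    sm <- case_surface_metrics(bins[sel], truths[sel], spacing)
    data.frame(case_id = cid,
               dsc = if (sp + st == 0) 100 else 100 * 2 * inter / (sp + st),
               jaccard = if (uni == 0) 100 else 100 * inter / uni,
               asd = sm[["asd"]], rmse = sm[["rmse"]])
  })
  per_case <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(c("dsc", "jaccard", "asd", "rmse"),
    function(mtr) {
      v <- per_case[[mtr]]
      v <- v[is.finite(v)]
      if (length(v) == 0)
        return(data.frame(metric = mtr, mean = NA_real_, sd = NA_real_,
                          min = NA_real_, max = NA_real_))
      data.frame(metric = mtr, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 min = min(v), max = max(v))
    }))
  structure(list(per_case = per_case, aggregate = agg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$per_case), " case(s)\n", sep = "")
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    unit <- if (a$metric[i] %in% c("dsc", "jaccard")) "%" else " mm"
    cat(sprintf("  %-7s %6.2f +/- %5.2f [%6.2f, %6.2f]%s\n", a$metric[i],
                a$mean[i], a$sd[i], a$min[i], a$max[i], unit))
  }
  invisible(x)
}

#' Write an eval report as CSV (one row per case plus an aggregate block)
#' @param report An `eval_report`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_eval_report <- function(report, file) {
  utils::write.csv(report$per_case, file, row.names = FALSE)
  agg_file <- sub("\\.csv$", "_aggregate.csv", file)
  utils::write.csv(report$aggregate, agg_file, row.names = FALSE)
  invisible(file)
}
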