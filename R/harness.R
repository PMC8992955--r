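## Experiment harness: 4-fold cross-validation per variant and the two-step
## selection protocol (backbone selection among unet/au_net/dau_net, then
## attention-placement selection among dau_net/adau_a1/adau_a2/adau_a3).
## All variants in a plan share the dataset, the folds and the per-fold
## seeds, so compared models consume identical batches in identical order.

#' Experiment plan
#'
#' @param variants Character vector of segmentor variant names to compare.
#' @param phantom A [phantom_config()].
#' @param tc A [train_config()] (shared budget for every variant).
#' @param w A [loss_weights()].
#' @param disc A [discriminator_config()].
#' @param seg_depth,seg_base_channels Segmentor size shared by all variants.
#' @param output_dir Optional run directory for CSVs/figures/checkpoints.
#' @param seed Master seed; per-fold model/batch seeds derive from it.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(variants, phantom = phantom_config(),
                            tc = train_config(), w = loss_weights(),
                            disc = discriminator_config(),
                            seg_depth = 4L, seg_base_channels = 16L,
                            output_dir = NULL, seed = 1L) {
  stopifnot(all(variants %in% SEG_VARIANTS), length(variants) >= 1L)
  structure(list(variants = variants, phantom = phantom, tc = tc, w = w,
                 disc = disc, seg_depth = as.integer(seg_depth),
                 seg_base_channels = as.integer(seg_base_channels),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_plan")
}

plan_dataset <- function(plan) generate_dataset(plan$phantom)

slice_cases <- function(slices) vapply(slices, function(s) s$case_id, 1L)

#' Run 4-fold cross-validation for one variant
#'
#' Trains one model per held-out fold on the other three folds and evaluates
#' it on the held-out cases; per-case rows from the four folds are
#' concatenated, so every case is evaluated exactly once.
#'
#' @param variant Segmentor variant name.
#' @param plan An [experiment_plan()].
#' @param dataset Optional pre-generated `phantom_dataset` (so several
#'   variants share the identical data).
#' @return An `eval_report` with attributes `histories` (per-fold training
#'   histories) and `fold_of_case`.
#' @export
run_cross_validation <- function(variant, plan, dataset = NULL) {
  if (is.null(dataset)) dataset <- plan_dataset(plan)
  folds <- dataset$folds
  cases <- slice_cases(dataset$slices)
  cfg <- segmentor_config(variant, depth = plan$seg_depth,
                          base_channels = plan$seg_base_channels)
  preds <- list(); truths <- list(); pred_cases <- integer(0)
  histories <- vector("list", 4L)
  for (f in 0:3) {
    test_cases <- as.integer(names(folds)[folds == f])
    if (length(test_cases) == 0L) stop("fold ", f, " has zero test cases")
    tr <- dataset$slices[!cases %in% test_cases]
    te <- dataset$slices[cases %in% test_cases]
    stopifnot(!any(slice_cases(tr) %in% slice_cases(te)))   # leakage guard
    model <- build_segmentor(cfg, seed = plan$seed + 100L + f)
    discs <- lapply(seq_len(cfg$n_adv_heads), function(h)
      build_discriminator(plan$disc, seed = plan$seed + 300L + 10L * f + h))
    tc <- plan$tc
    tc$seed <- plan$seed + 200L + f
    histories[[f + 1L]] <- train_segmentor(model, discs, tr, tc, plan$w)
    for (s in te) {
      preds[[length(preds) + 1L]] <- seg_forward(model, s$image)$main_map
      truths[[length(truths) + 1L]] <- s$mask
      pred_cases <- c(pred_cases, s$case_id)
    }
  }
  rep <- evaluate_segmentation(preds, truths, pred_cases)
  attr(rep, "histories") <- histories
  attr(rep, "fold_of_case") <- folds
  attr(rep, "variant") <- variant
  rep
}

select_variants <- function(plan, dataset = NULL) {
  if (is.null(dataset)) dataset <- plan_dataset(plan)
  reports <- lapply(plan$variants, run_cross_validation, plan = plan,
                    dataset = dataset)
  names(reports) <- plan$variants
  means <- vapply(reports, function(r)
    r$aggregate$mean[r$aggregate$metric == "dsc"], 1.0)
  jac <- vapply(reports, function(r)
    r$aggregate$mean[r$aggregate$metric == "jaccard"], 1.0)
  ## argmax mean DSC; ties broken by mean Jaccard, then by variant order
  best <- order(-means, -jac, seq_along(means))[1L]
  curves <- do.call(rbind, lapply(plan$variants, function(v) {
    pc <- reports[[v]]$per_case
    data.frame(variant = v, case_id = pc$case_id, dsc = pc$dsc,
               jaccard = pc$jaccard)
  }))
  structure(list(reports = reports, winner = plan$variants[best],
                 mean_dsc = means, curves = curves),
            class = "selection_report")
}

#' Backbone segmentor selection
#'
#' Cross-validates each backbone candidate (by default `unet`, `au_net`,
#' `dau_net`) under the identical budget and declares the variant with the
#' highest mean DSC the winner.
#'
#' @param plan An [experiment_plan()] whose `variants` are the candidates.
#' @param dataset Optional shared `phantom_dataset`.
#' @return A `selection_report`.
#' @export
select_backbone <- function(plan, dataset = NULL) {
  if (length(plan$variants) < 2L) stop("need at least 2 variants to select")
  select_variants(plan, dataset)
}

#' Attention-placement selection
#'
#' Same protocol as [select_backbone()] over the duplex backbone and its
#' attention-augmented versions (by default `dau_net`, `adau_a1`, `adau_a2`,
#' `adau_a3`).
#'
#' @inheritParams select_backbone
#' @return A `selection_report`.
#' @export
select_attention <- function(plan, dataset = NULL) {
  if (length(plan$variants) < 2L) stop("need at least 2 variants to select")
  select_variants(plan, dataset)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> winner:", x$winner, "\n")
  for (v in names(x$mean_dsc))
    cat(sprintf("  %-8s mean DSC %6.2f%%\n", v, x$mean_dsc[[v]]))
  invisible(x)
}

#' Write selection-report curves and training histories as figures + CSV
#'
#' @param report A `selection_report`.
#' @param output_dir Directory for `curves.csv`, `curves.png`,
#'   `history_<variant>.csv` and `losses.png`.
#' @param histories Optional named list of per-variant training histories.
#' @return Invisibly, the written file paths.
#' @export
plot_reports <- function(report, output_dir, histories = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  cf <- file.path(output_dir, "curves.csv")
  utils::write.csv(report$curves, cf, row.names = FALSE)
  files <- c(files, cf)
  if (!any(is.finite(report$curves$dsc))) {
    warning("plot_reports: empty DSC column, figure omitted")
    return(invisible(files))
  }
  pf <- file.path(output_dir, "curves.png")
  grDevices::png(pf, width = 700, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  vars <- unique(report$curves$variant)
  cols <- grDevices::hcl.colors(max(3L, length(vars)), "Dark 3")
  plot(NULL, xlim = range(report$curves$case_id),
       ylim = range(report$curves$dsc, na.rm = TRUE),
       xlab = "case", ylab = "DSC (%)", main = "Per-case DSC by variant")
  for (i in seq_along(vars)) {
    d <- report$curves[report$curves$variant == vars[i], ]
    graphics::lines(d$case_id, d$dsc, col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("bottomright", legend = vars, col = cols[seq_along(vars)],
                   lty = 1, pch = 16, bty = "n")
  files <- c(files, pf)
  if (!is.null(histories)) {
    for (v in names(histories)) {
      hf <- file.path(output_dir, paste0("history_", v, ".csv"))
      utils::write.csv(histories[[v]], hf, row.names = FALSE)
      files <- c(files, hf)
    }
  }
  invisible(files)
}
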