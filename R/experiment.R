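#' Phantom recovery experiment: train and evaluate the full pipeline
#'
#' Generates a randomized phantom cohort, trains the range-detection model
#' on multi-view fused coronal images and the slice-segmentation model on
#' axial slices, then runs the complete pipeline on held-out phantoms and
#' measures how well the known ground truth is recovered: the mean absolute
#' error of the two detected range endpoints (in original slices) and the
#' mean Dice coefficient of the final post-processed mask against the true
#' mask.
#'
#' The default problem sizes (150 training phantoms of 64 x 96 x 96 voxels,
#' 400 training slices, 30 held-out phantoms, single-digit epoch counts and
#' compact model configurations) are chosen so the whole experiment runs in
#' minutes on one CPU core while still exercising every stage of the
#' method.
#'
#' @param n_train,n_test phantom counts for training and held-out
#'   evaluation.
#' @param seg_slices number of axial slices drawn (across training
#'   phantoms) for segmentation training.
#' @param range_views fused-coronal views per phantom in the range training
#'   set.
#' @param range_epochs,seg_epochs training epochs for the two models.
#' @param range_cfg,seg_cfg model configurations; the defaults are the
#'   desk-scale toy settings.
#' @param pipe pipeline settings ([pipeline_config()]); its model configs
#'   are ignored in favour of `range_cfg`/`seg_cfg`.
#' @param seed master seed; every stage derives its randomness from it.
#' @param verbose print per-stage progress to stderr.
#' @return A `phantom_recovery` list: `range_mae` (length-2, lower/upper
#'   endpoint MAE in slices), `mean_dice`, `mean_iou`, `per_case`
#'   data frame, the trained `range_model` and `seg_model`, and timings.
#' @export
phantom_recovery_experiment <- function(n_train = 150, n_test = 30,
                                        seg_slices = 400, range_views = 3,
                                        range_epochs = 8, seg_epochs = 6,
                                        range_cfg = NULL, seg_cfg = NULL,
                                        pipe = pipeline_config(),
                                        seed = 42, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(range_cfg)) range_cfg <- range_model_config(seed = seed)
  if (is.null(seg_cfg)) {
    seg_cfg <- seg_model_config(levels = 4, base_channels = 8,
                                max_channels = 64, seed = seed)
  }
  t0 <- proc.time()[3]

  say("generating %d training phantoms", n_train)
  train <- generate_training_set(n_train, seed = seed)

  say("preparing range-detection training set (%d views/phantom)",
      range_views)
  imgs <- vector("list", n_train * range_views)
  labs <- vector("list", n_train * range_views)
  ii <- 0
  for (ph in train) {
    iso_ct <- resample_isotropic(ph$ct, pipe$iso_mm)
    iso_mk <- resample_isotropic(ph$mask, pipe$iso_mm)
    lab <- derive_range_label(iso_mk)
    views <- sample_fusion_positions(pipe$fractions, range_views,
                                     pipe$max_offset, seed = ph$spec$seed)
    for (v in views) {
      ii <- ii + 1
      imgs[[ii]] <- extract_fused_coronal(iso_ct, v, pipe$hu_window)$channels
      labs[[ii]] <- lab
    }
  }

  say("training range model (%d epochs)", range_epochs)
  range_model <- build_range_model(range_cfg)
  range_model <- train_range_model(range_model, imgs, labs,
                                   epochs = range_epochs, seed = seed)
  t_range <- proc.time()[3] - t0

  say("preparing %d segmentation slices", seg_slices)
  slices <- list(); masks <- list()
  with_seed(seed + 1L, {
    per_ph <- ceiling(seg_slices / n_train)
    for (ph in train) {
      nz <- dim(ph$mask$voxels)[1]
      nonempty <- which(rowSums(matrix(ph$mask$voxels, nrow = nz)) > 0)
      empty <- setdiff(seq_len(nz), nonempty)
      # mostly muscle-bearing slices, plus an occasional empty one so the
      # model sees both regimes
      pick <- sample(nonempty, min(per_ph, length(nonempty)))
      if (length(empty) && stats::runif(1) < 0.25) {
        pick <- c(pick, sample(empty, 1))
      }
      for (z in pick) {
        if (length(slices) >= seg_slices) break
        slices[[length(slices) + 1]] <-
          normalize_intensity(ph$ct$voxels[z, , ], pipe$hu_window)
        masks[[length(masks) + 1]] <- ph$mask$voxels[z, , ]
      }
    }
  })

  say("training segmentation model on %d slices (%d epochs)",
      length(slices), seg_epochs)
  seg_model <- build_seg_model(seg_cfg)
  seg_model <- train_seg_model(seg_model, slices, masks, epochs = seg_epochs,
                               lr = 2e-3, seed = seed)
  t_seg <- proc.time()[3] - t_range - t0

  say("evaluating on %d held-out phantoms", n_test)
  test <- generate_training_set(n_test, seed = seed + 1000L)
  per_case <- data.frame(case = integer(0), err_lo = numeric(0),
                         err_hi = numeric(0), dice = numeric(0),
                         iou = numeric(0), volume_cc = numeric(0),
                         true_volume_cc = numeric(0))
  for (i in seq_len(n_test)) {
    ph <- test[[i]]
    res <- run_pipeline(ph$ct, pipe, range_model = range_model,
                        seg_model = seg_model, truth = ph$mask)
    nz <- dim(ph$mask$voxels)[1]
    tz <- which(rowSums(matrix(ph$mask$voxels, nrow = nz)) > 0)
    per_case[i, ] <- list(i,
                          abs(res$report$slice_interval[1] - min(tz)),
                          abs(res$report$slice_interval[2] - (max(tz) + 1L)),
                          res$report$metrics$dsc, res$report$metrics$iou,
                          res$report$quant$volume_cc,
                          quantify_muscle(ph$ct, ph$mask)$volume_cc)
  }
  out <- structure(list(
    range_mae = c(lower = mean(per_case$err_lo),
                  upper = mean(per_case$err_hi)),
    mean_dice = mean(per_case$dice),
    mean_iou = mean(per_case$iou),
    per_case = per_case,
    range_model = range_model, seg_model = seg_model,
    timings = c(range_s = unname(t_range), seg_s = unname(t_seg),
                total_s = unname(proc.time()[3] - t0)),
    seed = seed), class = "phantom_recovery")
  say("done: endpoint MAE %.2f/%.2f slices, mean Dice %.3f (%.0f s)",
      out$range_mae[1], out$range_mae[2], out$mean_dice,
      out$timings["total_s"])
  out
}

#' @export
print.phantom_recovery <- function(x, ...) {
  cat(sprintf("<phantom_recovery> %d held-out phantoms\n", nrow(x$per_case)))
  cat(sprintf("  range endpoint MAE: %.2f (lower) / %.2f (upper) slices\n",
              x$range_mae[1], x$range_mae[2]))
  cat(sprintf("  mean Dice %.3f, mean IoU %.3f\n", x$mean_dice, x$mean_iou))
  invisible(x)
}
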