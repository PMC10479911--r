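#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end method: denoising, isotropic
#' resampling spacing, HU window, fusion fractions and jitter, number of
#' prediction views, the two model configurations (or checkpoint paths),
#' post-processing settings, and the global seed.
#'
#' @param iso_mm isotropic spacing for range detection (default 2 mm).
#' @param hu_window intensity window (default `c(-200, 300)` HU).
#' @param fractions,max_offset coronal fusion positions and rigid jitter.
#' @param n_views views median-aggregated at prediction (default 5).
#' @param denoise_method,denoise_strength optional smoothing hook
#'   (default `"none"`).
#' @param range_cfg,seg_cfg model configurations.
#' @param range_checkpoint,seg_checkpoint optional paths to saved trained
#'   models; loaded by [run_pipeline()] when model handles are not supplied.
#' @param post post-processing settings ([postprocess_config()]).
#' @param threshold segmentation probability cutoff.
#' @param seed global seed.
#' @param output_dir where [run_pipeline()] writes masks/reports (`NULL`
#'   disables writing).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(iso_mm = 2, hu_window = c(-200, 300),
                            fractions = c(3, 4, 5) / 8, max_offset = 1 / 16,
                            n_views = 5, denoise_method = "none",
                            denoise_strength = 1,
                            range_cfg = range_model_config(),
                            seg_cfg = seg_model_config(),
                            range_checkpoint = NULL, seg_checkpoint = NULL,
                            post = postprocess_config(), threshold = 0.5,
                            seed = 1, output_dir = NULL) {
  stopifnot(iso_mm > 0, n_views >= 1)
  structure(list(iso_mm = iso_mm, hu_window = hu_window,
                 fractions = fractions, max_offset = max_offset,
                 n_views = as.integer(n_views),
                 denoise_method = denoise_method,
                 denoise_strength = denoise_strength,
                 range_cfg = range_cfg, seg_cfg = seg_cfg,
                 range_checkpoint = range_checkpoint,
                 seg_checkpoint = seg_checkpoint, post = post,
                 threshold = threshold, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' blocks `range_model`, `seg_model` and `postprocess` mirror
#' [range_model_config()], [seg_model_config()] and [postprocess_config()].
#' Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("iso_mm", "hu_window", "fractions",
                                  "max_offset", "n_views", "denoise_method",
                                  "denoise_strength", "range_checkpoint",
                                  "seg_checkpoint", "threshold", "seed",
                                  "output_dir"))]
  if (!is.null(y$range_model)) {
    args$range_cfg <- do.call(range_model_config, y$range_model)
  }
  if (!is.null(y$seg_model)) {
    args$seg_cfg <- do.call(seg_model_config, y$seg_model)
  }
  if (!is.null(y$postprocess)) {
    args$post <- do.call(postprocess_config, y$postprocess)
  }
  do.call(pipeline_config, args)
}

#' Save / load a trained model checkpoint
#'
#' Checkpoints are RDS serializations of the model handle (parameters,
#' batch-norm statistics, config, training report).
#'
#' @param model a `range_model` or `seg_model`.
#' @param path destination / source path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "range_model") || inherits(model, "seg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  m <- readRDS(path)
  if (!(inherits(m, "range_model") || inherits(m, "seg_model"))) {
    stop("file is not a model checkpoint: ", path)
  }
  m
}

#' Run the full segmentation pipeline on one CT volume
#'
#' Executes the method end to end: optional denoising, isotropic resampling,
#' multichannel-coronal range detection with median aggregation, per-slice
#' U-Net segmentation of the original axial slices inside the detected
#' range, per-slice and 3D post-processing, and volumetry/densitometry.
#' When a ground-truth mask is supplied, agreement metrics are added to the
#' report.
#'
#' @param ct a [ct_volume()] or a NIfTI path.
#' @param cfg a [pipeline_config()].
#' @param range_model,seg_model trained model handles; when `NULL` the
#'   checkpoints named in `cfg` are loaded.
#' @param truth optional [mask_volume()] or NIfTI path.
#' @param visual_grade optional human 1-10 grade stored verbatim in the
#'   report (never computed).
#' @return `list(report = quant_report, mask = mask_volume)`. The report
#'   holds the case id, detected slice interval, `muscle_quant`, optional
#'   `segmentation_metrics`, and warnings. If `cfg$output_dir` is set, the
#'   mask (`<case>_mask.nii.gz`) and report (`<case>_report.json`) are
#'   written there.
#' @export
run_pipeline <- function(ct, cfg = pipeline_config(), range_model = NULL,
                         seg_model = NULL, truth = NULL,
                         visual_grade = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(ct)) ct <- load_volume(ct, "ct")
  if (is.character(truth)) truth <- load_volume(truth, "mask")
  if (is.null(range_model)) {
    if (is.null(cfg$range_checkpoint)) stop("no range model or checkpoint")
    range_model <- load_checkpoint(cfg$range_checkpoint)
  }
  if (is.null(seg_model)) {
    if (is.null(cfg$seg_checkpoint)) stop("no segmentation model or checkpoint")
    seg_model <- load_checkpoint(cfg$seg_checkpoint)
  }
  warnings_out <- character(0)

  ct_in <- denoise(ct, cfg$denoise_method, cfg$denoise_strength)
  iso <- resample_isotropic(ct_in, cfg$iso_mm, "linear")
  rng <- withCallingHandlers(
    predict_range(range_model, iso, n_views = cfg$n_views,
                  fractions = cfg$fractions, max_offset = cfg$max_offset,
                  window = cfg$hu_window, seed = cfg$seed),
    warning = function(w) {
      warnings_out <<- c(warnings_out, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (rng$empty) {
    mask <- mask_volume(array(0L, dim = dim(ct$voxels)), ct$spacing,
                        ct$origin, ct$source_id)
  } else {
    mask <- withCallingHandlers(
      predict_slice_masks(seg_model, ct_in, rng$slice_interval,
                          window = cfg$hu_window, threshold = cfg$threshold),
      warning = function(w) {
        warnings_out <<- c(warnings_out, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    mask <- postprocess_mask(mask, cfg$post)
  }
  quant <- quantify_muscle(ct, mask)
  metrics <- if (!is.null(truth)) segmentation_metrics(mask, truth) else NULL
  if (!is.null(visual_grade)) {
    stopifnot(visual_grade >= 1, visual_grade <= 10)
  }
  report <- structure(list(case_id = ct$source_id,
                           slice_interval = rng$slice_interval,
                           iso_interval = rng$iso_interval,
                           quant = quant, metrics = metrics,
                           visual_grade = visual_grade,
                           warnings = warnings_out),
                      class = "quant_report")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    base <- if (nzchar(ct$source_id)) gsub("[^A-Za-z0-9_.-]", "_",
                                           ct$source_id) else "case"
    save_volume(mask, file.path(cfg$output_dir,
                                paste0(base, "_mask.nii.gz")))
    writeLines(report_to_json(report),
               file.path(cfg$output_dir, paste0(base, "_report.json")))
  }
  list(report = report, mask = mask)
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> case '%s', slices [%d, %d)\n", x$case_id,
              x$slice_interval[1], x$slice_interval[2]))
  print(x$quant)
  if (!is.null(x$metrics)) print(x$metrics)
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Serialize / restore a quantification report as JSON
#'
#' The round trip is lossless for every report field (per-slice areas
#' included).
#'
#' @param report a `quant_report`.
#' @param json a JSON string from `report_to_json`.
#' @return A JSON string / a `quant_report`.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "quant_report"))
  x <- unclass(report)
  x$quant <- unclass(x$quant)
  if (!is.null(x$metrics)) x$metrics <- unclass(x$metrics)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname report_to_json
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$quant <- structure(x$quant, class = "muscle_quant")
  if (!is.null(x$metrics)) {
    x$metrics <- structure(x$metrics, class = "segmentation_metrics")
  }
  x$slice_interval <- as.integer(x$slice_interval)
  x$iso_interval <- as.integer(x$iso_interval)
  if (is.null(x$warnings)) x$warnings <- character(0)
  structure(x, class = "quant_report")
}

#' Split case ids into training and validation sets
#'
#' Seeded random split with `round(ratio * n)` training cases; the two sets
#' are disjoint and exhaustive.
#'
#' @param case_ids vector of ids.
#' @param ratio training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @return `list(train =, validation =)`.
#' @export
split_dataset <- function(case_ids, ratio = 0.8, seed = 1) {
  if (!length(case_ids)) stop("empty case list")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- length(case_ids)
  n_train <- round(ratio * n)
  perm <- with_seed(seed, sample.int(n))
  list(train = case_ids[sort(perm[seq_len(n_train)])],
       validation = case_ids[sort(perm[setdiff(seq_len(n), seq_len(n_train))])])
}

#' One active-learning round for the segmentation model
#'
#' Mirrors the incremental annotation workflow: predictions for each
#' unlabeled case are exported to `corrections_dir` as
#' `<case>_pred.nii.gz`; an annotator drops corrected masks there as
#' `<case>_corrected.nii.gz`. Corrected cases are merged into the training
#' pool and the model is retrained *from the prior checkpoint* (transfer
#' learning). With no corrections present, retraining is skipped with a
#' notice and the checkpoint is returned unchanged.
#'
#' @param seg_checkpoint path to the prior trained segmentation model.
#' @param range_model trained range model used to locate slices.
#' @param unlabeled named list of [ct_volume()]s (or NIfTI paths); names are
#'   the case ids.
#' @param corrections_dir directory for predictions and corrections.
#' @param cfg a [pipeline_config()].
#' @param epochs,lr retraining settings.
#' @return `list(checkpoint =, manifest =)`; the manifest records per-round
#'   pool sizes and corrected case ids.
#' @export
active_learning_round <- function(seg_checkpoint, range_model, unlabeled,
                                  corrections_dir, cfg = pipeline_config(),
                                  epochs = 2, lr = 1e-3) {
  model <- load_checkpoint(seg_checkpoint)
  stopifnot(inherits(model, "seg_model"))
  dir.create(corrections_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(unlabeled)
  if (is.null(ids)) ids <- sprintf("case%03d", seq_along(unlabeled))

  for (i in seq_along(unlabeled)) {
    ct <- unlabeled[[i]]
    if (is.character(ct)) ct <- load_volume(ct, "ct")
    res <- run_pipeline(ct, cfg, range_model = range_model, seg_model = model)
    save_volume(res$mask,
                file.path(corrections_dir, paste0(ids[i], "_pred.nii.gz")))
  }

  corrected <- list.files(corrections_dir, pattern = "_corrected\\.nii\\.gz$",
                          full.names = TRUE)
  if (!length(corrected)) {
    message("no corrected masks found; retraining skipped")
    manifest <- data.frame(round = NA_integer_, pool_before = length(unlabeled),
                           corrections = 0L, pool_after = length(unlabeled))
    return(list(checkpoint = seg_checkpoint, manifest = manifest))
  }

  slices <- list(); masks <- list()
  for (path in corrected) {
    cid <- sub("_corrected\\.nii\\.gz$", "", basename(path))
    j <- match(cid, ids)
    if (is.na(j)) next
    ct <- unlabeled[[j]]
    if (is.character(ct)) ct <- load_volume(ct, "ct")
    corr <- load_volume(path, "mask")
    nz <- dim(corr$voxels)[1]
    keep <- which(rowSums(matrix(corr$voxels, nrow = nz)) > 0)
    for (z in keep) {
      slices[[length(slices) + 1]] <-
        normalize_intensity(ct$voxels[z, , ], cfg$hu_window)
      masks[[length(masks) + 1]] <- corr$voxels[z, , ]
    }
  }
  if (!length(slices)) {
    message("corrected masks matched no unlabeled case; retraining skipped")
    manifest <- data.frame(round = NA_integer_, pool_before = length(unlabeled),
                           corrections = length(corrected),
                           pool_after = length(unlabeled))
    return(list(checkpoint = seg_checkpoint, manifest = manifest))
  }
  # Pad training slices to the divisibility constraint of the model.
  div <- 2^(model$cfg$levels - 1)
  slices <- lapply(slices, pad_to_multiple, div = div)
  masks <- lapply(masks, pad_to_multiple, div = div)
  model2 <- train_seg_model(model, slices, masks, epochs = epochs, lr = lr,
                            seed = cfg$seed,
                            init_weights = list(params = model$params,
                                                state = model$state))
  new_ckpt <- sub("(\\.rds)?$", "_next.rds", seg_checkpoint)
  save_checkpoint(model2, new_ckpt)
  manifest <- data.frame(round = model2$epochs_trained,
                         pool_before = length(unlabeled),
                         corrections = length(corrected),
                         pool_after = length(unlabeled) + length(corrected))
  list(checkpoint = new_ckpt, manifest = manifest)
}

# Zero-pad a matrix on the bottom/right to multiples of `div`.
pad_to_multiple <- function(m, div) {
  H <- nrow(m); W <- ncol(m)
  Hp <- as.integer(ceiling(H / div) * div)
  Wp <- as.integer(ceiling(W / div) * div)
  if (Hp == H && Wp == W) return(m)
  out <- matrix(0, Hp, Wp)
  out[seq_len(H), seq_len(W)] <- m
  out
}
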