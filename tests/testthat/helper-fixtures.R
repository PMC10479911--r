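# Shared fixtures: tiny phantoms and toy trained models, built in code.

tiny_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(shape = c(24, 48, 48), spacing = c(1.5, 1.5, 3),
               muscle_z_fraction = c(0.25, 0.7), muscle_thickness_px = 6,
               noise_sd = 5, seed = seed, ...)
}

# Brute-force overlap metrics by explicit voxel counting (independent of
# segmentation_metrics' arithmetic).
oracle_metrics <- function(r, t) {
  inter <- 0; nr <- 0; nt <- 0; agree <- 0
  for (i in seq_along(r)) {
    ri <- r[i] > 0; ti <- t[i] > 0
    if (ri && ti) inter <- inter + 1
    if (ri) nr <- nr + 1
    if (ti) nt <- nt + 1
    if (ri == ti) agree <- agree + 1
  }
  list(dsc = if (nr + nt == 0) 1 else 2 * inter / (nr + nt),
       iou = if (nr + nt - inter == 0) 1 else inter / (nr + nt - inter),
       precision = if (nr == 0) as.numeric(nt == 0) else inter / nr,
       pixel_accuracy = agree / length(r))
}

# Brute-force per-column median + longest run of ones via scan.
oracle_median_interval <- function(votes) {
  med <- apply(votes, 2, function(col) {
    m <- stats::median(col)
    as.integer(m >= 0.5)
  })
  best_len <- 0; best_lo <- 1; cur_len <- 0; cur_lo <- 1
  for (i in seq_along(med)) {
    if (med[i] == 1) {
      if (cur_len == 0) cur_lo <- i
      cur_len <- cur_len + 1
      if (cur_len > best_len) { best_len <- cur_len; best_lo <- cur_lo }
    } else cur_len <- 0
  }
  if (best_len == 0) list(binary = med, interval = c(1L, 1L))
  else list(binary = med, interval = c(best_lo, best_lo + best_len))
}

# One pair of toy trained models on tiny phantoms, cached per test run.
.tiny_models_cache <- new.env(parent = emptyenv())
tiny_trained_models <- function() {
  if (!is.null(.tiny_models_cache$models)) return(.tiny_models_cache$models)
  train <- generate_training_set(10, seed = 7, shape = c(24, 48, 48),
                                 spec_ranges = list(f_lo = c(0.2, 0.3),
                                                    span = c(0.3, 0.4),
                                                    thickness_px = c(5, 7),
                                                    distractors = 0,
                                                    low_dose_prop = 0.5))
  imgs <- list(); labs <- list()
  for (ph in train) {
    iso_ct <- resample_isotropic(ph$ct, 2)
    iso_mk <- resample_isotropic(ph$mask, 2)
    lab <- derive_range_label(iso_mk)
    for (v in sample_fusion_positions(n = 2, seed = ph$spec$seed)) {
      imgs[[length(imgs) + 1]] <- extract_fused_coronal(iso_ct, v)$channels
      labs[[length(labs) + 1]] <- lab
    }
  }
  rmod <- build_range_model(range_model_config(encoder_width = 0.2,
                                               encoder_depth = 2,
                                               out_bins = 32, seed = 7))
  rmod <- train_range_model(rmod, imgs, labs, epochs = 6, seed = 7)

  slices <- list(); masks <- list()
  set.seed(7)
  for (ph in train) {
    nz <- dim(ph$mask$voxels)[1]
    nonempty <- which(rowSums(matrix(ph$mask$voxels, nrow = nz)) > 0)
    for (z in sample(nonempty, 4)) {
      slices[[length(slices) + 1]] <- normalize_intensity(ph$ct$voxels[z, , ])
      masks[[length(masks) + 1]] <- ph$mask$voxels[z, , ]
    }
  }
  smod <- build_seg_model(seg_model_config(levels = 3, base_channels = 6,
                                           max_channels = 24, seed = 7))
  smod <- train_seg_model(smod, slices, masks, epochs = 6, lr = 2e-3,
                          seed = 7)
  .tiny_models_cache$models <- list(range = rmod, seg = smod, train = train)
  .tiny_models_cache$models
}
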