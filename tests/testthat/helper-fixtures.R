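# Shared fixtures, generated once per test run.

small_phantom_cfg <- function(seed = 1L, n = 3L, shape = 40L)
  phantom_config(shape = shape, n_lesions = n, lesion_radius_range = c(2, 3.5),
                 lesion_contrast = 0.4, noise_sd = 0.03, seed = seed)

# high-contrast, low-noise conditions with large new lesions: the "easy"
# regime for the scaled-down end-to-end recovery runs
easy_phantom_cfg <- function(seed, n = 2L)
  phantom_config(shape = 48, n_lesions = n, lesion_radius_range = c(2, 3.5),
                 lesion_contrast = 0.5, noise_sd = 0.02, seed = seed)

the <- new.env()

get_small_phantom <- function() {
  if (is.null(the$ph)) the$ph <- make_phantom(small_phantom_cfg())
  the$ph
}

# CPU-scale spec; no instance norm so feature statistics do not depend on
# the inference window size (training uses 16^3 patches, inference larger)
test_net_spec <- function(base = 4L)
  network_spec(levels = 2L, base_channels = base, convs_per_block = 1L,
               norm = FALSE)

# Scaled-down three-stage pipeline: stage-1 pretraining on single
# time-point phantoms, stage-2 ensemble pretraining on synthetic pairs,
# optional stage-3 fine-tuning on ground-truth longitudinal pairs, and
# evaluation on held-out easy pairs.
run_scaled_pipeline <- function(seed0, n_models = 3L, n_pairs = 40L,
                                n_eval = 10L, stage1_steps = 250L,
                                stage2_steps = 800L, stage3_steps = 0L,
                                lr = 1e-3, stage2_pf = 0.5) {
  ph_train <- lapply(1:6, function(i) {
    p <- make_phantom(easy_phantom_cfg(seed0 * 1000 + i, n = 3L))
    list(volume = p$volume, mask = p$mask, tissue = p$tissue, atlas = p$atlas)
  })
  spec <- test_net_spec()
  ck1 <- train_stage(1, ph_train, NULL,
                     train_config(stage = 1, patch_size = 16,
                                  steps = stage1_steps, learning_rate = 1e-3,
                                  positive_fraction = 1, seed = seed0), spec)
  syn_aug <- augment_config(probabilities = c(noise = 1),
                            noise_sd_range = c(0.02, 0.05))
  syn_cfg <- synthesis_config(generated_contrast = 0.5,
                              generated_radius_range = c(3, 4.5))
  pairs <- lapply(seq_len(n_pairs), function(i) {
    src <- ph_train[[((i - 1) %% length(ph_train)) + 1]]
    suppressWarnings(synthesize_pair(src$volume, src$mask, src$tissue,
                                     src$atlas, syn_cfg, aug_cfg = syn_aug,
                                     seed = seed0 * 10000 + i))
  })
  cks2 <- lapply(seq_len(n_models), function(f)
    suppressWarnings(train_stage(2, pairs, ck1,
                                 train_config(stage = 2, patch_size = 16,
                                              steps = stage2_steps,
                                              learning_rate = lr,
                                              positive_fraction = stage2_pf,
                                              val_every = 50L,
                                              seed = seed0 + 100 * f))))
  cks3 <- NULL
  if (stage3_steps > 0L) {
    real_pairs <- lapply(1:4, function(i)
      make_longitudinal_truth(easy_phantom_cfg(seed0 * 77777 + i), n_new = 2L))
    cks3 <- lapply(seq_along(cks2), function(f)
      suppressWarnings(train_stage(3, real_pairs, cks2[[f]],
                                   train_config(stage = 3, patch_size = 16,
                                                steps = stage3_steps,
                                                learning_rate = lr,
                                                seed = seed0 + 500 * f))))
  }
  eval_res <- lapply(seq_len(n_eval), function(i) {
    tr <- make_longitudinal_truth(easy_phantom_cfg(seed0 * 55555 + i), n_new = 2L)
    pred <- ensemble_predict(cks3 %||% cks2, tr$tp1, tr$tp2, patch_size = 48)
    evaluate_case(pred, tr$new_mask)
  })
  # a case with lesions but an empty prediction is a complete miss: LesF1 0
  f1s <- vapply(eval_res, function(r) {
    if (!r$lesion$pl_defined && r$lesion$sl_defined && r$lesion$SL == 0) 0
    else r$lesion$les_f1
  }, numeric(1))
  list(ck1 = ck1, cks2 = cks2, cks3 = cks3,
       dice = mean(vapply(eval_res, function(r) r$voxel$dice, numeric(1))),
       les_f1 = mean(f1s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
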