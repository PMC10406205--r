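# Three-stage training orchestration: single-time-point pretraining,
# synthetic-pair pretraining with a frozen encoder, and fine-tuning on real
# pairs. Optimizer is Adam (lr 1e-4, beta1 0.9 by default); the loss is the
# soft dice loss for the segmentation tasks and MSE for the
# inpainting/generation regressors.

#' Training configuration
#'
#' @param stage Pipeline stage, 1 (single-time-point segmentation), 2
#'   (synthetic-pair pretraining) or 3 (fine-tuning on real pairs).
#' @param patch_size Training patch edge length(s) in voxels (default 64^3).
#' @param steps Optimizer steps.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param adam_beta1 Adam first-moment decay (default 0.9; "momentum").
#' @param adam_beta2,adam_eps Remaining Adam constants.
#' @param ensemble_size Networks in the ensemble (default 5, one per
#'   training/validation split).
#' @param freeze_encoder Freeze encoder + bottleneck parameters; must be
#'   `TRUE` for stages 2 and 3 (the encoder is trained in stage 1 only).
#' @param positive_fraction Fraction of training patches centred inside a
#'   positive component (class-imbalance oversampling).
#' @param val_fraction Fraction of samples held out per validation split.
#' @param val_every Validation cadence in steps (best-validation checkpoint
#'   is kept); 0 disables validation tracking.
#' @param grad_clip Global-norm gradient clipping threshold (stabilizes the
#'   dice loss against early softmax saturation); `Inf` disables.
#' @param augment `NULL` or an [augment_config()] applied to training patches.
#' @param seed Integer seed governing all randomness of the run.
#' @return A list of class `ll_train_config`.
#' @export
train_config <- function(stage, patch_size = c(64, 64, 64), steps = 200L,
                         learning_rate = 1e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         ensemble_size = 5L, freeze_encoder = (stage != 1L),
                         positive_fraction = 0.5, val_fraction = 0.2,
                         val_every = 0L, grad_clip = 1, augment = NULL,
                         seed = 1L) {
  if (!stage %in% 1:3) stopf("stage must be 1, 2 or 3")
  if (stage != 1L && !freeze_encoder)
    stopf("freeze_encoder may be FALSE only for stage 1")
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  structure(list(stage = as.integer(stage), patch_size = as.integer(patch_size),
                 steps = as.integer(steps), learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, ensemble_size = as.integer(ensemble_size),
                 freeze_encoder = isTRUE(freeze_encoder),
                 positive_fraction = positive_fraction,
                 val_fraction = val_fraction, val_every = as.integer(val_every),
                 grad_clip = grad_clip, augment = augment,
                 seed = as.integer(seed)),
            class = "ll_train_config")
}

#' Soft dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with probabilities
#' as continuous values; lies in `[0, 1]`.
#'
#' @param probabilities Array of per-voxel foreground probabilities in `[0,1]`.
#' @param target_mask Binary array on the same grid.
#' @param eps Stabilizer (default 1e-5).
#' @return Scalar loss.
#' @export
dice_loss <- function(probabilities, target_mask, eps = 1e-5) {
  p <- as_arr(probabilities); t <- as_arr(target_mask)
  if (!identical(dim(p), dim(t))) stopf("probability/target grid mismatch")
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

# gradient of dice_loss w.r.t. p
dice_loss_grad <- function(p, t, eps = 1e-5) {
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  -(2 * t * den - num) / den^2
}

## ---- patch sampling --------------------------------------------------

default_brain_mask <- function(vol) {
  a <- as_arr(vol)
  thr <- 0.25 * stats::quantile(a, 0.99, names = FALSE)
  a > thr
}

clamp_center <- function(center, d, ps) {
  half <- ps %/% 2L
  pmin(pmax(center, half), d - (ps - half))   # keeps the patch inside the grid
}

#' Sample a training patch, oversampling the positive class
#'
#' With probability `positive_fraction` the patch is centred on a random
#' voxel of a positive component; otherwise the centre is uniform over the
#' brain support. Centres are clamped so the patch lies inside the grid.
#'
#' @param volumes A single volume or list of aligned volumes (e.g. the two
#'   time-points).
#' @param mask Positive-class `ll_mask` (lesion or new-lesion mask).
#' @param patch_size Patch edge lengths.
#' @param positive_fraction Probability of centring on a positive voxel. If
#'   positives are requested but the mask is empty, sampling falls back to
#'   uniform with a warning.
#' @param brain_mask Optional logical array of brain support; derived by
#'   intensity thresholding when absent.
#' @return List with `patches` (list of arrays, one per input volume),
#'   `target` (mask patch array) and `center` (0-based).
#' @export
sample_training_patch <- function(volumes, mask, patch_size,
                                  positive_fraction = 0.5, brain_mask = NULL) {
  if (inherits(volumes, "ll_volume")) volumes <- list(volumes)
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  d <- dim(volumes[[1]]$data)
  want_pos <- runif(1) < positive_fraction
  pos_idx <- which(mask$data > 0)
  if (want_pos && length(pos_idx) == 0L) {
    warning("positive patch requested but mask is empty; sampling uniformly")
    want_pos <- FALSE
  }
  center <- if (want_pos) {
    arrayInd(pos_idx[sample.int(length(pos_idx), 1L)], d)[1, ] - 1L
  } else {
    if (is.null(brain_mask)) brain_mask <- default_brain_mask(volumes[[1]])
    bidx <- which(brain_mask)
    arrayInd(bidx[sample.int(length(bidx), 1L)], d)[1, ] - 1L
  }
  center <- clamp_center(center, d, as.integer(patch_size))
  spec <- patch_spec(center, patch_size)
  list(patches = lapply(volumes, function(v) extract_patch(v, spec)$data),
       target = extract_patch(lesion_mask(mask$data, mask$spacing), spec)$data,
       center = center)
}

## ---- optimizer -------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg, frozen = character()) {
  clip <- cfg$grad_clip %||% Inf
  if (is.finite(clip)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm > clip) grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  for (nm in names(grads)) {
    if (any(startsWith(nm, frozen))) next
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

## ---- training steps --------------------------------------------------

# one optimizer step on a (inputs..., target) tuple; returns loss + updates
segmentation_step <- function(net, inputs, target, opt_state, cfg) {
  fw <- do.call(network_forward, c(list(net), inputs, list(with_tape = TRUE)))
  d <- dim(fw$out)
  p <- array(fw$out[, , , 2L], dim = d[1:3])
  loss <- dice_loss(p, target)
  gp <- dice_loss_grad(p, target)
  gout <- array(0, dim = d)
  gout[, , , 2L] <- gp
  grads <- tape_backward(fw$tape, fw$out_node, gout)
  upd <- adam_step(net$params, grads, opt_state, cfg, net$frozen)
  net$params <- upd$params
  list(net = net, opt_state = upd$state, loss = loss)
}

regression_step <- function(net, input, target, opt_state, cfg) {
  fw <- network_forward(net, input, with_tape = TRUE)
  d <- dim(fw$out)
  res <- fw$out - array(target, dim = d)
  loss <- mean(res^2)
  grads <- tape_backward(fw$tape, fw$out_node, 2 * res / length(res))
  upd <- adam_step(net$params, grads, opt_state, cfg, net$frozen)
  net$params <- upd$params
  list(net = net, opt_state = upd$state, loss = loss)
}

checkpoint <- function(net, stage, cfg, lineage = character(), history = NULL,
                       val_loss = NA_real_) {
  structure(list(params = net$params, spec = net$spec, kind = net$kind,
                 frozen = net$frozen, stage = stage,
                 lineage = c(lineage, paste0("stage", stage)),
                 history = history, val_loss = val_loss,
                 package_version = as.character(utils::packageVersion("longlesion"))),
            class = "ll_checkpoint")
}

#' @export
print.ll_checkpoint <- function(x, ...) {
  cat(sprintf("<ll_checkpoint %s, stage %d, lineage %s>\n", x$kind, x$stage,
              paste(x$lineage, collapse = " -> ")))
  invisible(x)
}

checkpoint_to_network <- function(ckpt) {
  new_network(ckpt$spec, ckpt$kind, ckpt$params, ckpt$frozen)
}

#' Save / load a training checkpoint
#' @param ckpt An `ll_checkpoint`.
#' @param path File path (`.rds`).
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) { saveRDS(ckpt, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "ll_checkpoint")) stopf("not a checkpoint file: %s", path)
  ckpt
}

draw_sample <- function(data, i) if (is.function(data)) data(i) else
  data[[((i - 1L) %% length(data)) + 1L]]

n_samples <- function(data) if (is.function(data)) Inf else length(data)

#' Train one stage of the pipeline
#'
#' * Stage 1 trains encoder + decoder of the single-time-point U-Net on
#'   (volume, lesion mask) samples, with optional artifact augmentation.
#' * Stage 2 builds the siamese new-lesion network from the stage-1 encoder
#'   (copied by layer name and frozen) and trains the aggregation blocks and
#'   decoder on synthetic pairs.
#' * Stage 3 continues training aggregation + decoder on real pairs with the
#'   encoder still frozen.
#'
#' Optimization is Adam with the configured learning rate and `beta1`, and
#' the soft dice loss. With `val_every > 0`, a validation subset is held out
#' (by sample id) and the best-validation-loss parameters are returned.
#'
#' @param stage 1, 2 or 3 (must match `cfg$stage`).
#' @param data Stage 1: list of `list(volume, mask)`. Stages 2-3: list of
#'   `list(tp1, tp2, new_mask)`, or a function `f(i)` generating the i-th
#'   sample on the fly (stage 2 synthetic pairs).
#' @param network For stage 1: an optional `ll_network` (a fresh
#'   segmentation U-Net is built from `spec` otherwise). For stage 2: the
#'   stage-1 checkpoint. For stage 3: the stage-2 checkpoint.
#' @param cfg A [train_config()].
#' @param spec A [network_spec()] (stages 1 and 2; stage 3 reuses the
#'   checkpoint's).
#' @return An `ll_checkpoint` recording parameters, stage lineage and the
#'   training-loss history.
#' @export
train_stage <- function(stage, data, network = NULL, cfg, spec = NULL) {
  stopifnot(inherits(cfg, "ll_train_config"))
  if (stage != cfg$stage) stopf("stage argument (%d) disagrees with cfg$stage (%d)", stage, cfg$stage)
  lineage <- character()
  if (stage == 2L) {
    if (is.null(network)) stopf("stage 2 requires a stage-1 checkpoint")
    if (!inherits(network, "ll_checkpoint") || network$stage != 1L)
      stopf("stage 2 requires a stage-1 checkpoint, got %s",
            if (inherits(network, "ll_checkpoint")) paste0("stage-", network$stage) else class(network)[1])
    lineage <- network$lineage
  } else if (stage == 3L) {
    if (is.null(network) || !inherits(network, "ll_checkpoint") || network$stage != 2L)
      stopf("stage 3 requires a stage-2 checkpoint")
    lineage <- network$lineage
  }
  # construction (including fresh-parameter initialization) happens inside the
  # seeded region so runs are bit-reproducible given cfg$seed
  build_net <- function() {
    net <- if (stage == 1L) {
      n <- network %||% build_segmentation_unet(spec %||% network_spec())
      if (inherits(n, "ll_checkpoint")) checkpoint_to_network(n) else n
    } else if (stage == 2L) {
      build_new_lesion_network(spec %||% network$spec, encoder_from = network)
    } else {
      checkpoint_to_network(network)
    }
    if (cfg$freeze_encoder && stage != 1L) net$frozen <- c("enc.", "bott.")
    net
  }
  if (cfg$steps == 0L)
    return(with_seed(cfg$seed, checkpoint(build_net(), stage, cfg,
                                          lineage = lineage)))
  with_seed(cfg$seed, {
    net <- build_net()
    nsamp <- n_samples(data)
    val_ids <- integer(0)
    if (cfg$val_every > 0L && is.finite(nsamp) && nsamp >= 5L)
      val_ids <- sample.int(nsamp, max(1L, round(cfg$val_fraction * nsamp)))
    train_ids <- if (is.finite(nsamp)) setdiff(seq_len(nsamp), val_ids) else NULL
    # fixed validation patches: every checkpoint is scored on the same set
    val_patches <- lapply(val_ids, function(vi) {
      vs <- draw_sample(data, vi)
      if (stage == 1L) {
        vp <- sample_training_patch(vs$volume, vs$mask, cfg$patch_size, 1)
        list(inputs = vp$patches, target = vp$target)
      } else {
        vp <- sample_training_patch(list(vs$tp1, vs$tp2), vs$new_mask,
                                    cfg$patch_size, 1)
        list(inputs = vp$patches, target = vp$target)
      }
    })
    opt <- adam_new(net$params)
    history <- numeric(cfg$steps)
    best <- list(loss = Inf, params = net$params)
    for (step in seq_len(cfg$steps)) {
      i <- if (is.null(train_ids)) step else train_ids[((step - 1L) %% length(train_ids)) + 1L]
      smp <- draw_sample(data, i)
      if (stage == 1L) {
        pt <- sample_training_patch(smp$volume, smp$mask, cfg$patch_size,
                                    cfg$positive_fraction)
        x <- pt$patches[[1]]
        if (!is.null(cfg$augment))
          x <- as_arr(random_augment(x, cfg$augment,
                                     seed = sample.int(.Machine$integer.max, 1L))$volume)
        st <- segmentation_step(net, list(x), pt$target, opt, cfg)
      } else {
        pt <- sample_training_patch(list(smp$tp1, smp$tp2), smp$new_mask,
                                    cfg$patch_size, cfg$positive_fraction)
        xs <- pt$patches
        if (!is.null(cfg$augment))
          xs <- lapply(xs, function(x)
            as_arr(random_augment(x, cfg$augment,
                                  seed = sample.int(.Machine$integer.max, 1L))$volume))
        st <- segmentation_step(net, xs, pt$target, opt, cfg)
      }
      net <- st$net; opt <- st$opt_state; history[step] <- st$loss
      if (length(val_patches) && step %% cfg$val_every == 0L) {
        vl <- mean(vapply(val_patches, function(vp) {
          p <- do.call(network_forward, c(list(net), vp$inputs))
          dice_loss(array(p[, , , 2L], dim = dim(p)[1:3]), vp$target)
        }, numeric(1)))
        if (vl < best$loss) best <- list(loss = vl, params = net$params)
      }
    }
    if (length(val_patches) && is.finite(best$loss)) net$params <- best$params
    checkpoint(net, stage, cfg, lineage = lineage, history = history,
               val_loss = if (length(val_patches)) best$loss else NA_real_)
  })
}

#' Train an ensemble for one stage
#'
#' Trains `cfg$ensemble_size` networks with different seeds and different
#' training/validation splits (both derived from `cfg$seed` + fold index).
#'
#' @inheritParams train_stage
#' @return List of `ll_checkpoint`s.
#' @export
train_ensemble <- function(stage, data, network = NULL, cfg, spec = NULL) {
  lapply(seq_len(cfg$ensemble_size), function(f) {
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + f - 1L
    train_stage(stage, data, network, cfg_f, spec)
  })
}

sliding_starts <- function(n, ps, stride) {
  s <- unique(c(seq(0L, n - ps, by = stride), n - ps))
  s[s >= 0L]
}

#' Ensemble prediction of the new-lesion mask
#'
#' Sliding-window patch inference (stride `patch/2`, uniform overlap
#' averaging) per model; per-voxel class probabilities are averaged across
#' models and the highest-probability class picked; an exact 0.5 tie
#' resolves to background.
#'
#' @param checkpoints List of `ll_checkpoint`s (>= 1) of kind `"newlesion"`.
#' @param tp1,tp2 The two co-registered time-point volumes.
#' @param patch_size Inference patch size.
#' @param stride Window stride (default `patch_size / 2`).
#' @param return_probability Also return the averaged probability map.
#' @return An `ll_mask` of predicted new lesions (plus `probability` as an
#'   attribute when requested).
#' @export
ensemble_predict <- function(checkpoints, tp1, tp2,
                             patch_size = c(64, 64, 64),
                             stride = NULL, return_probability = FALSE) {
  if (inherits(checkpoints, "ll_checkpoint")) checkpoints <- list(checkpoints)
  if (length(checkpoints) < 1L) stopf("need at least one checkpoint")
  kinds <- vapply(checkpoints, `[[`, character(1), "kind")
  if (!all(kinds == kinds[1])) stopf("incompatible checkpoints in ensemble")
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride %||% (patch_size %/% 2L))
  if (!same_grid(tp1, tp2)) stopf("time-point grids do not match")
  d <- dim(tp1$data)
  acc <- array(0, dim = d); cnt <- array(0, dim = d)
  nets <- lapply(checkpoints, checkpoint_to_network)
  starts <- lapply(1:3, function(i) sliding_starts(d[i], patch_size[i], stride[i]))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    spec <- patch_spec(c(sx, sy, sz) + patch_size %/% 2L, patch_size)
    p1 <- extract_patch(tp1, spec)$data
    p2 <- extract_patch(tp2, spec)$data
    psum <- 0
    for (net in nets) {
      out <- network_forward(net, p1, p2)
      psum <- psum + out[, , , 2L]
    }
    xs <- (sx + 1L):(sx + patch_size[1])
    ys <- (sy + 1L):(sy + patch_size[2])
    zs <- (sz + 1L):(sz + patch_size[3])
    acc[xs, ys, zs] <- acc[xs, ys, zs] + psum / length(nets)
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
  }
  prob <- acc / pmax(cnt, 1)
  mask <- lesion_mask(array(as.numeric(prob > 0.5), dim = d), spacing = tp1$spacing)
  if (return_probability) attr(mask, "probability") <- prob
  mask
}

#' Single-time-point lesion segmentation by sliding window
#' @param ckpt A stage-1 `ll_checkpoint` (or list, ensemble-averaged).
#' @param vol Input `ll_volume`.
#' @inheritParams ensemble_predict
#' @return An `ll_mask`.
#' @export
predict_segmentation <- function(ckpt, vol, patch_size = c(64, 64, 64),
                                 stride = NULL) {
  if (inherits(ckpt, "ll_checkpoint")) ckpt <- list(ckpt)
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride %||% (patch_size %/% 2L))
  d <- dim(vol$data)
  acc <- array(0, dim = d); cnt <- array(0, dim = d)
  nets <- lapply(ckpt, checkpoint_to_network)
  starts <- lapply(1:3, function(i) sliding_starts(d[i], patch_size[i], stride[i]))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    spec <- patch_spec(c(sx, sy, sz) + patch_size %/% 2L, patch_size)
    p <- extract_patch(vol, spec)$data
    psum <- 0
    for (net in nets) psum <- psum + network_forward(net, p)[, , , 2L]
    xs <- (sx + 1L):(sx + patch_size[1])
    ys <- (sy + 1L):(sy + patch_size[2])
    zs <- (sz + 1L):(sz + patch_size[3])
    acc[xs, ys, zs] <- acc[xs, ys, zs] + psum / length(nets)
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
  }
  prob <- acc / pmax(cnt, 1)
  lesion_mask(array(as.numeric(prob > 0.5), dim = d), spacing = vol$spacing)
}
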