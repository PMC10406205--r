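test_that("soft dice loss follows its closed form", {
  m <- array(0, dim = c(8, 8, 8)); m[1:4, , ] <- 1    # half-full mask
  expect_lte(dice_loss(m, m), 1e-5)
  expect_gte(dice_loss(1 - m, m), 1 - 1e-4)
  # p = 0.5 everywhere on a half-full mask: 1 - (2*0.5*N/2)/(0.5N + N/2) = 0.5
  p <- array(0.5, dim = dim(m))
  expect_equal(dice_loss(p, m), 0.5, tolerance = 1e-4)
  expect_error(dice_loss(array(0.5, dim = c(4, 4, 4)), m), "mismatch")
})

test_that("dice loss gradient matches finite differences", {
  set.seed(61)
  p <- array(runif(6^3, 0.05, 0.95), dim = c(6, 6, 6))
  t <- array(rbinom(6^3, 1, 0.3), dim = c(6, 6, 6))
  g <- longlesion:::dice_loss_grad(p, t)
  eps <- 1e-7
  for (j in sample(seq_along(p), 5)) {
    p2 <- p; p2[j] <- p2[j] + eps
    p3 <- p; p3[j] <- p3[j] - eps
    expect_equal(g[j], (dice_loss(p2, t) - dice_loss(p3, t)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("patch sampling oversamples the positive class as configured", {
  ph <- get_small_phantom()
  set.seed(62)
  for (i in 1:10) {
    pt <- sample_training_patch(ph$volume, ph$mask, 16, positive_fraction = 1)
    expect_gt(sum(pt$target), 0)
    expect_identical(dim(pt$patches[[1]]), c(16L, 16L, 16L))
  }
  # positive_fraction = 0: centres uniform over the supplied brain support
  brain <- ph$tissue$data > 0
  set.seed(63)
  centers <- t(vapply(1:2000, function(i)
    sample_training_patch(ph$volume, ph$mask, 8, positive_fraction = 0,
                          brain_mask = brain)$center, numeric(3)))
  # chi-squared on halves along each axis (restricted to clamp-free interior)
  d <- dim(brain)
  mid <- d[1] / 2
  interior <- which(brain, arr.ind = TRUE)
  interior <- interior[apply(interior, 1, function(co)
    all(co - 1 >= 4 & co - 1 <= d - 4)), ]
  p_left <- mean(interior[, 1] - 1 < mid)
  obs <- table(factor(centers[, 1] < mid, levels = c(TRUE, FALSE)))
  ct <- suppressWarnings(chisq.test(obs, p = c(p_left, 1 - p_left)))
  expect_gt(ct$p.value, 0.001)
  # seeded reproducibility
  set.seed(64); a <- sample_training_patch(ph$volume, ph$mask, 16, 0.5)
  set.seed(64); b <- sample_training_patch(ph$volume, ph$mask, 16, 0.5)
  expect_identical(a$center, b$center)
  # empty mask with positives requested: uniform fallback with a warning
  empty <- lesion_mask(array(0, dim = dim(ph$mask$data)))
  set.seed(65)
  expect_warning(sample_training_patch(ph$volume, empty, 16, 1), "empty")
})

test_that("training configuration enforces the stage contracts", {
  expect_error(train_config(stage = 4), "stage")
  expect_error(train_config(stage = 2, freeze_encoder = FALSE), "freeze_encoder")
  cfg <- train_config(stage = 1, steps = 10)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$adam_beta1, 0.9)
  expect_equal(cfg$ensemble_size, 5L)
  expect_identical(cfg$patch_size, c(64L, 64L, 64L))
})

test_that("a tiny stage-1 run reduces the training dice loss substantially", {
  ph_train <- lapply(1:3, function(i) {
    p <- make_phantom(easy_phantom_cfg(600 + i, n = 3L))
    list(volume = p$volume, mask = p$mask)
  })
  ck <- train_stage(1, ph_train, NULL,
                    train_config(stage = 1, patch_size = 16, steps = 250,
                                 learning_rate = 1e-3, positive_fraction = 1,
                                 seed = 66), test_net_spec())
  early <- mean(ck$history[1:10])
  late <- mean(tail(ck$history, 10))
  expect_lte(late, 0.5 * early)
})

test_that("stage prerequisites and zero-step checkpoints behave as specified", {
  set.seed(67)
  spec <- test_net_spec()
  seg <- build_segmentation_unet(spec)
  ck1 <- longlesion:::checkpoint(seg, 1L, NULL)
  expect_error(train_stage(2, list(), NULL,
                           train_config(stage = 2, steps = 1)), "stage-1")
  expect_error(train_stage(3, list(), ck1,
                           train_config(stage = 3, steps = 1)), "stage-2")
  ck2 <- train_stage(2, list(), ck1, train_config(stage = 2, steps = 0))
  expect_equal(ck2$stage, 2L)
  ck3 <- train_stage(3, list(), ck2, train_config(stage = 3, steps = 0))
  expect_identical(ck3$params, ck2$params)
  expect_identical(ck3$lineage, c("stage1", "stage2", "stage3"))
})

test_that("checkpoints round-trip through disk", {
  set.seed(68)
  ck <- longlesion:::checkpoint(build_segmentation_unet(test_net_spec()), 1L, NULL)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  expect_identical(ck2$params, ck$params)
  expect_equal(ck2$stage, 1L)
})

test_that("an ensemble of identical checkpoints equals the single model", {
  set.seed(69)
  tr <- make_longitudinal_truth(easy_phantom_cfg(70), n_new = 1L)
  net <- build_new_lesion_network(test_net_spec())
  net$params[["head.w"]][] <- rnorm(length(net$params[["head.w"]]), 0, 0.5)
  ck <- longlesion:::checkpoint(net, 2L, NULL)
  single <- ensemble_predict(list(ck), tr$tp1, tr$tp2, patch_size = 48)
  five <- ensemble_predict(rep(list(ck), 5), tr$tp1, tr$tp2, patch_size = 48)
  expect_identical(five$data, single$data)
  expect_true(all(five$data %in% c(0, 1)))
  expect_identical(dim(five$data), dim(tr$tp1$data))
})

test_that("ensemble probabilities are the mean of member probabilities", {
  set.seed(71)
  tr <- make_longitudinal_truth(easy_phantom_cfg(71, n = 1L), n_new = 1L)
  nets <- lapply(1:2, function(i) {
    n <- build_new_lesion_network(test_net_spec())
    n$params[["head.w"]][] <- rnorm(length(n$params[["head.w"]]), 0, 0.5)
    n
  })
  cks <- lapply(nets, function(n) longlesion:::checkpoint(n, 2L, NULL))
  prob <- attr(ensemble_predict(cks, tr$tp1, tr$tp2, patch_size = 48,
                                return_probability = TRUE), "probability")
  p1 <- network_forward(nets[[1]], tr$tp1$data, tr$tp2$data)[, , , 2]
  p2 <- network_forward(nets[[2]], tr$tp1$data, tr$tp2$data)[, , , 2]
  expect_equal(prob, (p1 + p2) / 2, tolerance = 1e-12)
  # argmax with ties to background: voxels are positive only above 0.5
  mask <- ensemble_predict(cks, tr$tp1, tr$tp2, patch_size = 48)
  expect_identical(mask$data > 0, (p1 + p2) / 2 > 0.5)
})

test_that("training with a frozen encoder never touches encoder parameters", {
  ph <- get_small_phantom()
  pair <- list(tp1 = ph$volume, tp2 = ph$volume, new_mask = ph$mask)
  spec <- test_net_spec()
  seg <- build_segmentation_unet(spec)
  ck1 <- longlesion:::checkpoint(seg, 1L, NULL)
  ck2 <- suppressWarnings(train_stage(2, list(pair), ck1,
                                      train_config(stage = 2, patch_size = 16,
                                                   steps = 5, seed = 72)))
  enc_names <- grep("^(enc|bott)", names(seg$params), value = TRUE)
  for (nm in enc_names) expect_identical(ck2$params[[nm]], seg$params[[nm]])
  # decoder-side parameters did change (head starts at zero)
  expect_false(all(ck2$params[["head.w"]] == 0))
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  ph <- get_small_phantom()
  data <- list(list(volume = ph$volume, mask = ph$mask))
  cfg <- train_config(stage = 1, patch_size = 16, steps = 8,
                      learning_rate = 1e-3, seed = 73)
  a <- train_stage(1, data, NULL, cfg, test_net_spec())
  invisible(rnorm(100))   # perturb the caller's RNG stream
  b <- train_stage(1, data, NULL, cfg, test_net_spec())
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})
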