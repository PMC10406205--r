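test_that("split_lesions partitions masks into 26-connected components", {
  empty <- lesion_mask(array(0, dim = c(10, 10, 10)))
  expect_length(split_lesions(empty), 0)

  two <- array(0, dim = c(12, 12, 12))
  two[2:4, 2:4, 2:4] <- 1
  two[8:10, 8:10, 8:10] <- 1
  comps <- split_lesions(lesion_mask(two))
  expect_length(comps, 2)
  expect_equal(vapply(comps, function(co) length(co$idx), numeric(1)), c(27, 27))
  expect_equal(comps[[1]]$volume_mm3, 27)

  diag <- array(0, dim = c(6, 6, 6))
  diag[2, 2, 2] <- 1; diag[3, 3, 3] <- 1    # touch only at a corner
  comps <- split_lesions(lesion_mask(diag))
  expect_length(comps, 1)
  expect_equal(max(oracle_label_components(diag)), 1)
})

test_that("component labelling matches the flood-fill oracle on random masks", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_mask_array(c(12, 12, 12), p = 0.2)
    comps <- split_lesions(lesion_mask(m))
    lab <- oracle_label_components(m)
    expect_length(comps, max(lab))
    for (co in comps) expect_true(all(lab[co$idx] == lab[co$idx][1]))
  }
})

test_that("fates are drawn i.i.d. from the configured probabilities", {
  comps <- split_lesions(lesion_mask({
    a <- array(0, dim = c(8, 8, 8)); a[2, 2, 2] <- 1; a[6, 6, 6] <- 1; a
  }))
  all_keep <- synthesis_config(fate_probabilities = c(keep_both = 1,
    remove_tp1 = 0, remove_tp2 = 0, remove_both = 0))
  set.seed(1)
  expect_true(all(vapply(assign_fates(comps, all_keep), `[[`, character(1),
                         "fate") == "keep_both"))
  # multinomial bound: 10,000 draws at equal probabilities
  eq <- synthesis_config(fate_probabilities = c(keep_both = 0.25,
    remove_tp1 = 0.25, remove_tp2 = 0.25, remove_both = 0.25))
  many <- rep(comps[1], 10000)
  set.seed(2)
  draw <- table(vapply(assign_fates(many, eq), `[[`, character(1), "fate"))
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(draw - 2500) <= 3 * sigma))
  set.seed(3); f1 <- assign_fates(comps, synthesis_config())
  set.seed(3); f2 <- assign_fates(comps, synthesis_config())
  expect_identical(vapply(f1, `[[`, character(1), "fate"),
                   vapply(f2, `[[`, character(1), "fate"))
})

test_that("inpainting is local and blends into surrounding tissue", {
  ph <- get_small_phantom()
  comps <- split_lesions(ph$mask)
  expect_identical(inpaint_components(ph$volume, list())$data, ph$volume$data)
  set.seed(4)
  inp <- inpaint_components(ph$volume, comps)
  shape <- dim(ph$volume$data)
  touched <- longlesion:::dilate_indices(which(ph$mask$data > 0), shape, 1L)
  far <- setdiff(seq_along(ph$volume$data),
                 longlesion:::dilate_indices(which(ph$mask$data > 0), shape, 3L))
  expect_identical(inp$data[far], ph$volume$data[far])
  cfg <- small_phantom_cfg()
  wm_mean <- mean(ph$volume$data[ph$tissue$data == 3 & ph$mask$data == 0])
  for (co in comps)
    expect_lt(abs(mean(inp$data[co$idx]) - wm_mean), 2 * cfg$noise_sd)
})

test_that("inpainting-model training pairs have the documented structure", {
  ph <- make_phantom(small_phantom_cfg(seed = 31, n = 0L))
  set.seed(5)
  zero <- corrupt_for_inpainting(ph$volume, n_regions = 0)
  expect_identical(zero$corrupted$data, ph$volume$data)
  smp <- corrupt_for_inpainting(ph$volume, n_regions = 3,
                                within = ph$tissue$data == 3)
  idx <- which(smp$region$data > 0)
  expect_gt(length(idx), 0)
  mu <- mean(ph$volume$data)
  expect_lt(abs(mean(smp$corrupted$data[idx]) - mu),
            3 * sd(ph$volume$data) / sqrt(length(idx)))
  expect_identical(smp$target$data, ph$volume$data)
  # untouched voxels identical; regions are connected blobs of plausible size
  out <- which(smp$region$data == 0)
  expect_identical(smp$corrupted$data[out], ph$volume$data[out])
  comps <- split_lesions(smp$region)
  expect_true(all(vapply(comps, function(co) length(co$idx), numeric(1)) >= 2))
})

test_that("generator training samples pair a noised channel with its mask", {
  ph <- get_small_phantom()
  set.seed(6)
  smp <- prepare_generator_sample(ph$volume, ph$mask)
  expect_identical(dim(smp$input), c(dim(ph$volume$data), 2L))
  expect_identical(smp$input[, , , 2], ph$mask$data)
  idx <- which(ph$mask$data > 0)
  out <- which(ph$mask$data == 0)
  ch1 <- smp$input[, , , 1]
  expect_identical(ch1[out], ph$volume$data[out])
  expect_lt(abs(cor(ch1[idx], smp$target[idx])), 0.3)
  expect_error(prepare_generator_sample(ph$volume,
    lesion_mask(array(0, dim = dim(ph$volume$data)))), "non-empty")
})

test_that("generation sites follow the atlas restricted to plausible tissue", {
  ph <- get_small_phantom()
  expect_identical(nrow(sample_generation_sites(ph$tissue, ph$atlas, 0L)), 0L)
  # single-voxel atlas: every site is that voxel
  one <- array(0, dim = dim(ph$atlas$data))
  wm_idx <- which(ph$tissue$data == 3)[100]
  one[wm_idx] <- 1
  set.seed(7)
  s <- sample_generation_sites(ph$tissue, lesion_atlas(one, ph$atlas$spacing), 1L)
  expect_equal(coords_to_index_test(s, dim(one)), wm_idx)
  # uniform atlas over WM: empirical distribution uniform over octants
  unif <- array(0, dim = dim(ph$atlas$data))
  unif[ph$tissue$data == 3] <- 1 / sum(ph$tissue$data == 3)
  atl <- lesion_atlas(unif, ph$atlas$spacing)
  set.seed(8)
  sites <- do.call(rbind, lapply(1:2000, function(i)
    sample_generation_sites(ph$tissue, atl, 1L)))
  mid <- dim(unif) / 2
  octant <- 1 + (sites[, 1] > mid[1]) + 2 * (sites[, 2] > mid[2]) +
    4 * (sites[, 3] > mid[3])
  wm_co <- arrayInd(which(ph$tissue$data == 3), dim(unif))
  wm_oct <- 1 + (wm_co[, 1] > mid[1]) + 2 * (wm_co[, 2] > mid[2]) +
    4 * (wm_co[, 3] > mid[3])
  expected_p <- as.vector(table(factor(wm_oct, levels = 1:8))) / nrow(wm_co)
  ct <- suppressWarnings(chisq.test(table(factor(octant, levels = 1:8)),
                                    p = expected_p))
  expect_gt(ct$p.value, 0.01)
  expect_true(all(ph$tissue$data[coords_to_index_test(sites, dim(unif))] %in% c(2, 3)))
})

test_that("degenerate synthesis settings reproduce their contracts", {
  ph <- get_small_phantom()
  # all keep, no generation: no new lesions, copies identical pre-augmentation
  cfg0 <- synthesis_config(fate_probabilities = c(keep_both = 1, remove_tp1 = 0,
                                                  remove_tp2 = 0, remove_both = 0),
                           n_generated_range = c(0L, 0L))
  smp <- synthesize_pair(ph$volume, ph$mask, ph$tissue, ph$atlas, cfg0,
                         aug_cfg = augment_config(), seed = 41)
  expect_equal(sum(smp$new_mask$data), 0)
  expect_identical(smp$tp1_pre$data, smp$tp2_pre$data)
  # all remove_tp1, no generation: new mask equals the full lesion support
  cfg1 <- synthesis_config(fate_probabilities = c(keep_both = 0, remove_tp1 = 1,
                                                  remove_tp2 = 0, remove_both = 0),
                           n_generated_range = c(0L, 0L))
  smp1 <- synthesize_pair(ph$volume, ph$mask, ph$tissue, ph$atlas, cfg1,
                          aug_cfg = NULL, seed = 42)
  expect_equal(sum(smp1$new_mask$data), sum(ph$mask$data))
  expect_equal(sum(smp1$tp1_lesion_mask$data), 0)
  # tp1 is lesion-free at the inpainted sites: intensities near WM level
  cfg_ph <- small_phantom_cfg()
  idx <- which(smp1$new_mask$data > 0)
  expect_lt(mean(smp1$tp1_pre$data[idx]),
            cfg_ph$wm_intensity + cfg_ph$lesion_contrast / 2)
  # and tp2 keeps them hyperintense
  expect_gt(mean(smp1$tp2_pre$data[idx]),
            cfg_ph$wm_intensity + cfg_ph$lesion_contrast / 3)
})

test_that("synthesis bookkeeping is exact across seeds", {
  ph <- get_small_phantom()
  for (seed in 1:10) {
    smp <- suppressWarnings(
      synthesize_pair(ph$volume, ph$mask, ph$tissue, ph$atlas,
                      synthesis_config(), aug_cfg = augment_config(),
                      seed = seed))
    expect_identical(reconstruct_new_mask(smp)$data, smp$new_mask$data)
    expect_equal(sum(smp$new_mask$data * smp$tp1_lesion_mask$data), 0)
    # locality: untouched voxels identical across pre-augmentation copies
    # (component indices live in the geometrically augmented space)
    shape <- dim(ph$volume$data)
    comp_idx <- unlist(lapply(smp$fates, function(f) f$component$idx))
    touched <- unique(c(
      if (length(comp_idx)) longlesion:::dilate_indices(comp_idx, shape, 3L),
      unlist(lapply(smp$generated_sites, function(g)
        longlesion:::dilate_indices(g$support, shape, 6L)))))
    far <- setdiff(seq_along(ph$volume$data), touched)
    expect_identical(smp$tp1_pre$data[far], smp$tp2_pre$data[far])
    # determinism
    smp2 <- suppressWarnings(
      synthesize_pair(ph$volume, ph$mask, ph$tissue, ph$atlas,
                      synthesis_config(), aug_cfg = augment_config(),
                      seed = seed))
    expect_identical(smp$tp1$data, smp2$tp1$data)
    expect_identical(smp$tp2$data, smp2$tp2$data)
  }
})
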