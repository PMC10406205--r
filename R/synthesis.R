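# Two-time-point synthesis from single time-point scans: connected-component
# lesion bookkeeping, per-lesion fates (inpaint from one/both time-points or
# keep), lesion generation at atlas-guided sites, and the full pair
# synthesizer with an exact new-lesion bookkeeping log.

#' Split a lesion mask into connected components
#'
#' 26-connectivity; components are labelled deterministically in ascending
#' order of their first voxel (column-major linear index).
#'
#' @param mask An `ll_mask`.
#' @return List of `ll_lesion_component`: `label`, `voxels` (n x 3 matrix of
#'   1-based voxel coordinates), `idx` (linear indices), `volume_mm3`.
#' @export
split_lesions <- function(mask) {
  d <- dim(mask$data)
  lab <- cc_label_26_cpp(as.integer(mask$data > 0), d[1], d[2], d[3])
  n <- max(lab)
  if (n == 0L) return(list())
  vv <- prod(mask$spacing)
  lapply(seq_len(n), function(i) {
    idx <- which(lab == i)
    structure(list(label = i, voxels = arrayInd(idx, d), idx = idx,
                   volume_mm3 = length(idx) * vv),
              class = "ll_lesion_component")
  })
}

#' Synthesis configuration
#'
#' @param fate_probabilities Probabilities of the four per-lesion fates
#'   `keep_both`, `remove_tp1`, `remove_tp2`, `remove_both` (must sum to 1).
#'   A lesion removed from time-point 1 but kept in time-point 2 is a *new*
#'   lesion; one removed from time-point 2 only is a disappearing lesion and
#'   is never labelled.
#' @param n_generated_range Inclusive count interval of generated lesions
#'   per sample (drawn uniformly).
#' @param generated_placement_probabilities Weights for placing a generated
#'   lesion in `tp2_only` (a new lesion), `both`, or `tp1_only`
#'   (disappearing); must sum to 1.
#' @param atlas_threshold Minimum atlas probability for a generation site.
#' @param generated_radius_range Generated-lesion semi-axis range, mm.
#' @param generated_contrast Peak added intensity of generated lesions
#'   (classical generator model).
#' @return A list of class `ll_synthesis_config`.
#' @export
synthesis_config <- function(fate_probabilities = c(keep_both = 0.4,
                                                    remove_tp1 = 0.3,
                                                    remove_tp2 = 0.15,
                                                    remove_both = 0.15),
                             n_generated_range = c(0L, 3L),
                             generated_placement_probabilities = c(tp2_only = 0.6,
                                                                   both = 0.3,
                                                                   tp1_only = 0.1),
                             atlas_threshold = 0,
                             generated_radius_range = c(2, 5),
                             generated_contrast = 0.3) {
  if (abs(sum(fate_probabilities) - 1) > 1e-9)
    stopf("fate_probabilities must sum to 1")
  if (abs(sum(generated_placement_probabilities) - 1) > 1e-9)
    stopf("generated_placement_probabilities must sum to 1")
  structure(list(fate_probabilities = fate_probabilities,
                 n_generated_range = as.integer(n_generated_range),
                 generated_placement_probabilities = generated_placement_probabilities,
                 atlas_threshold = atlas_threshold,
                 generated_radius_range = as.numeric(generated_radius_range),
                 generated_contrast = generated_contrast),
            class = "ll_synthesis_config")
}

FATES <- c("keep_both", "remove_tp1", "remove_tp2", "remove_both")

#' Assign a fate to each lesion component
#'
#' Fates are drawn i.i.d. from `cfg$fate_probabilities`.
#'
#' @param components Output of [split_lesions()].
#' @param cfg A [synthesis_config()].
#' @return List of `list(component, fate)`.
#' @export
assign_fates <- function(components, cfg) {
  if (length(components) == 0L) return(list())
  fates <- sample(FATES, length(components), replace = TRUE,
                  prob = cfg$fate_probabilities)
  Map(function(comp, fate) list(component = comp, fate = fate),
      components, fates)
}

## ---- inpainting ------------------------------------------------------

# Distance-weighted shell-mean fill with matched noise: the classical
# inpainting model. For each region voxel the fill value is a 1/d-weighted
# mean of the surrounding healthy shell, plus Gaussian noise with the
# shell's residual SD.
classical_inpaint <- function(data, region_idx, shape) {
  shell <- setdiff(dilate_indices(region_idx, shape, 3L),
                   dilate_indices(region_idx, shape, 1L))
  if (length(shell) == 0L) return(data)
  shell_vals <- data[shell]
  shell_sd <- sd(shell_vals)
  rc <- arrayInd(region_idx, shape)
  sc <- arrayInd(shell, shape)
  for (i in seq_along(region_idx)) {
    d2 <- (sc[, 1] - rc[i, 1])^2 + (sc[, 2] - rc[i, 2])^2 + (sc[, 3] - rc[i, 3])^2
    w <- 1 / (sqrt(d2) + 1)
    data[region_idx[i]] <- sum(w * shell_vals) / sum(w) + rnorm(1, 0, shell_sd)
  }
  data
}

#' Inpaint lesion components with healthy-looking tissue
#'
#' Each component region (dilated by 1 voxel to remove partial-volume rims)
#' is replaced by the inpainting model's output; all other voxels are
#' unchanged bitwise.
#'
#' @param vol An `ll_volume`.
#' @param components List of lesion components (from [split_lesions()]).
#' @param inpainter `NULL` for the classical distance-weighted shell-mean
#'   model, or a trained regression network (`ll_network` /
#'   `ll_checkpoint`) that reconstructs noise-filled regions.
#' @return The inpainted `ll_volume`.
#' @export
inpaint_components <- function(vol, components, inpainter = NULL) {
  if (length(components) == 0L) return(vol)
  shape <- dim(vol$data)
  data <- vol$data
  for (comp in components) {
    if (any(comp$voxels < 1) || any(sweep(comp$voxels, 2, shape, `>`)))
      stopf("component %d lies outside the volume grid", comp$label)
    region <- dilate_indices(comp$idx, shape, 1L)
    if (is.null(inpainter)) {
      data <- classical_inpaint(data, region, shape)
    } else {
      data <- network_inpaint(data, region, shape, inpainter)
    }
  }
  out <- vol; out$data <- data
  out
}

# Neural inpainting: noise-fill the region, run the 1->1 U-Net on a patch
# around it, write back region voxels only.
network_inpaint <- function(data, region_idx, shape, inpainter) {
  if (inherits(inpainter, "ll_checkpoint")) inpainter <- checkpoint_to_network(inpainter)
  mu <- mean(data); s <- sd(data)
  data_noised <- data
  data_noised[region_idx] <- rnorm(length(region_idx), mu, s)
  rc <- arrayInd(region_idx, shape)
  center <- floor(colMeans(rc)) - 1L
  ps <- 2L^inpainter$spec$levels * 2L
  ps <- max(ps, 16L)
  spec <- patch_spec(clamp_center(center, shape, rep(ps, 3L)), ps)
  pv <- extract_patch(volume(data_noised), spec)
  rec <- network_forward(inpainter, pv$data)
  patched <- insert_patch(volume(data_noised), volume(array(rec, dim = rep(ps, 3L))), spec)
  data[region_idx] <- patched$data[region_idx]
  data
}

#' Build a training pair for the inpainting model
#'
#' Corrupts a lesion-free volume with Gaussian noise (image global mean and
#' SD) in lesion-like regions at random locations; the uncorrupted input is
#' the regression target.
#'
#' @param vol Lesion-free `ll_volume`.
#' @param n_regions Number of corrupted regions.
#' @param radius_range Region semi-axis range, mm.
#' @param within Optional logical array restricting region centres (e.g. WM).
#' @return List with `corrupted` (`ll_volume`), `target` (`ll_volume`),
#'   `region` (`ll_mask` of filled voxels).
#' @export
corrupt_for_inpainting <- function(vol, n_regions = 2L, radius_range = c(2, 5),
                                   within = NULL) {
  shape <- dim(vol$data)
  region <- array(0, dim = shape)
  data <- vol$data
  mu <- mean(data); s <- sd(data)
  cand <- if (is.null(within)) seq_along(data) else which(within)
  for (i in seq_len(n_regions)) {
    center <- arrayInd(cand[sample.int(length(cand), 1L)], shape)[1, ]
    radii <- runif(3, radius_range[1], radius_range[2])
    blob <- lesion_blob(center, radii, random_rotation(), shape, vol$spacing)
    idx <- coords_to_index(blob$coords[blob$support, , drop = FALSE], shape)
    region[idx] <- 1
  }
  idx <- which(region > 0)
  data[idx] <- rnorm(length(idx), mu, s)
  list(corrupted = volume(data, vol$spacing, vol$space),
       target = vol,
       region = lesion_mask(region, vol$spacing))
}

#' Build a training sample for the lesion generator model
#'
#' Channel 1 is the volume with lesion regions replaced by random noise,
#' channel 2 the lesion mask; the target is the original volume (the model
#' learns to hallucinate lesions into the masked regions).
#'
#' @param vol `ll_volume` containing lesions.
#' @param mask Non-empty lesion `ll_mask`.
#' @return List with `input` (4D array, 2 channels) and `target` (3D array).
#' @export
prepare_generator_sample <- function(vol, mask) {
  idx <- which(mask$data > 0)
  if (length(idx) == 0L) stopf("generator sample requires a non-empty mask")
  mu <- mean(vol$data); s <- sd(vol$data)
  ch1 <- vol$data
  ch1[idx] <- rnorm(length(idx), mu, s)
  input <- array(c(ch1, mask$data), dim = c(dim(vol$data), 2L))
  list(input = input, target = vol$data)
}

#' Sample lesion-generation sites from the atlas
#'
#' Sites are drawn proportional to the atlas probability restricted to
#' WM or GM with atlas value >= `atlas_threshold`, with pairwise Chebyshev
#' separation of at least 2 voxels.
#'
#' @param tissue An `ll_tissue`.
#' @param atlas An `ll_atlas` on the same grid.
#' @param n Number of sites.
#' @param atlas_threshold Minimum atlas probability.
#' @return n x 3 matrix of 1-based voxel coordinates.
#' @export
sample_generation_sites <- function(tissue, atlas, n, atlas_threshold = 0) {
  if (!identical(dim(tissue$data), dim(atlas$data)))
    stopf("tissue and atlas grids differ")
  shape <- dim(atlas$data)
  p <- as.vector(atlas$data)
  feas <- (tissue$data %in% c(2L, 3L)) & (atlas$data >= atlas_threshold) & (p > 0)
  p[!feas] <- 0
  if (n == 0L) return(matrix(integer(0), 0, 3))
  if (!any(p > 0)) stopf("no feasible generation sites (atlas/tissue support empty)")
  sites <- matrix(0L, n, 3)
  taken <- integer(0)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      idx <- sample.int(length(p), 1L, prob = p)
      co <- arrayInd(idx, shape)[1, ]
      if (length(taken) == 0L ||
          all(apply(abs(sweep(matrix(sites[seq_along(taken), ], ncol = 3), 2, co)),
                    1, max) >= 2)) {
        sites[i, ] <- co
        taken <- c(taken, idx)
        break
      }
      if (try == 100) stopf("could not find separated generation sites")
    }
  }
  sites
}

# Classical lesion generator: adds the blob's Gaussian taper, scaled by the
# configured contrast (deterministic given the blob).
classical_generate <- function(data, blob, shape, cfg) {
  idx <- coords_to_index(blob$coords, shape)
  data[idx] <- data[idx] + cfg$generated_contrast * blob$taper
  data
}

# Neural generation: stamp the blob mask, noise-fill it, run the 2->1 U-Net.
network_generate <- function(data, blob, support, shape, gen_seed, generator) {
  if (inherits(generator, "ll_checkpoint")) generator <- checkpoint_to_network(generator)
  with_seed(gen_seed, {
    mask <- array(0, dim = shape); mask[support] <- 1
    mu <- mean(data); s <- sd(data)
    noised <- data; noised[support] <- rnorm(length(support), mu, s)
    ps <- max(2L^generator$spec$levels * 2L, 16L)
    site <- round(colMeans(arrayInd(support, shape)))
    spec <- patch_spec(clamp_center(site - 1L, shape, rep(ps, 3L)), ps)
    p1 <- extract_patch(volume(noised), spec)$data
    p2 <- extract_patch(lesion_mask(mask), spec)$data
    out <- network_forward(generator, array(c(p1, p2), dim = c(rep(ps, 3L), 2L)))
    patched <- insert_patch(volume(noised), volume(array(out, dim = rep(ps, 3L))), spec)
    data[support] <- patched$data[support]
    data
  })
}

#' Synthesize a longitudinal pair with new lesions from one time-point
#'
#' Three steps: (1) the scan and its lesion mask are geometrically augmented
#' (random flips and orthogonal rotations) and duplicated into two
#' time-point copies; (2) each lesion component is inpainted from one or
#' both copies, or kept, per its sampled fate — components removed from
#' time-point 1 but kept in time-point 2 become new lesions; (3) synthetic
#' lesions are generated at atlas-guided sites in one or both copies — only
#' those generated in time-point 2 alone join the new-lesion mask. Finally
#' the two copies receive independent acquisition-artifact augmentation.
#'
#' @param flair Single time-point `ll_volume`.
#' @param mask Its lesion `ll_mask`.
#' @param tissue `ll_tissue` on the same grid.
#' @param atlas `ll_atlas` on the same grid.
#' @param cfg A [synthesis_config()].
#' @param aug_cfg `NULL`, or an [augment_config()] for the final independent
#'   quality augmentation of the two copies.
#' @param models Optional list with `inpainter` and/or `generator` networks;
#'   `NULL` components use the classical models.
#' @param seed Integer seed; the sample is fully determined by it.
#' @return A list of class `ll_longitudinal_sample`: `tp1`, `tp2`
#'   (augmented volumes), `tp1_pre`, `tp2_pre` (pre-augmentation copies),
#'   `new_mask`, `fates`, `generated_sites` (data frame with placement and
#'   support bookkeeping), `tp1_lesion_mask` (lesion support remaining in
#'   time-point 1), `seed`.
#' @export
synthesize_pair <- function(flair, mask, tissue, atlas, cfg = synthesis_config(),
                            aug_cfg = NULL, models = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "ll_synthesis_config"))
  if (!same_grid(flair, mask)) stopf("flair and mask grids differ")
  with_seed(seed, {
    shape <- dim(flair$data)
    ## step 1: geometric augmentation, duplication
    geo <- random_flip_rotation(list(flair$data, mask$data, tissue$data, atlas$data))
    base <- volume(geo[[1]], flair$spacing, flair$space)
    gmask <- lesion_mask(geo[[2]], mask$spacing)
    gtissue <- structure(list(data = geo[[3]], spacing = tissue$spacing), class = "ll_tissue")
    gatlas <- structure(list(data = geo[[4]], spacing = atlas$spacing), class = "ll_atlas")
    tp1 <- base; tp2 <- base
    ## step 2: component fates and inpainting
    comps <- split_lesions(gmask)
    fates <- assign_fates(comps, cfg)
    inpainter <- models$inpainter
    rm1 <- Filter(function(f) f$fate %in% c("remove_tp1", "remove_both"), fates)
    rm2 <- Filter(function(f) f$fate %in% c("remove_tp2", "remove_both"), fates)
    tp1 <- inpaint_components(tp1, lapply(rm1, `[[`, "component"), inpainter)
    tp2 <- inpaint_components(tp2, lapply(rm2, `[[`, "component"), inpainter)
    new_idx <- unlist(lapply(Filter(function(f) f$fate == "remove_tp1", fates),
                             function(f) f$component$idx))
    tp1_lesion_idx <- unlist(lapply(Filter(function(f) f$fate %in% c("keep_both", "remove_tp2"),
                                           fates),
                                    function(f) f$component$idx))
    ## step 3: generated lesions
    n_gen <- if (cfg$n_generated_range[2] > cfg$n_generated_range[1])
      sample(cfg$n_generated_range[1]:cfg$n_generated_range[2], 1L)
    else cfg$n_generated_range[1]
    gen_records <- list()
    if (n_gen > 0L) {
      # generated lesions must not touch existing lesion components or each
      # other (rejection sampling keeps the bookkeeping exact)
      all_comp_idx <- unlist(lapply(comps, function(co) co$idx))
      occupied <- array(FALSE, dim = shape)
      if (length(all_comp_idx))
        occupied[dilate_indices(all_comp_idx, shape, 1L)] <- TRUE
      placements <- sample(names(cfg$generated_placement_probabilities), n_gen,
                           replace = TRUE, prob = cfg$generated_placement_probabilities)
      for (i in seq_len(n_gen)) {
        blob <- NULL
        for (try in 1:30) {
          site <- sample_generation_sites(gtissue, gatlas, 1L, cfg$atlas_threshold)[1, ]
          radii <- runif(3, cfg$generated_radius_range[1], cfg$generated_radius_range[2])
          cand <- lesion_blob(site, radii, random_rotation(), shape, flair$spacing)
          sup <- coords_to_index(cand$coords[cand$support, , drop = FALSE], shape)
          if (length(sup) >= 2L && !any(occupied[sup])) {
            blob <- cand; support <- sup
            break
          }
        }
        if (is.null(blob)) next   # no room left; drop this generated lesion
        gen_seed <- sample.int(.Machine$integer.max, 1L)
        gen1 <- function(data) {
          if (is.null(models$generator)) classical_generate(data, blob, shape, cfg)
          else network_generate(data, blob, support, shape, gen_seed, models$generator)
        }
        if (placements[i] %in% c("tp1_only", "both")) tp1$data <- gen1(tp1$data)
        if (placements[i] %in% c("tp2_only", "both")) tp2$data <- gen1(tp2$data)
        occupied[dilate_indices(support, shape, 1L)] <- TRUE
        gen_records[[length(gen_records) + 1L]] <-
          list(site = site, placement = placements[i], support = support)
        if (placements[i] == "tp2_only") new_idx <- c(new_idx, support)
        if (placements[i] %in% c("tp1_only", "both"))
          tp1_lesion_idx <- c(tp1_lesion_idx, support)
      }
    }
    new_mask_arr <- array(0, dim = shape); new_mask_arr[new_idx] <- 1
    tp1_les_arr <- array(0, dim = shape); tp1_les_arr[tp1_lesion_idx] <- 1
    ## final: independent quality augmentation of the two finished copies
    tp1_pre <- tp1; tp2_pre <- tp2
    logs <- list(NULL, NULL)
    if (!is.null(aug_cfg)) {
      s1 <- sample.int(.Machine$integer.max, 1L)
      s2 <- sample.int(.Machine$integer.max, 1L)
      a1 <- random_augment(tp1, aug_cfg, s1); tp1 <- a1$volume; logs[[1]] <- a1$log
      a2 <- random_augment(tp2, aug_cfg, s2); tp2 <- a2$volume; logs[[2]] <- a2$log
    }
    structure(list(tp1 = tp1, tp2 = tp2, tp1_pre = tp1_pre, tp2_pre = tp2_pre,
                   new_mask = lesion_mask(new_mask_arr, flair$spacing),
                   tp1_lesion_mask = lesion_mask(tp1_les_arr, flair$spacing),
                   fates = fates, generated_sites = gen_records,
                   augment_logs = logs, seed = seed),
              class = "ll_longitudinal_sample")
  })
}

#' Reconstruct the new-lesion mask from a sample's fate log
#'
#' Bookkeeping check: the new-lesion mask must equal the union of components
#' with fate `remove_tp1` and the supports of lesions generated in
#' time-point 2 only.
#'
#' @param sample An `ll_longitudinal_sample`.
#' @return An `ll_mask`.
#' @export
reconstruct_new_mask <- function(sample) {
  shape <- dim(sample$new_mask$data)
  idx <- unlist(lapply(Filter(function(f) f$fate == "remove_tp1", sample$fates),
                       function(f) f$component$idx))
  idx <- c(idx, unlist(lapply(Filter(function(g) g$placement == "tp2_only",
                                     sample$generated_sites),
                              function(g) g$support)))
  arr <- array(0, dim = shape)
  if (length(idx)) arr[idx] <- 1
  lesion_mask(arr, sample$new_mask$spacing)
}
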