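#' Phantom generator configuration
#'
#' Describes a brain-like FLAIR phantom: nested ellipsoidal tissue
#' compartments (background / CSF / GM / WM), smoothed ellipsoidal
#' hyperintense lesions placed fully inside white matter, additive Gaussian
#' noise, and a lesion-probability atlas concentrated in deep white matter.
#'
#' Intensities follow FLAIR contrast on a normalized scale: CSF suppressed
#' (dark), grey matter brighter than white matter, lesions hyperintense
#' relative to both.
#'
#' @param shape Grid shape in voxels (length 1 or 3). Default 96^3 holds a
#'   64^3 training patch comfortably while remaining CPU-friendly.
#' @param n_lesions Number of lesions to place.
#' @param lesion_radius_range Min/max lesion semi-axis length in mm.
#' @param wm_intensity,gm_intensity,csf_intensity Mean tissue intensities.
#' @param lesion_contrast Peak intensity added at a lesion centre; must be
#'   positive (lesions are hyperintense on FLAIR).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param spacing Voxel size in mm.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @return A list of class `ll_phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 96), n_lesions = 8,
                           lesion_radius_range = c(2, 5),
                           wm_intensity = 0.35, gm_intensity = 0.5,
                           csf_intensity = 0.1, lesion_contrast = 0.3,
                           noise_sd = 0.03, spacing = c(1, 1, 1), seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (any(shape < 16L)) stopf("shape must be at least 16 voxels per axis")
  if (!is_count(n_lesions)) stopf("n_lesions must be a non-negative count")
  if (lesion_contrast <= 0) stopf("lesion_contrast must be > 0 (FLAIR lesions are hyperintense)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  r <- sort(as.numeric(lesion_radius_range))
  if (r[1] < min(spacing)) stopf("lesion radii must be at least 1 voxel")
  structure(list(shape = shape, n_lesions = as.integer(n_lesions),
                 lesion_radius_range = r, wm_intensity = wm_intensity,
                 gm_intensity = gm_intensity, csf_intensity = csf_intensity,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "ll_phantom_config")
}

#' Tissue label map
#' @param data 3D array with labels 0 (background), 1 (CSF), 2 (GM), 3 (WM).
#' @param spacing Voxel size in mm.
#' @return Object of class `ll_tissue`.
#' @export
tissue_map <- function(data, spacing = c(1, 1, 1)) {
  if (!all(data %in% 0:3)) stopf("tissue labels must be in {0,1,2,3}")
  if (!any(data == 3)) stopf("WM region must be non-empty")
  structure(list(data = data, spacing = as.numeric(spacing)), class = "ll_tissue")
}

#' Lesion-probability atlas
#' @param data 3D array of probabilities summing to 1.
#' @param spacing Voxel size in mm.
#' @return Object of class `ll_atlas`.
#' @export
lesion_atlas <- function(data, spacing = c(1, 1, 1)) {
  if (any(data < 0) || any(data > 1)) stopf("atlas values must lie in [0,1]")
  structure(list(data = data, spacing = as.numeric(spacing)), class = "ll_atlas")
}

# normalized squared ellipsoid radius field over the full grid
ellipsoid_rho2 <- function(shape, center, radii) {
  x <- (seq_len(shape[1]) - 1 - center[1]) / radii[1]
  y <- (seq_len(shape[2]) - 1 - center[2]) / radii[2]
  z <- (seq_len(shape[3]) - 1 - center[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

make_tissue_geometry <- function(shape, spacing) {
  center <- (shape - 1) / 2
  half <- (shape - 1) / 2 * spacing         # physical half-extent in mm
  csf_r <- 0.92 * half
  gm_r <- 0.80 * half
  wm_r <- 0.62 * half
  lab <- array(0L, dim = shape)
  rho_csf <- ellipsoid_rho2(shape, center, csf_r / spacing)
  rho_gm <- ellipsoid_rho2(shape, center, gm_r / spacing)
  rho_wm <- ellipsoid_rho2(shape, center, wm_r / spacing)
  lab[rho_csf <= 1] <- 1L
  lab[rho_gm <= 1] <- 2L
  lab[rho_wm <= 1] <- 3L
  list(labels = lab, center = center, wm_radii_vox = wm_r / spacing)
}

make_atlas_field <- function(geom, shape) {
  rho_wm <- sqrt(ellipsoid_rho2(shape, geom$center, geom$wm_radii_vox))
  w <- pmax(1 - rho_wm, 0)          # peaks at the WM core, 0 at the WM edge
  w[geom$labels != 3L] <- 0
  w / sum(w)
}

# Draw a voxel center index (1-based triple) from a probability field.
sample_field_center <- function(field, shape) {
  idx <- sample.int(length(field), 1L, prob = as.vector(field))
  arrayInd(idx, shape)[1, ]
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Gaussian-tapered ellipsoidal blob. Returns taper values and voxel coords for
# the region rho <= 2; support (the mask) is rho <= 1 i.e. taper >= 0.5.
lesion_blob <- function(center, radii_mm, rot, shape, spacing) {
  radii_vox <- radii_mm / spacing
  ext <- ceiling(2 * max(radii_vox)) + 1L
  lo <- pmax(center - ext, 1L); hi <- pmin(center + ext, shape)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  d <- rbind((g$x - center[1]) * spacing[1],
             (g$y - center[2]) * spacing[2],
             (g$z - center[3]) * spacing[3])
  local <- rot %*% d
  rho2 <- colSums((local / radii_mm)^2)
  keep <- rho2 <= 4
  list(coords = as.matrix(g[keep, , drop = FALSE]),
       taper = exp(-log(2) * rho2[keep]),
       support = rho2[keep] <= 1)
}

coords_to_index <- function(coords, shape) {
  (coords[, 1]) + shape[1] * ((coords[, 2] - 1) + shape[2] * (coords[, 3] - 1))
}

# Chebyshev-dilate a set of linear voxel indices by `by` voxels.
dilate_indices <- function(idx, shape, by = 1L) {
  if (length(idx) == 0L) return(integer(0))
  coords <- arrayInd(idx, shape)
  offs <- as.matrix(expand.grid(dx = -by:by, dy = -by:by, dz = -by:by))
  out <- integer(0)
  for (i in seq_len(nrow(offs))) {
    shifted <- sweep(coords, 2, offs[i, ], `+`)
    ok <- shifted[, 1] >= 1 & shifted[, 1] <= shape[1] &
          shifted[, 2] >= 1 & shifted[, 2] <= shape[2] &
          shifted[, 3] >= 1 & shifted[, 3] <= shape[3]
    out <- c(out, coords_to_index(shifted[ok, , drop = FALSE], shape))
  }
  unique(out)
}

# Place n lesions fully inside WM, pairwise separated, atlas-guided.
# Returns list of blobs; `occupied` forbids placement near existing lesions.
place_lesions <- function(n, geom, atlas_field, cfg, occupied = integer(0),
                          max_tries = 200L) {
  shape <- cfg$shape
  blocked <- array(FALSE, dim = shape)
  blocked[occupied] <- TRUE
  wm <- geom$labels == 3L
  blobs <- vector("list", n)
  i <- 1L
  while (i <= n) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      center <- sample_field_center(atlas_field, shape)
      radii <- runif(3, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2])
      rot <- random_rotation()
      blob <- lesion_blob(center, radii, rot, shape, cfg$spacing)
      sup_idx <- coords_to_index(blob$coords[blob$support, , drop = FALSE], shape)
      # support plus a 1-voxel rim must be WM; support must clear other lesions
      rim <- dilate_indices(sup_idx, shape, 1L)
      if (length(sup_idx) < 2L || !all(wm[rim])) next
      if (any(blocked[sup_idx]) || any(blocked[rim])) next
      blob$support_idx <- sup_idx
      blobs[[i]] <- blob
      blocked[dilate_indices(sup_idx, shape, 2L)] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stopf(paste0("could not place lesion %d of %d without overlap after %d tries; ",
                   "use a larger shape or fewer/smaller lesions"), i, n, max_tries)
    i <- i + 1L
  }
  blobs
}

apply_blobs <- function(base, blobs, contrast, shape) {
  for (blob in blobs) {
    idx <- coords_to_index(blob$coords, shape)
    base[idx] <- base[idx] + contrast * blob$taper
  }
  base
}

blob_mask <- function(blobs, shape) {
  m <- array(0, dim = shape)
  for (blob in blobs) m[blob$support_idx] <- 1
  m
}

tissue_intensity <- function(geom, cfg) {
  lut <- c(0, cfg$csf_intensity, cfg$gm_intensity, cfg$wm_intensity)
  array(lut[geom$labels + 1L], dim = cfg$shape)
}

#' Generate a brain-like FLAIR phantom
#'
#' Builds nested ellipsoidal tissue compartments, places
#' `cfg$n_lesions` Gaussian-tapered ellipsoidal hyperintense lesions fully
#' inside white matter (pairwise separated so each forms its own
#' 26-connected component), adds Gaussian noise, and derives a
#' lesion-probability atlas whose support lies in deep white matter and which
#' sums to 1.
#'
#' @param cfg A [phantom_config()].
#' @return A list with elements `volume` (`ll_volume`), `mask` (`ll_mask`),
#'   `tissue` (`ll_tissue`), `atlas` (`ll_atlas`).
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "ll_phantom_config"))
  with_seed(cfg$seed, {
    geom <- make_tissue_geometry(cfg$shape, cfg$spacing)
    atlas_field <- make_atlas_field(geom, cfg$shape)
    blobs <- place_lesions(cfg$n_lesions, geom, atlas_field, cfg)
    base <- tissue_intensity(geom, cfg)
    base <- apply_blobs(base, blobs, cfg$lesion_contrast, cfg$shape)
    noisy <- base + array(rnorm(prod(cfg$shape), 0, cfg$noise_sd), dim = cfg$shape)
    list(volume = volume(noisy, spacing = cfg$spacing),
         mask = lesion_mask(blob_mask(blobs, cfg$shape), spacing = cfg$spacing),
         tissue = tissue_map(geom$labels, spacing = cfg$spacing),
         atlas = lesion_atlas(make_atlas_field(geom, cfg$shape), spacing = cfg$spacing))
  })
}

#' Generate a ground-truth longitudinal phantom pair
#'
#' The second time-point equals the first plus `n_new` additional
#' hyperintense lesions; the two time-points share identical base lesions and
#' differ otherwise only by independent noise draws. Used as a ground-truth
#' end-to-end test bed for new-lesion detection.
#'
#' @param cfg A [phantom_config()] (its `n_lesions` are the shared lesions).
#' @param n_new Number of new lesions appearing at time-point 2.
#' @return List with `tp1`, `tp2` (`ll_volume`), `new_mask` (`ll_mask`),
#'   `tp1_mask` (`ll_mask` of shared lesions) and `tissue`, `atlas`.
#' @export
make_longitudinal_truth <- function(cfg, n_new) {
  stopifnot(inherits(cfg, "ll_phantom_config"), is_count(n_new))
  with_seed(cfg$seed, {
    geom <- make_tissue_geometry(cfg$shape, cfg$spacing)
    atlas_field <- make_atlas_field(geom, cfg$shape)
    shared <- place_lesions(cfg$n_lesions, geom, atlas_field, cfg)
    occupied <- unlist(lapply(shared, function(b)
      dilate_indices(b$support_idx, cfg$shape, 2L)))
    new <- place_lesions(n_new, geom, atlas_field, cfg, occupied = occupied)
    base <- tissue_intensity(geom, cfg)
    base1 <- apply_blobs(base, shared, cfg$lesion_contrast, cfg$shape)
    base2 <- apply_blobs(base1, new, cfg$lesion_contrast, cfg$shape)
    n <- prod(cfg$shape)
    tp1 <- base1 + array(rnorm(n, 0, cfg$noise_sd), dim = cfg$shape)
    tp2 <- base2 + array(rnorm(n, 0, cfg$noise_sd), dim = cfg$shape)
    list(tp1 = volume(tp1, spacing = cfg$spacing),
         tp2 = volume(tp2, spacing = cfg$spacing),
         new_mask = lesion_mask(blob_mask(new, cfg$shape), spacing = cfg$spacing),
         tp1_mask = lesion_mask(blob_mask(shared, cfg$shape), spacing = cfg$spacing),
         tissue = tissue_map(geom$labels, spacing = cfg$spacing),
         atlas = lesion_atlas(atlas_field, spacing = cfg$spacing))
  })
}
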