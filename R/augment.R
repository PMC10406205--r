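# MRI quality-disparity augmentation: nine acquisition-artifact operators
# (blur, edge enhancement, axial subsampling distortion, anisotropic
# downsampling, noise, bias field, and k-space motion / spike / ghosting)
# plus a seeded random sampler over them.

as_arr <- function(x) if (inherits(x, c("ll_volume", "ll_mask"))) x$data else x

rewrap <- function(x, arr) {
  if (inherits(x, "ll_volume")) volume(arr, spacing = x$spacing, space = x$space)
  else arr
}

#' Augmentation configuration
#'
#' Parameter ranges and application probabilities for the nine
#' acquisition-artifact operators. Ranges follow typical FLAIR acquisition
#' variability: blur SD in `[0.5, 1.75]` voxels, axial mean-filter widths
#' `{2,3,4}`, anisotropic downsampling factors `[1.5, 4]`, additive noise SD
#' `[0.02, 0.1]` on the normalized intensity scale, and k-space motion with
#' rotations in `[-5, 5]` degrees and translations in `[-4, 4]` mm.
#'
#' @param blur_sd_range Gaussian blur SD range, voxel units.
#' @param unsharp_amount_range Edge-enhancement strength range.
#' @param axial_filter_sizes Allowed axial mean-filter widths.
#' @param downsample_factor_range Anisotropic downsampling factor range.
#' @param noise_sd_range Additive Gaussian noise SD range.
#' @param bias_order Polynomial order of the multiplicative bias field.
#' @param bias_coeff_range Range of each log-bias polynomial coefficient.
#' @param motion_rotation_range Motion rotation range, degrees.
#' @param motion_translation_range Motion translation range, mm.
#' @param motion_n_transforms Number of k-space-composited positions
#'   (the first is always the unmoved reference).
#' @param spike_params List: `magnitude_rel_range` (spike magnitude relative
#'   to the DC coefficient), `n_spikes`.
#' @param ghost_params List: `periods` (every k-th line), `attenuation_range`.
#' @param probabilities Named per-operator application probabilities
#'   (default 1/9 each).
#' @param max_ops At most this many operators fire per draw.
#' @return A list of class `ll_augment_config`.
#' @export
augment_config <- function(blur_sd_range = c(0.5, 1.75),
                           unsharp_amount_range = c(0.5, 1.5),
                           axial_filter_sizes = c(2L, 3L, 4L),
                           downsample_factor_range = c(1.5, 4),
                           noise_sd_range = c(0.02, 0.1),
                           bias_order = 2L,
                           bias_coeff_range = c(-0.2, 0.2),
                           motion_rotation_range = c(-5, 5),
                           motion_translation_range = c(-4, 4),
                           motion_n_transforms = 3L,
                           spike_params = list(magnitude_rel_range = c(0.05, 0.2),
                                               n_spikes = 1L),
                           ghost_params = list(periods = 2:4,
                                               attenuation_range = c(0.2, 0.8)),
                           probabilities = NULL,
                           max_ops = 3L) {
  ops <- c("blur", "unsharp", "axial_subsample", "downsample", "bias",
           "motion", "spike", "ghost", "noise")
  if (is.null(probabilities)) probabilities <- stats::setNames(rep(1/9, 9), ops)
  if (is.null(names(probabilities))) names(probabilities) <- ops
  if (!all(names(probabilities) %in% ops))
    stopf("unknown operator in probabilities: %s",
          paste(setdiff(names(probabilities), ops), collapse = ", "))
  p <- stats::setNames(rep(0, 9), ops)
  p[names(probabilities)] <- probabilities
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0,1]")
  chk_range <- function(r, name) {
    if (length(r) != 2L || r[1] > r[2]) stopf("%s must be an increasing interval", name)
  }
  chk_range(blur_sd_range, "blur_sd_range")
  chk_range(downsample_factor_range, "downsample_factor_range")
  chk_range(noise_sd_range, "noise_sd_range")
  if (!all(axial_filter_sizes %in% 2:4)) stopf("axial_filter_sizes must be within {2,3,4}")
  structure(list(blur_sd_range = blur_sd_range,
                 unsharp_amount_range = unsharp_amount_range,
                 axial_filter_sizes = as.integer(axial_filter_sizes),
                 downsample_factor_range = downsample_factor_range,
                 noise_sd_range = noise_sd_range,
                 bias_order = as.integer(bias_order),
                 bias_coeff_range = bias_coeff_range,
                 motion_rotation_range = motion_rotation_range,
                 motion_translation_range = motion_translation_range,
                 motion_n_transforms = as.integer(motion_n_transforms),
                 spike_params = spike_params, ghost_params = ghost_params,
                 probabilities = p, max_ops = as.integer(max_ops)),
            class = "ll_augment_config")
}

gaussian_kernel_1d <- function(sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-0.5 * ((-r:r) / sd)^2)
  k / sum(k)
}

#' Gaussian blur (reflective boundaries)
#' @param vol `ll_volume` or 3D array.
#' @param sd Kernel standard deviation in voxel units; 0 is the identity.
#' @return Blurred input of the same type and grid.
#' @export
gaussian_blur <- function(vol, sd) {
  if (sd < 0) stopf("blur sd must be >= 0")
  a <- as_arr(vol)
  if (sd == 0) return(vol)
  d <- dim(a)
  k <- gaussian_kernel_1d(sd)
  for (axis in 0:2)
    a <- sepconv_reflect_cpp(a, d[1], d[2], d[3], k, axis)
  rewrap(vol, array(a, dim = d))
}

#' Edge enhancement by unsharp masking
#'
#' `out = vol + amount * (vol - blur(vol, sd))`: the inverse operation of
#' the blur filter.
#'
#' @param vol Input volume or array.
#' @param sd Blur SD of the subtracted low-pass, voxel units.
#' @param amount Enhancement strength; 0 is the identity.
#' @return Sharpened input, same grid.
#' @export
unsharp_mask <- function(vol, sd, amount) {
  if (sd <= 0) stopf("unsharp sd must be > 0")
  a <- as_arr(vol)
  b <- as_arr(gaussian_blur(a, sd))
  rewrap(vol, a + amount * (a - b))
}

#' Axial subsampling distortion
#'
#' Simulates thick-slice acquisition: a uniform (mean) filter of width `sz`
#' along the axial axis (third array axis), edge-replicated; in-plane axes
#' are untouched.
#'
#' @param vol Input volume or array.
#' @param sz Filter width, one of 2, 3, 4.
#' @return Filtered input, same grid.
#' @export
axial_subsample_distortion <- function(vol, sz) {
  if (!sz %in% 2:4) stopf("sz must be one of 2, 3, 4")
  a <- as_arr(vol)
  d <- dim(a)
  out <- meanfilter_axis_cpp(a, d[1], d[2], d[3], as.integer(sz), 2L)
  rewrap(vol, array(out, dim = d))
}

#' Anisotropic downsampling
#'
#' Downsamples along one axis by `factor` and resamples back to the original
#' grid with cubic spline interpolation, attenuating high-frequency content
#' along that axis while preserving the grid.
#'
#' @param vol Input volume or array.
#' @param axis Axis index (1, 2 or 3).
#' @param factor Downsampling factor, >= 1; 1 is the identity (to
#'   interpolation tolerance).
#' @return Resampled input, same grid.
#' @export
anisotropic_downsample <- function(vol, axis, factor) {
  if (factor < 1) stopf("downsampling factor must be >= 1")
  if (!axis %in% 1:3) stopf("axis must be 1, 2 or 3")
  a <- as_arr(vol)
  d <- dim(a)
  n <- d[axis]
  m <- max(2L, as.integer(round(n / factor)))
  pos_down <- (seq_len(m) - 0.5) * n / m - 0.5
  down <- interp_axis_bspline_cpp(a, d[1], d[2], d[3], axis - 1L, pos_down)
  dd <- d; dd[axis] <- m
  pos_up <- (seq_len(n) - 0.5) * m / n - 0.5
  up <- interp_axis_bspline_cpp(down, dd[1], dd[2], dd[3], axis - 1L, pos_up)
  rewrap(vol, array(up, dim = d))
}

#' Additive Gaussian noise
#' @param vol Input volume or array (intensity-normalized scale assumed).
#' @param sd Noise standard deviation; 0 is the identity.
#' @return Noisy input, same grid. Uses the current RNG stream.
#' @export
add_gaussian_noise <- function(vol, sd) {
  if (sd < 0) stopf("noise sd must be >= 0")
  a <- as_arr(vol)
  if (sd == 0) return(vol)
  rewrap(vol, a + array(rnorm(length(a), 0, sd), dim = dim(a)))
}

# 3D monomial exponent table for total degree <= order, deterministic order.
bias_basis_exponents <- function(order) {
  g <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  g <- g[g$i + g$j + g$k <= order, ]
  g[order(g$i + g$j + g$k, g$i, g$j, g$k), , drop = FALSE]
}

#' Number of bias-field basis functions for a polynomial order
#' @param order Polynomial total degree.
#' @return `choose(order + 3, 3)`.
#' @export
bias_n_coeffs <- function(order) choose(order + 3, 3)

#' Multiplicative polynomial bias field
#'
#' Multiplies the image by `exp(sum_k c_k phi_k(x))` where `phi_k` are the 3D
#' monomials of total degree `<= order` over coordinates scaled to
#' `[-1, 1]`, modelling smooth intensity inhomogeneity.
#'
#' @param vol Input volume or array.
#' @param coeffs Coefficient vector of length [bias_n_coeffs()]; all zeros is
#'   the identity.
#' @param order Polynomial order.
#' @return Biased input, same grid.
#' @export
bias_field <- function(vol, coeffs, order) {
  exps <- bias_basis_exponents(order)
  if (length(coeffs) != nrow(exps))
    stopf("expected %d coefficients for order %d, got %d",
          nrow(exps), order, length(coeffs))
  a <- as_arr(vol)
  d <- dim(a)
  cx <- if (d[1] > 1) seq(-1, 1, length.out = d[1]) else 0
  cy <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
  cz <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
  logb <- array(0, dim = d)
  for (r in seq_len(nrow(exps))) {
    if (coeffs[r] == 0) next
    logb <- logb + coeffs[r] *
      outer(outer(cx^exps$i[r], cy^exps$j[r]), cz^exps$k[r])
  }
  rewrap(vol, a * exp(logb))
}

rotation_matrix_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1,0,0, 0,cx,sx, 0,-sx,cx), 3, 3)
  ry <- matrix(c(cy,0,-sy, 0,1,0, sy,0,cy), 3, 3)
  rz <- matrix(c(cz,sz,0, -sz,cz,0, 0,0,1), 3, 3)
  rz %*% ry %*% rx
}

#' k-space acquisition artifacts: motion, spike, ghosting
#'
#' * `motion`: the k-space is composed from the FFTs of affinely transformed
#'   copies of the volume (the first copy is the unmoved reference),
#'   partitioned into contiguous blocks along the phase-encoding (second)
#'   axis, one block per position; the inverse FFT yields the corrupted
#'   image. `params`: `rotations` (n x 3 matrix, degrees), `translations`
#'   (n x 3 matrix, mm), optional `spacing`.
#' * `spike`: adds a high-magnitude point to the k-space.
#'   `params`: `location` (1-based index triple; `c(1,1,1)` is DC),
#'   `magnitude` (added to the complex coefficient).
#' * `ghost`: attenuates every `period`-th k-space line along one axis
#'   (offset lines, so DC is untouched), producing displaced replicas.
#'   `params`: `period`, `axis`, `attenuation` (0 is the identity),
#'   optional `offset` (default 1).
#'
#' @param vol Input volume or array.
#' @param kind One of `"motion"`, `"spike"`, `"ghost"`.
#' @param params Operator parameter list, see Details.
#' @return Real-valued corrupted input, same grid.
#' @export
kspace_artifact <- function(vol, kind, params = list()) {
  a <- as_arr(vol)
  d <- dim(a)
  n <- prod(d)
  out <- switch(kind,
    motion = {
      rot <- params$rotations
      tra <- params$translations
      if (is.null(dim(rot))) rot <- matrix(rot, ncol = 3)
      if (is.null(dim(tra))) tra <- matrix(tra, ncol = 3)
      spacing <- params$spacing %||% c(1, 1, 1)
      nt <- nrow(rot) + 1L   # first position is the unmoved reference
      ksp <- fft(a)
      breaks <- round(seq(0, d[2], length.out = nt + 1L))
      for (t in seq_len(nrow(rot))) {
        moved <- affine_resample_cpp(a, d[1], d[2], d[3],
                                     rotation_matrix_zyx(rot[t, ]),
                                     tra[t, ] / spacing, 0)
        kt <- fft(array(moved, dim = d))
        lo <- breaks[t + 1L] + 1L; hi <- breaks[t + 2L]
        if (hi >= lo) ksp[, lo:hi, ] <- kt[, lo:hi, ]
      }
      Re(fft(ksp, inverse = TRUE)) / n
    },
    spike = {
      loc <- params$location %||% c(1L, 1L, 1L)
      ksp <- fft(a)
      ksp[loc[1], loc[2], loc[3]] <- ksp[loc[1], loc[2], loc[3]] + params$magnitude
      Re(fft(ksp, inverse = TRUE)) / n
    },
    ghost = {
      period <- params$period %||% 2L
      axis <- params$axis %||% 2L
      att <- params$attenuation %||% 0.5
      offset <- params$offset %||% 1L
      if (att == 0) return(vol)
      ksp <- fft(a)
      idx <- which((seq_len(d[axis]) - 1L) %% period == offset %% period)
      if (axis == 1) ksp[idx, , ] <- ksp[idx, , ] * (1 - att)
      else if (axis == 2) ksp[, idx, ] <- ksp[, idx, ] * (1 - att)
      else ksp[, , idx] <- ksp[, , idx] * (1 - att)
      Re(fft(ksp, inverse = TRUE)) / n
    },
    stopf("unknown k-space artifact kind: %s", kind)
  )
  if (inherits(out, c("ll_volume"))) return(out)
  rewrap(vol, array(out, dim = d))
}

runif1 <- function(range) runif(1, range[1], range[2])

#' Random acquisition-artifact augmentation
#'
#' Each operator fires independently with its configured probability (capped
#' at `cfg$max_ops` per draw), with parameters drawn uniformly from its
#' range. Operators are applied in acquisition-chain order: spatial-domain
#' operators first (blur, unsharp, axial subsampling, downsampling, bias),
#' then k-space operators (motion, spike, ghost), then noise last.
#'
#' @param vol Input `ll_volume` or 3D array.
#' @param cfg An [augment_config()].
#' @param seed Integer seed; the draw (and [replay_augment()]) is fully
#'   determined by it.
#' @return List with `volume` (augmented input) and `log` (operator order,
#'   parameters and seed, sufficient to replay bitwise).
#' @export
random_augment <- function(vol, cfg, seed) {
  stopifnot(inherits(cfg, "ll_augment_config"))
  with_seed(seed, {
    ops <- names(cfg$probabilities)
    fired <- runif(length(ops)) < cfg$probabilities
    chosen <- ops[fired]
    if (length(chosen) > cfg$max_ops)
      chosen <- chosen[sort(sample.int(length(chosen), cfg$max_ops))]
    log <- list(seed = seed, ops = list())
    d <- dim(as_arr(vol))
    out <- vol
    for (op in ops) {    # ops is already in canonical application order
      if (!op %in% chosen) next
      params <- switch(op,
        blur = list(sd = runif1(cfg$blur_sd_range)),
        unsharp = list(sd = runif1(cfg$blur_sd_range),
                       amount = runif1(cfg$unsharp_amount_range)),
        axial_subsample = list(sz = sample(cfg$axial_filter_sizes, 1L)),
        downsample = list(axis = sample.int(3L, 1L),
                          factor = runif1(cfg$downsample_factor_range)),
        bias = list(order = cfg$bias_order,
                    coeffs = runif(bias_n_coeffs(cfg$bias_order),
                                   cfg$bias_coeff_range[1], cfg$bias_coeff_range[2])),
        motion = {
          nt <- cfg$motion_n_transforms - 1L
          list(rotations = matrix(runif(3 * nt, cfg$motion_rotation_range[1],
                                        cfg$motion_rotation_range[2]), ncol = 3),
               translations = matrix(runif(3 * nt, cfg$motion_translation_range[1],
                                           cfg$motion_translation_range[2]), ncol = 3))
        },
        spike = {
          loc <- vapply(d, function(k) sample.int(k, 1L), integer(1))
          if (all(loc == 1L)) loc[1] <- 2L
          list(location = loc,
               magnitude = runif1(cfg$spike_params$magnitude_rel_range) *
                 abs(sum(as_arr(vol))))
        },
        ghost = list(period = sample(cfg$ghost_params$periods, 1L),
                     axis = sample.int(3L, 1L),
                     attenuation = runif1(cfg$ghost_params$attenuation_range),
                     offset = 1L),
        noise = list(sd = runif1(cfg$noise_sd_range),
                     sub_seed = sample.int(.Machine$integer.max, 1L))
      )
      out <- apply_augment_op(out, op, params)
      log$ops[[length(log$ops) + 1L]] <- list(op = op, params = params)
    }
    list(volume = out, log = log)
  })
}

apply_augment_op <- function(vol, op, params) {
  switch(op,
    blur = gaussian_blur(vol, params$sd),
    unsharp = unsharp_mask(vol, params$sd, params$amount),
    axial_subsample = axial_subsample_distortion(vol, params$sz),
    downsample = anisotropic_downsample(vol, params$axis, params$factor),
    bias = bias_field(vol, params$coeffs, params$order),
    motion = kspace_artifact(vol, "motion", params),
    spike = kspace_artifact(vol, "spike", params),
    ghost = kspace_artifact(vol, "ghost", params),
    noise = with_seed(params$sub_seed, add_gaussian_noise(vol, params$sd)),
    stopf("unknown operator: %s", op))
}

#' Replay a logged augmentation
#'
#' Applies the operators recorded by [random_augment()] with their logged
#' parameters, reproducing the output bitwise.
#'
#' @param vol The same input that was augmented.
#' @param log The `log` element returned by [random_augment()].
#' @return The augmented volume.
#' @export
replay_augment <- function(vol, log) {
  out <- vol
  for (entry in log$ops) out <- apply_augment_op(out, entry$op, entry$params)
  out
}

# Random flips and orthogonal 90-degree rotations, applied identically to a
# list of aligned arrays (exact for masks and label maps). Used by the
# time-point synthesis step. Returns the transformed arrays.
random_flip_rotation <- function(arrays) {
  flips <- runif(3) < 0.5
  plane <- sample.int(3L, 1L)        # rotation plane: axes other than `plane`
  k <- sample(0:3, 1L)               # number of quarter turns
  axes <- setdiff(1:3, plane)
  lapply(arrays, function(a) {
    d <- dim(a)
    idx <- lapply(seq_along(d), function(i) if (flips[i]) rev(seq_len(d[i])) else seq_len(d[i]))
    a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    if (k > 0 && d[axes[1]] == d[axes[2]]) {
      perm <- seq_len(3); perm[axes] <- axes[2:1]
      for (q in seq_len(k)) {
        a <- aperm(a, perm)
        ridx <- lapply(seq_len(3), function(i) if (i == axes[1]) rev(seq_len(dim(a)[i])) else seq_len(dim(a)[i]))
        a <- do.call(`[`, c(list(a), ridx, list(drop = FALSE)))
      }
    }
    a
  })
}
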