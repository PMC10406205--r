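rand_vol <- function(n = 16, seed = 1) {
  set.seed(seed)
  volume(array(0.3 + 0.1 * rnorm(n^3), dim = c(n, n, n)))
}

test_that("each operator has an identity parameter setting", {
  v <- rand_vol()
  expect_identical(gaussian_blur(v, 0)$data, v$data)
  expect_equal(unsharp_mask(v, 1, 0)$data, v$data, tolerance = 1e-12)
  expect_lt(max(abs(anisotropic_downsample(v, 1, 1)$data - v$data)), 1e-5)
  expect_identical(add_gaussian_noise(v, 0)$data, v$data)
  expect_identical(bias_field(v, numeric(bias_n_coeffs(2)), 2)$data, v$data)
  zero_motion <- list(rotations = matrix(0, 2, 3), translations = matrix(0, 2, 3))
  expect_lt(max(abs(kspace_artifact(v, "motion", zero_motion)$data - v$data)), 1e-5)
  expect_lt(max(abs(kspace_artifact(v, "ghost",
                                    list(period = 2, axis = 2, attenuation = 0))$data -
                      v$data)), 1e-5)
})

test_that("blur of a constant volume is unchanged and intensity is conserved", {
  const <- volume(array(0.7, dim = c(12, 12, 12)))
  expect_equal(gaussian_blur(const, 1.5)$data, const$data, tolerance = 1e-12)
  v <- rand_vol()
  for (sd in c(0.5, 1, 1.75)) {
    b <- gaussian_blur(v, sd)
    expect_lt(abs(sum(b$data) - sum(v$data)) / abs(sum(v$data)), 1e-3)
  }
})

test_that("blurred delta impulse matches the sampled 3D Gaussian kernel", {
  n <- 17L
  a <- array(0, dim = c(n, n, n)); a[9, 9, 9] <- 1
  out <- gaussian_blur(volume(a), 1)$data
  r <- 3L
  k1 <- exp(-0.5 * ((-r:r) / 1)^2); k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  got <- out[(9 - r):(9 + r), (9 - r):(9 + r), (9 - r):(9 + r)]
  expect_lt(max(abs(got - expected)), 1e-4)
})

test_that("unsharp masking follows its definition and amplifies edges", {
  v <- rand_vol()
  out <- unsharp_mask(v, 1, 0.8)
  blur <- gaussian_blur(v, 1)
  expect_equal(out$data, v$data + 0.8 * (v$data - blur$data), tolerance = 1e-12)
  const <- volume(array(0.4, dim = c(10, 10, 10)))
  expect_equal(unsharp_mask(const, 1, 2)$data, const$data, tolerance = 1e-12)
  # step edge (along the third axis): gradient magnitude strictly increases
  step <- array(rep(c(0, 1), each = 8 * 16 * 16), dim = c(16, 16, 16))
  sharp <- unsharp_mask(volume(step), 1, 1)$data
  g0 <- abs(step[8, 8, 9] - step[8, 8, 8])
  g1 <- abs(sharp[8, 8, 9] - sharp[8, 8, 8])
  expect_gt(g1, g0)
})

test_that("axial mean filter acts along the axial axis only", {
  # constant along the axial axis: identity
  a <- array(rep(matrix(rnorm(64), 8, 8), 8), dim = c(8, 8, 8))
  expect_equal(axial_subsample_distortion(volume(a), 3)$data, a,
               tolerance = 1e-12)
  # axial ramp, sz = 2: window [i, i+1], so means of adjacent pairs
  ramp <- aperm(array(rep(0:3, 16), dim = c(4, 4, 4)), c(2, 3, 1))
  out <- axial_subsample_distortion(volume(ramp), 2)$data
  expect_equal(out[1, 1, ], c(0.5, 1.5, 2.5, 3))   # last slice edge-replicated
  expect_error(axial_subsample_distortion(volume(ramp), 5), "one of 2, 3, 4")
})

test_that("axial filtering smooths only the axial axis of a separable pattern", {
  set.seed(4)
  inplane <- matrix(rnorm(16 * 16), 16, 16)
  axial <- rnorm(16)
  a <- outer(inplane, axial)          # dims 16 x 16 x 16, separable
  out <- axial_subsample_distortion(volume(array(a, dim = c(16, 16, 16))), 3)$data
  # axial autocorrelation increases (differences shrink)
  d_ax_before <- mean(abs(diff(a[8, 8, ])))
  d_ax_after <- mean(abs(diff(out[8, 8, ])))
  expect_lt(d_ax_after, d_ax_before)
  # in-plane structure of each slice is preserved up to scale: correlation ~ 1
  cors <- vapply(1:16, function(z) cor(as.vector(out[, , z]), as.vector(inplane)),
                 numeric(1))
  expect_true(all(abs(cors) > 0.999))
})

test_that("anisotropic downsampling attenuates high frequencies, keeps low ones", {
  n <- 32L
  zs <- seq_len(n)
  low <- array(rep(sin(2 * pi * zs / 32), each = n * n), dim = c(n, n, n))
  out_low <- anisotropic_downsample(volume(low), 3, 2)$data
  rms <- function(x) sqrt(mean(x^2))
  # frequency response measured away from the mirror boundaries
  core <- 5:(n - 4)
  expect_lt(rms(out_low[, , core] - low[, , core]) / rms(low[, , core]), 0.02)
  expect_lt(rms(out_low - low) / rms(low), 0.05)
  nyq <- array(rep(c(1, -1), length.out = n * n * n), dim = c(n, n, n))
  nyq <- aperm(array(rep(rep(c(1, -1), length.out = n), n * n), dim = c(n, n, n)),
               c(2, 3, 1))
  out_nyq <- anisotropic_downsample(volume(nyq), 3, 2)$data
  expect_lt(rms(out_nyq - mean(out_nyq)), 0.2 * rms(nyq - mean(nyq)))
  expect_error(anisotropic_downsample(volume(low), 3, 0.8), ">= 1")
})

test_that("added noise has the configured statistics and is seed-stable", {
  z <- volume(array(0, dim = c(64, 64, 64)))
  set.seed(5)
  out <- add_gaussian_noise(z, 0.1)$data
  expect_lt(abs(mean(out)), 3 * 0.1 / sqrt(length(out)))
  expect_true(sd(out) > 0.095 && sd(out) < 0.105)
  a <- with_seed_test(7, add_gaussian_noise(z, 0.05)$data)
  b <- with_seed_test(7, add_gaussian_noise(z, 0.05)$data)
  expect_identical(a, b)
})

test_that("bias field is multiplicative, exact for constants, log-linear", {
  v <- rand_vol()
  # constant-only coefficient: uniform scaling by exp(c)
  co <- numeric(bias_n_coeffs(1)); co[1] <- 0.3
  out <- bias_field(v, co, 1)
  expect_equal(out$data, v$data * exp(0.3), tolerance = 1e-12)
  expect_error(bias_field(v, numeric(3), 1), "expected 4 coefficients")
  # single axis-linear coefficient at order 2: log-ratio is linear along x
  ones <- volume(array(1, dim = c(16, 16, 16)))
  co2 <- numeric(bias_n_coeffs(2))
  co2[4] <- 0.5    # basis order within degree 1: z, y, then x
  out2 <- bias_field(ones, co2, 2)$data
  prof <- log(out2[, 8, 8])
  x <- seq(-1, 1, length.out = 16)
  fit <- lm(prof ~ x)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-9)
})

test_that("k-space spike at the origin adds a constant m/N", {
  v <- rand_vol(12)
  n <- length(v$data)
  out <- kspace_artifact(v, "spike", list(location = c(1, 1, 1), magnitude = 7))
  expect_equal(out$data, v$data + 7 / n, tolerance = 1e-10)
  expect_error(kspace_artifact(v, "wiggle", list()), "unknown k-space")
})

test_that("ghosting attenuates periodic k-space lines, sparing DC", {
  v <- rand_vol(16)
  out <- kspace_artifact(v, "ghost", list(period = 2, axis = 2,
                                          attenuation = 0.5))
  expect_true(all(is.finite(out$data)))
  # DC (overall mean) preserved: only offset lines are attenuated
  expect_equal(mean(out$data), mean(v$data), tolerance = 1e-10)
  expect_gt(max(abs(out$data - v$data)), 1e-4)
})

test_that("motion artifact is real-valued and grid-preserving", {
  v <- rand_vol(16)
  out <- kspace_artifact(v, "motion",
                         list(rotations = matrix(c(3, -2, 4), 1, 3),
                              translations = matrix(c(2, -1, 0), 1, 3)))
  expect_identical(dim(out$data), dim(v$data))
  expect_true(all(is.finite(out$data)))
  expect_gt(max(abs(out$data - v$data)), 1e-4)
})

test_that("random augmentation with zero probabilities is the identity", {
  v <- rand_vol()
  cfg <- augment_config(probabilities = setNames(rep(0, 9),
    c("blur", "unsharp", "axial_subsample", "downsample", "bias",
      "motion", "spike", "ghost", "noise")))
  res <- random_augment(v, cfg, seed = 3)
  expect_identical(res$volume$data, v$data)
  expect_length(res$log$ops, 0)
})

test_that("random augmentation is deterministic and replayable bitwise", {
  v <- rand_vol()
  cfg <- augment_config()
  for (seed in c(2, 5, 8, 13)) {
    r1 <- random_augment(v, cfg, seed)
    r2 <- random_augment(v, cfg, seed)
    expect_identical(r1$volume$data, r2$volume$data)
    expect_identical(r1$log, r2$log)
    expect_identical(replay_augment(v, r1$log)$data, r1$volume$data)
    expect_true(all(is.finite(r1$volume$data)))
    expect_identical(dim(r1$volume$data), dim(v$data))
    expect_lte(length(r1$log$ops), cfg$max_ops)
  }
})

test_that("operator application frequency follows its probability", {
  v <- volume(array(0.5, dim = c(6, 6, 6)))
  cfg <- augment_config(probabilities = c(blur = 0.3))
  hits <- sum(vapply(1:1000, function(s) {
    length(random_augment(v, cfg, seed = s)$log$ops) > 0
  }, logical(1)))
  expect_true(abs(hits - 300) <= 45)   # 3 sigma of Binomial(1000, 0.3)
})
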