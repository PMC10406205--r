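mask_of <- function(arr) lesion_mask(arr, c(1, 1, 1))

test_that("voxel confusion counts match their definitions", {
  a <- array(0, dim = c(6, 6, 6)); a[1:10] <- 1
  expect_equal(voxel_confusion(mask_of(a), mask_of(a)),
               list(TP = 10L, FP = 0L, FN = 0L))
  empty <- array(0, dim = c(6, 6, 6))
  g <- array(0, dim = c(6, 6, 6)); g[5:11] <- 1
  expect_equal(voxel_confusion(mask_of(empty), mask_of(g)),
               list(TP = 0L, FP = 0L, FN = 7L))
  expect_error(voxel_confusion(mask_of(a), mask_of(array(0, dim = c(5, 6, 6)))),
               "grids differ")
})

test_that("voxel metrics follow the printed formulas and flag 0/0 cases", {
  m <- voxel_metrics(list(TP = 2, FP = 1, FN = 1))
  expect_equal(m$dice, 2 / 3)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$tpr, 2 / 3)
  perfect <- voxel_metrics(list(TP = 5, FP = 0, FN = 0))
  expect_equal(c(perfect$dice, perfect$ppv, perfect$tpr), c(1, 1, 1))
  both_empty <- voxel_metrics(list(TP = 0, FP = 0, FN = 0))
  expect_equal(both_empty$dice, 1)
  expect_true(is.na(both_empty$ppv) && !both_empty$ppv_defined)
  expect_true(is.na(both_empty$tpr) && !both_empty$tpr_defined)
})

test_that("dice equals the harmonic mean of ppv and tpr", {
  set.seed(81)
  for (i in 1:1000) {
    counts <- list(TP = sample(1:100, 1), FP = sample(0:100, 1),
                   FN = sample(0:100, 1))
    m <- voxel_metrics(counts)
    expect_equal(m$dice, 2 * m$ppv * m$tpr / (m$ppv + m$tpr),
                 tolerance = 1e-12)
  }
})

test_that("small-lesion filtering respects the 3 mm^3 boundary and is idempotent", {
  a <- array(0, dim = c(12, 12, 12))
  a[2:3, 2, 2] <- 1                 # 2 voxels = 2 mm^3 at 1 mm iso: removed
  a[8:10, 8, 8] <- 1                # 3 voxels = 3 mm^3: kept (tie)
  f <- filter_small_lesions(mask_of(a))
  expect_equal(sum(f$data), 3)
  expect_equal(sum(f$data[8:10, 8, 8]), 3)
  expect_identical(filter_small_lesions(f)$data, f$data)
  empty <- mask_of(array(0, dim = c(6, 6, 6)))
  expect_equal(sum(filter_small_lesions(empty)$data), 0)
  # anisotropic spacing: volume is voxels times voxel volume
  m2 <- lesion_mask(a, spacing = c(2, 1, 1))   # 2-voxel lesion is now 4 mm^3
  expect_equal(sum(filter_small_lesions(m2)$data), 5)
})

test_that("lesion-wise rules reproduce the worked detection cases", {
  # identical three-component masks
  a <- array(0, dim = c(16, 16, 16))
  a[2:4, 2:4, 2:4] <- 1; a[8:10, 8:10, 8:10] <- 1; a[13:15, 2:4, 13:15] <- 1
  lm <- lesion_metrics(mask_of(a), mask_of(a))
  expect_equal(c(lm$SL, lm$PL, lm$les_f1), c(1, 1, 1))

  # one 20-voxel gt lesion; prediction covers 2 of its voxels and nothing else:
  # coverage 10% passes SL; the 2-voxel prediction lies fully inside -> PL 1
  g <- array(0, dim = c(12, 12, 12)); g[3:7, 3:6, 3] <- 1   # 20 voxels
  p <- array(0, dim = c(12, 12, 12)); p[3:4, 3, 3] <- 1     # 2 of them
  lm2 <- lesion_metrics(mask_of(p), mask_of(g),
                        detection_rules(min_lesion_volume = 0))
  expect_equal(lm2$SL, 1)
  expect_equal(lm2$PL, 1)
  expect_equal(lm2$les_f1, 1)
  # 9% coverage fails the 10% rule
  g3 <- array(0, dim = c(14, 14, 14)); g3[2:12, 2:11, 2] <- 0
  g3[2:11, 2:11, 2] <- 1                                    # 100 voxels
  p3 <- array(0, dim = c(14, 14, 14)); p3[2:10, 2, 2] <- 1  # 9 of them
  lm3 <- lesion_metrics(mask_of(p3), mask_of(g3))
  expect_equal(lm3$SL, 0)
  # 65%-overlap boundary for PL: 13/20 inside (65%) passes, 12/20 fails
  g4 <- array(0, dim = c(14, 14, 14)); g4[2:11, 2:3, 2] <- 1
  p4 <- array(0, dim = c(14, 14, 14)); p4[2:11, 3:4, 2] <- 1  # 10 in, 10 out
  lm4 <- lesion_metrics(mask_of(p4), mask_of(g4))
  expect_equal(lm4$PL, 0)   # 50% < 65%
  p5 <- array(0, dim = c(14, 14, 14))
  p5[2:11, 3, 2] <- 1; p5[2:4, 4, 2] <- 1   # 10 inside, 3 outside: 77% in
  lm5 <- lesion_metrics(mask_of(p5), mask_of(g4))
  expect_equal(lm5$PL, 1)
})

test_that("undefined lesion metrics are flagged rather than zeroed", {
  empty <- mask_of(array(0, dim = c(8, 8, 8)))
  a <- array(0, dim = c(8, 8, 8)); a[2:4, 2:4, 2:4] <- 1
  lm <- lesion_metrics(mask_of(a), empty)
  expect_false(lm$sl_defined)
  expect_true(is.na(lm$SL))
  lm2 <- lesion_metrics(empty, mask_of(a))
  expect_false(lm2$pl_defined)
  expect_true(is.na(lm2$PL))
  expect_equal(lm2$SL, 0)
})

test_that("lesion F1 is the harmonic mean with a 0/0 guard", {
  # SL = PL = 0.5 -> f1 = 0.5: one detected of two, one true positive of two
  g <- array(0, dim = c(20, 20, 8))
  g[2:4, 2:4, 2:4] <- 1; g[10:12, 10:12, 2:4] <- 1
  p <- array(0, dim = c(20, 20, 8))
  p[2:4, 2:4, 2:4] <- 1                 # matches lesion 1 fully
  p[16:18, 16:18, 2:4] <- 1             # false positive component
  lm <- lesion_metrics(mask_of(p), mask_of(g))
  expect_equal(lm$SL, 0.5)
  expect_equal(lm$PL, 0.5)
  expect_equal(lm$les_f1, 0.5)
  # totally disjoint masks: SL = PL = 0 and f1 = 0 by convention
  q <- array(0, dim = c(20, 20, 8)); q[16:18, 16:18, 2:4] <- 1
  lm0 <- lesion_metrics(mask_of(q), mask_of(g))
  expect_equal(lm0$les_f1, 0)
})

test_that("avg score averages dice and lesion F1", {
  expect_equal(avg_score(1, 1), 1)
  expect_equal(avg_score(0.514, 0.573), 0.5435)
  expect_equal(avg_score(0, 0.8), 0.4)
  expect_true(is.na(avg_score(NA_real_, 0.5)))
})

test_that("metrics match brute-force oracles on random mask pairs", {
  set.seed(82)
  for (i in 1:30) {
    p <- random_mask_array(c(16, 16, 16), p = runif(1, 0.05, 0.3))
    g <- random_mask_array(c(16, 16, 16), p = runif(1, 0.05, 0.3))
    vc <- voxel_confusion(mask_of(p), mask_of(g))
    ovc <- oracle_voxel_confusion(p, g)
    expect_identical(vc$TP, ovc$TP)
    expect_identical(vc$FP, ovc$FP)
    expect_identical(vc$FN, ovc$FN)
    lm <- lesion_metrics(mask_of(p), mask_of(g))
    olm <- oracle_lesion_metrics(p, g)
    expect_identical(lm$SL, olm$SL)
    expect_identical(lm$PL, olm$PL)
    expect_identical(lm$les_f1, olm$les_f1)
  }
})

test_that("adding a true-positive voxel never decreases dice or tpr", {
  set.seed(83)
  for (i in 1:50) {
    p <- random_mask_array(c(10, 10, 10), 0.15)
    g <- random_mask_array(c(10, 10, 10), 0.15)
    miss <- which(g > 0 & p == 0)
    if (length(miss) == 0) next
    m0 <- voxel_metrics(voxel_confusion(mask_of(p), mask_of(g)))
    p2 <- p; p2[miss[sample.int(length(miss), 1)]] <- 1
    m1 <- voxel_metrics(voxel_confusion(mask_of(p2), mask_of(g)))
    expect_gte(m1$dice, m0$dice)
    expect_gte(m1$tpr, ifelse(is.na(m0$tpr), 0, m0$tpr))
  }
})

test_that("the paired Wilcoxon test matches exact enumeration", {
  a <- c(0.5, 0.6, 0.55, 0.7, 0.62, 0.58, 0.64, 0.51, 0.69, 0.57)
  res <- paired_wilcoxon(a, a)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  b <- a + 0.1
  res2 <- paired_wilcoxon(b, a)
  expect_equal(res2$p_value, oracle_signed_rank_p(b - a), tolerance = 1e-12)
  expect_equal(res2$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_true(res2$significant)
  res3 <- paired_wilcoxon(a, b)
  expect_equal(res3$p_value, res2$p_value)
  set.seed(84)
  x <- rnorm(12); y <- x + rnorm(12, 0.05, 0.2)
  expect_equal(paired_wilcoxon(x, y)$p_value,
               oracle_signed_rank_p(x - y), tolerance = 1e-12)
  expect_error(paired_wilcoxon(1:3, 2:4), "at least 6")
})

test_that("cohort evaluation aggregates defined cases with counts", {
  a <- array(0, dim = c(10, 10, 10)); a[2:4, 2:4, 2:4] <- 1
  empty <- array(0, dim = c(10, 10, 10))
  rep <- evaluate_cohort(list(
    list(pred = mask_of(a), gt = mask_of(a)),
    list(pred = mask_of(empty), gt = mask_of(a))))
  expect_equal(rep$summary$dice$mean, 0.5)   # (1 + 0) / 2
  expect_equal(rep$summary$dice$n, 2)
  expect_equal(rep$summary$PL$n, 1)          # undefined PL excluded
  expect_equal(rep$summary$avg_score$n, 1)
})
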