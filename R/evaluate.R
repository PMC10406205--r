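# Voxel-wise and lesion-wise segmentation metrics, the aggregate score, and
# the paired Wilcoxon significance test.

#' Lesion detection rules
#'
#' Defaults match the standard new-lesion evaluation protocol: lesions
#' smaller than 3 mm^3 are removed from both masks; a ground-truth lesion
#' counts as detected when at least 10% of it is covered by the
#' segmentation; a predicted lesion is a true positive when at least 65% of
#' it overlaps the ground truth and no more than 70% of it lies outside
#' (the outside clause is implied by the first but implemented literally,
#' and both thresholds are overridable). Ties at a threshold pass
#' ("at least" readings).
#'
#' @param min_lesion_volume Minimum lesion volume kept, mm^3.
#' @param sl_overlap_min Minimum covered fraction for lesion sensitivity.
#' @param pl_overlap_min Minimum overlap fraction for lesion PPV.
#' @param pl_outside_max Maximum outside fraction for lesion PPV.
#' @return A list of class `ll_detection_rules`.
#' @export
detection_rules <- function(min_lesion_volume = 3, sl_overlap_min = 0.10,
                            pl_overlap_min = 0.65, pl_outside_max = 0.70) {
  structure(list(min_lesion_volume = min_lesion_volume,
                 sl_overlap_min = sl_overlap_min,
                 pl_overlap_min = pl_overlap_min,
                 pl_outside_max = pl_outside_max),
            class = "ll_detection_rules")
}

#' Voxel-level confusion counts
#' @param pred,gt Binary `ll_mask`s on the same grid.
#' @return List with integer `TP`, `FP`, `FN`.
#' @export
voxel_confusion <- function(pred, gt) {
  if (!same_grid(pred, gt)) stopf("prediction and ground-truth grids differ")
  p <- pred$data > 0; g <- gt$data > 0
  list(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g))
}

#' Voxel-wise metrics from confusion counts
#'
#' `dice = 2 TP / ((TP+FN) + (TP+FP))`, `ppv = TP / (TP+FP)`,
#' `tpr = TP / (TP+FN)`. A zero denominator yields `NA` with the
#' corresponding `*_defined` flag set to `FALSE`, except that dice is 1 when
#' prediction and ground truth are both empty.
#'
#' @param counts Output of [voxel_confusion()].
#' @return List with `dice`, `ppv`, `tpr` and `dice_defined`, `ppv_defined`,
#'   `tpr_defined` flags.
#' @export
voxel_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  dice_den <- (TP + FN) + (TP + FP)
  dice <- if (dice_den == 0) 1 else 2 * TP / dice_den
  ppv <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  tpr <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  list(dice = dice, ppv = ppv, tpr = tpr,
       dice_defined = TRUE, ppv_defined = TP + FP > 0, tpr_defined = TP + FN > 0)
}

#' Remove lesions below the minimum volume
#'
#' Connected components (26-connectivity) with volume strictly below
#' `rules$min_lesion_volume` are removed; exact ties are kept. Applied to
#' both prediction and ground truth before lesion-wise metrics.
#'
#' @param mask An `ll_mask`.
#' @param rules A [detection_rules()].
#' @return The filtered `ll_mask`.
#' @export
filter_small_lesions <- function(mask, rules = detection_rules()) {
  comps <- split_lesions(mask)
  if (length(comps) == 0L) return(mask)
  out <- mask$data
  for (comp in comps)
    if (comp$volume_mm3 < rules$min_lesion_volume) out[comp$idx] <- 0
  lesion_mask(out, mask$spacing)
}

#' Lesion-wise detection metrics
#'
#' `SL` (lesion sensitivity) is the proportion of ground-truth components
#' with at least `sl_overlap_min` of their volume covered by the
#' prediction. `PL` (lesion positive predictive value) is the proportion of
#' predicted components with at least `pl_overlap_min` of their volume
#' inside the ground truth and at most `pl_outside_max` outside.
#' `les_f1 = 2*SL*PL/(SL+PL)` (0 when both are 0). Small-lesion filtering
#' is applied first. Matching is per component by any-overlap; no
#' one-to-one assignment is made.
#'
#' @param pred,gt Binary `ll_mask`s on the same grid.
#' @param rules A [detection_rules()].
#' @param prefiltered Set to `TRUE` if [filter_small_lesions()] was already
#'   applied to both masks.
#' @return List with `SL`, `PL`, `les_f1`, defined-flags, and `match_table`
#'   (per-lesion overlap fractions and decisions).
#' @export
lesion_metrics <- function(pred, gt, rules = detection_rules(),
                           prefiltered = FALSE) {
  if (!same_grid(pred, gt)) stopf("prediction and ground-truth grids differ")
  if (!prefiltered) {
    pred <- filter_small_lesions(pred, rules)
    gt <- filter_small_lesions(gt, rules)
  }
  gt_comps <- split_lesions(gt)
  pred_comps <- split_lesions(pred)
  pv <- pred$data > 0; gv <- gt$data > 0
  gt_rows <- lapply(gt_comps, function(comp) {
    frac <- sum(pv[comp$idx]) / length(comp$idx)
    data.frame(kind = "gt", label = comp$label, size = length(comp$idx),
               overlap_frac = frac, outside_frac = NA_real_,
               positive = frac >= rules$sl_overlap_min)
  })
  pred_rows <- lapply(pred_comps, function(comp) {
    inside <- sum(gv[comp$idx]) / length(comp$idx)
    outside <- 1 - inside
    data.frame(kind = "pred", label = comp$label, size = length(comp$idx),
               overlap_frac = inside, outside_frac = outside,
               positive = inside >= rules$pl_overlap_min &
                          outside <= rules$pl_outside_max)
  })
  tab <- do.call(rbind, c(gt_rows, pred_rows))
  SL <- if (length(gt_comps)) mean(vapply(gt_rows, function(r) r$positive, logical(1)))
        else NA_real_
  PL <- if (length(pred_comps)) mean(vapply(pred_rows, function(r) r$positive, logical(1)))
        else NA_real_
  les_f1 <- if (is.na(SL) || is.na(PL)) NA_real_
            else if (SL + PL == 0) 0
            else 2 * SL * PL / (SL + PL)
  list(SL = SL, PL = PL, les_f1 = les_f1,
       sl_defined = length(gt_comps) > 0, pl_defined = length(pred_comps) > 0,
       match_table = tab)
}

#' Aggregate score: mean of dice and lesion F1
#' @param v Output of [voxel_metrics()] (or a dice scalar).
#' @param l Output of [lesion_metrics()] (or a les_f1 scalar).
#' @return `(dice + les_f1) / 2`; `NA` if either input is undefined.
#' @export
avg_score <- function(v, l) {
  dice <- if (is.list(v)) v$dice else v
  f1 <- if (is.list(l)) l$les_f1 else l
  if (is.na(dice) || is.na(f1)) return(NA_real_)
  (dice + f1) / 2
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided, zero-difference pairs dropped; significance at p < 0.05. When
#' every difference is zero the test is degenerate: p = 1 and the
#' `degenerate` flag is set. For up to 14 effective pairs the p-value is
#' computed exactly by enumerating all sign assignments of the absolute-rank
#' sums (valid under ties, with average ranks); larger samples delegate to
#' [stats::wilcox.test()].
#'
#' @param scores_a,scores_b Per-case score lists, paired by position
#'   (length >= 6).
#' @return List with `statistic`, `p_value`, `significant`, `degenerate`,
#'   `n_effective` (pairs after dropping zeros).
#' @export
paired_wilcoxon <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stopf("score lists must be paired")
  if (length(scores_a) < 6L) stopf("need at least 6 pairs")
  d <- scores_a - scores_b
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = NA_real_, p_value = 1, significant = FALSE,
                degenerate = TRUE, n_effective = 0L))
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= 14L) {
    # exact sign-flip distribution of the positive-rank sum
    sums <- 0
    for (i in seq_len(n)) sums <- c(sums, sums + r[i])
    p <- min(1, 2 * min(mean(sums >= W), mean(sums <= W)))
  } else {
    ht <- suppressWarnings(wilcox.test(scores_a, scores_b, paired = TRUE,
                                       alternative = "two.sided"))
    p <- ht$p.value
  }
  list(statistic = W, p_value = p, significant = p < 0.05,
       degenerate = FALSE, n_effective = n)
}

#' Evaluate one predicted new-lesion mask against ground truth
#'
#' @param pred,gt Binary `ll_mask`s on the same grid.
#' @param rules A [detection_rules()].
#' @return List with `voxel` ([voxel_metrics()]), `lesion`
#'   ([lesion_metrics()]) and `avg_score`.
#' @export
evaluate_case <- function(pred, gt, rules = detection_rules()) {
  v <- voxel_metrics(voxel_confusion(pred, gt))
  l <- lesion_metrics(pred, gt, rules)
  list(voxel = v, lesion = l, avg_score = avg_score(v, l))
}

#' Evaluate a cohort of predicted/ground-truth mask pairs
#'
#' Cohort means exclude cases with undefined metrics; the number of cases
#' contributing to each mean is reported alongside it.
#'
#' @param pairs List of `list(pred, gt)` mask pairs.
#' @param rules A [detection_rules()].
#' @return List of class `ll_eval_report`: `cases` (per-case results) and
#'   `summary` (means + contributing counts).
#' @export
evaluate_cohort <- function(pairs, rules = detection_rules()) {
  cases <- lapply(pairs, function(p) evaluate_case(p$pred, p$gt, rules))
  pull <- function(f) vapply(cases, f, numeric(1))
  mets <- list(dice = pull(function(cs) cs$voxel$dice),
               ppv = pull(function(cs) cs$voxel$ppv),
               tpr = pull(function(cs) cs$voxel$tpr),
               SL = pull(function(cs) cs$lesion$SL),
               PL = pull(function(cs) cs$lesion$PL),
               les_f1 = pull(function(cs) cs$lesion$les_f1),
               avg_score = pull(function(cs) cs$avg_score))
  summary <- lapply(mets, function(x)
    list(mean = mean(x, na.rm = TRUE), n = sum(!is.na(x))))
  structure(list(cases = cases, summary = summary), class = "ll_eval_report")
}

#' @export
print.ll_eval_report <- function(x, ...) {
  cat(sprintf("<ll_eval_report, %d case(s)>\n", length(x$cases)))
  for (nm in names(x$summary))
    cat(sprintf("  %-10s mean %.4f  (n=%d)\n", nm, x$summary[[nm]]$mean,
                x$summary[[nm]]$n))
  invisible(x)
}
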