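# Independent brute-force oracles used to validate the package's metric and
# component machinery. Deliberately naive implementations.

# Flood-fill connected-component labelling, 26-connectivity, labels assigned
# in ascending order of each component's first (column-major) voxel.
oracle_label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (start in seq_along(mask)) {
    if (mask[start] == 0 || lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- co + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > d)) next
        ni <- nb[1] + d[1] * ((nb[2] - 1) + d[2] * (nb[3] - 1))
        if (mask[ni] != 0 && lab[ni] == 0L) {
          lab[ni] <- nxt
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

# Triple-loop voxel confusion counting.
oracle_voxel_confusion <- function(pred, gt) {
  d <- dim(pred)
  TP <- 0L; FP <- 0L; FN <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    p <- pred[x, y, z] > 0
    g <- gt[x, y, z] > 0
    if (p && g) TP <- TP + 1L
    else if (p && !g) FP <- FP + 1L
    else if (!p && g) FN <- FN + 1L
  }
  list(TP = TP, FP = FP, FN = FN)
}

# Per-component brute-force application of the detection rules.
oracle_lesion_metrics <- function(pred, gt, spacing = c(1, 1, 1),
                                  min_volume = 3, sl_min = 0.10,
                                  pl_min = 0.65, pl_out_max = 0.70) {
  vv <- prod(spacing)
  strip_small <- function(m) {
    lab <- oracle_label_components(m)
    if (max(lab) == 0L) return(m)
    for (i in seq_len(max(lab))) {
      idx <- which(lab == i)
      if (length(idx) * vv < min_volume) m[idx] <- 0
    }
    m
  }
  pred <- strip_small(pred); gt <- strip_small(gt)
  plab <- oracle_label_components(pred)
  glab <- oracle_label_components(gt)
  SL <- NA_real_; PL <- NA_real_
  if (max(glab) > 0L) {
    hits <- 0L
    for (i in seq_len(max(glab))) {
      idx <- which(glab == i)
      if (sum(pred[idx] > 0) / length(idx) >= sl_min) hits <- hits + 1L
    }
    SL <- hits / max(glab)
  }
  if (max(plab) > 0L) {
    hits <- 0L
    for (i in seq_len(max(plab))) {
      idx <- which(plab == i)
      inside <- sum(gt[idx] > 0) / length(idx)
      if (inside >= pl_min && (1 - inside) <= pl_out_max) hits <- hits + 1L
    }
    PL <- hits / max(plab)
  }
  f1 <- if (is.na(SL) || is.na(PL)) NA_real_
        else if (SL + PL == 0) 0 else 2 * SL * PL / (SL + PL)
  list(SL = SL, PL = PL, les_f1 = f1)
}

# Exact two-sided signed-rank p-value by enumeration of all sign patterns
# (ties in |d| not handled; fine for the constructed cases).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Ws <- as.matrix(signs) %*% r
  pm <- mean(Ws >= W)
  pp <- mean(Ws <= W)
  min(1, 2 * min(pm, pp))
}

random_mask_array <- function(d, p = 0.15) {
  array(as.numeric(runif(prod(d)) < p), dim = d)
}

coords_to_index_test <- function(coords, shape)
  coords[, 1] + shape[1] * ((coords[, 2] - 1) + shape[2] * (coords[, 3] - 1))
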