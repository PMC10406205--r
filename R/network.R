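# 3D U-Net building blocks with a hand-rolled reverse-mode tape.
#
# Tensors are R arrays laid out (x, y, z, channel). Each graph node is an
# environment holding the forward value, the accumulated output gradient and
# whatever the backward pass needs. `needs` marks whether any trainable
# parameter lies in the node's subtree; frozen subtrees (the encoder in
# training stages two and three) are skipped entirely during backward.

#' Network architecture specification
#'
#' @param in_channels,out_channels Input/output channel counts.
#' @param levels Encoder depth (number of skip-connection resolutions); the
#'   bottleneck sits one pooling below the last level.
#' @param base_channels Channels at the first level; deeper levels grow by
#'   `growth` per level.
#' @param growth Channel growth factor per level.
#' @param convs_per_block Convolutions (3x3x3 + instance norm + ReLU) per
#'   encoder/decoder block.
#' @param norm Use instance normalization after each convolution.
#' @return A list of class `ll_network_spec`.
#' @export
network_spec <- function(in_channels = 1L, out_channels = 2L, levels = 4L,
                         base_channels = 32L, growth = 2, convs_per_block = 2L,
                         norm = TRUE) {
  if (levels < 2L) stopf("levels must be >= 2")
  if (base_channels < 4L) stopf("base_channels must be >= 4")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 growth = growth, convs_per_block = as.integer(convs_per_block),
                 norm = isTRUE(norm)),
            class = "ll_network_spec")
}

spec_channels <- function(spec, level) {
  as.integer(round(spec$base_channels * spec$growth^level))
}

check_patch_divisible <- function(size, levels) {
  need <- 2L^levels
  if (any(size %% need != 0L) || any(size %/% need < 2L))
    stopf(paste0("patch size %s is not usable with %d levels: each axis must be ",
                 "divisible by 2^levels (= %d) and leave a bottleneck of at ",
                 "least 2 voxels"), paste(size, collapse = "x"), levels, need)
  invisible(TRUE)
}

init_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)), dim = c(k, k, k, cin, cout))
}

# parameter set for one conv(+norm) unit
add_conv_params <- function(params, prefix, k, cin, cout, norm) {
  params[[paste0(prefix, ".w")]] <- init_conv(k, cin, cout)
  params[[paste0(prefix, ".b")]] <- numeric(cout)
  if (norm) {
    params[[paste0(prefix, ".ng")]] <- rep(1, cout)
    params[[paste0(prefix, ".nb")]] <- numeric(cout)
  }
  params
}

encoder_param_layout <- function(spec) {
  layout <- list()
  cin <- spec$in_channels
  for (l in seq_len(spec$levels) - 1L) {
    cl <- spec_channels(spec, l)
    for (i in seq_len(spec$convs_per_block)) {
      layout[[length(layout) + 1L]] <- list(prefix = sprintf("enc.l%d.c%d", l, i),
                                            cin = if (i == 1L) cin else cl, cout = cl)
    }
    cin <- cl
  }
  cb <- spec_channels(spec, spec$levels)
  for (i in seq_len(spec$convs_per_block)) {
    layout[[length(layout) + 1L]] <- list(prefix = sprintf("bott.c%d", i),
                                          cin = if (i == 1L) cin else cb, cout = cb)
  }
  layout
}

decoder_param_layout <- function(spec) {
  layout <- list()
  for (l in rev(seq_len(spec$levels) - 1L)) {
    cl <- spec_channels(spec, l)
    cabove <- spec_channels(spec, l + 1L)
    layout[[length(layout) + 1L]] <- list(prefix = sprintf("dec.l%d.red", l),
                                          cin = cabove, cout = cl)
    for (i in seq_len(spec$convs_per_block)) {
      layout[[length(layout) + 1L]] <- list(prefix = sprintf("dec.l%d.c%d", l, i),
                                            cin = if (i == 1L) 2L * cl else cl, cout = cl)
    }
  }
  layout
}

build_params <- function(spec, include_agg = FALSE) {
  params <- list()
  for (u in encoder_param_layout(spec))
    params <- add_conv_params(params, u$prefix, 3L, u$cin, u$cout, spec$norm)
  if (include_agg) {
    for (l in seq_len(spec$levels) - 1L) {
      cl <- spec_channels(spec, l)
      params <- add_conv_params(params, sprintf("agg.l%d", l), 1L, 2L * cl, cl, FALSE)
    }
    cb <- spec_channels(spec, spec$levels)
    params <- add_conv_params(params, "agg.bott", 1L, 2L * cb, cb, FALSE)
  }
  for (u in decoder_param_layout(spec))
    params <- add_conv_params(params, u$prefix, 3L, u$cin, u$cout, spec$norm)
  # zero-initialized head: the softmax starts unsaturated at p = 0.5, which
  # keeps early dice-loss gradients alive
  params[["head.w"]] <- array(0, dim = c(1, 1, 1, spec$base_channels,
                                         spec$out_channels))
  params[["head.b"]] <- numeric(spec$out_channels)
  params
}

## ---- tape -------------------------------------------------------------

tape_new <- function(params, frozen = character(), keep_cols = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$params <- params
  tp$frozen <- frozen
  tp$keep_cols <- keep_cols
  tp
}

tape_add <- function(tp, node) {
  node$id <- length(tp$nodes) + 1L
  node$grad <- NULL
  tp$nodes[[node$id]] <- node
  node
}

new_node <- function(...) {
  e <- new.env(parent = emptyenv())
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

trainable <- function(tp, pname) !is.null(pname) && !any(startsWith(pname, tp$frozen))

t_input <- function(tp, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  tape_add(tp, new_node(op = "input", out = x, needs = FALSE))
}

# im2col + BLAS GEMM when the unrolled matrix is small enough; direct
# C++ convolution otherwise (memory guard for large volumes).
gemm_budget <- 3e7

conv_fwd <- function(x, w, b, keep_cols = FALSE) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[5]
  nvox <- prod(d[1:3])
  if (nvox * k^3 * d[4] > gemm_budget) {
    out <- conv3d_fwd_cpp(x, d[1], d[2], d[3], d[4], w, k, cout, b)
    return(if (keep_cols) list(out = out, cols = NULL) else list(out = out))
  }
  cols <- if (k == 1L) matrix(x, nvox, d[4])
          else im2col_cpp(x, d[1], d[2], d[3], d[4], k)
  out <- cols %*% matrix(w, k^3 * d[4], cout)
  out <- out + matrix(b, nvox, cout, byrow = TRUE)
  out <- array(out, dim = c(d[1:3], cout))
  if (keep_cols) list(out = out, cols = cols) else list(out = out)
}

conv_bwd <- function(x, w, gout, need_gin, cols = NULL) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[5]
  nvox <- prod(d[1:3])
  if (nvox * k^3 * d[4] > gemm_budget) {
    bw <- conv3d_bwd_cpp(x, d[1], d[2], d[3], d[4], w, k, cout, gout)
    return(list(gw = bw$gw, gb = bw$gb, gin = if (need_gin) bw$gin else NULL))
  }
  gm <- matrix(gout, nvox, cout)
  if (is.null(cols))
    cols <- if (k == 1L) matrix(x, nvox, d[4])
            else im2col_cpp(x, d[1], d[2], d[3], d[4], k)
  gw <- array(crossprod(cols, gm), dim = dim(w))
  gb <- colSums(gm)
  gin <- NULL
  if (need_gin) {
    gcols <- tcrossprod(gm, matrix(w, k^3 * d[4], cout))
    gin <- if (k == 1L) array(gcols, dim = d)
           else col2im_cpp(gcols, d[1], d[2], d[3], d[4], k)
  }
  list(gw = gw, gb = gb, gin = gin)
}

t_conv <- function(tp, inp, prefix, k) {
  wname <- paste0(prefix, ".w"); bname <- paste0(prefix, ".b")
  w <- tp$params[[wname]]; b <- tp$params[[bname]]
  if (is.null(w)) stopf("missing parameter %s", wname)
  keep <- isTRUE(tp$keep_cols) && (trainable(tp, wname) || inp$needs)
  fw <- conv_fwd(inp$out, w, b, keep_cols = keep)
  tape_add(tp, new_node(op = "conv", inp = inp, wname = wname, bname = bname,
                        k = k, out = fw$out, cols = fw$cols,
                        needs = inp$needs || trainable(tp, wname)))
}

t_inorm <- function(tp, inp, prefix, eps = 1e-5) {
  gname <- paste0(prefix, ".ng"); bname <- paste0(prefix, ".nb")
  g <- tp$params[[gname]]; b <- tp$params[[bname]]
  d <- dim(inp$out)
  nvox <- prod(d[1:3])
  m <- matrix(inp$out, nvox, d[4])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  s <- sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, s, `/`)
  out <- array(sweep(sweep(xhat, 2, g, `*`), 2, b, `+`), dim = d)
  tape_add(tp, new_node(op = "inorm", inp = inp, gname = gname, bname = bname,
                        xhat = xhat, s = s, out = out,
                        needs = inp$needs || trainable(tp, gname)))
}

t_relu <- function(tp, inp) {
  out <- inp$out
  out[out < 0] <- 0
  tape_add(tp, new_node(op = "relu", inp = inp, out = out, needs = inp$needs))
}

t_pool <- function(tp, inp) {
  d <- dim(inp$out)
  tape_add(tp, new_node(op = "pool", inp = inp, indim = d,
                        out = avgpool2_fwd_cpp(inp$out, d[1], d[2], d[3], d[4]),
                        needs = inp$needs))
}

t_up <- function(tp, inp) {
  d <- dim(inp$out)
  tape_add(tp, new_node(op = "up", inp = inp, indim = d,
                        out = upsample2_fwd_cpp(inp$out, d[1], d[2], d[3], d[4]),
                        needs = inp$needs))
}

t_concat <- function(tp, a, b) {
  da <- dim(a$out); db <- dim(b$out)
  out <- array(c(a$out, b$out), dim = c(da[1:3], da[4] + db[4]))
  tape_add(tp, new_node(op = "concat", a = a, b = b, ca = da[4], out = out,
                        needs = a$needs || b$needs))
}

t_softmax <- function(tp, inp) {
  d <- dim(inp$out)
  nvox <- prod(d[1:3])
  m <- matrix(inp$out, nvox, d[4])
  rowmax <- m[, 1]
  for (j in seq_len(d[4])[-1]) rowmax <- pmax(rowmax, m[, j])
  m <- m - rowmax
  e <- exp(m)
  y <- e / rowSums(e)
  tape_add(tp, new_node(op = "softmax", inp = inp, y = y,
                        out = array(y, dim = d), needs = inp$needs))
}

accum_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Reverse pass: seeds the output node with `grad_out`, walks nodes in
# reverse creation order, returns gradients by parameter name (trainable
# parameters only).
tape_backward <- function(tp, out_node, grad_out) {
  out_node$grad <- grad_out
  grads <- list()
  addp <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  for (i in rev(seq_along(tp$nodes))) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad)) next
    g <- nd$grad
    switch(nd$op,
      input = NULL,
      conv = {
        want_w <- trainable(tp, nd$wname)
        if (want_w || nd$inp$needs) {
          bw <- conv_bwd(nd$inp$out, tp$params[[nd$wname]], g, nd$inp$needs,
                         cols = nd$cols)
          if (want_w) { addp(nd$wname, bw$gw); addp(nd$bname, bw$gb) }
          if (nd$inp$needs) accum_grad(nd$inp, bw$gin)
        }
      },
      inorm = {
        d <- dim(nd$inp$out)
        nvox <- prod(d[1:3])
        gm <- matrix(g, nvox, d[4])
        gain <- tp$params[[nd$gname]]
        if (trainable(tp, nd$gname)) {
          addp(nd$gname, colSums(gm * nd$xhat))
          addp(nd$bname, colSums(gm))
        }
        if (nd$inp$needs) {
          gy <- sweep(gm, 2, gain, `*`)
          mg <- colMeans(gy)
          mgx <- colMeans(gy * nd$xhat)
          gx <- sweep(gy, 2, mg) - sweep(nd$xhat, 2, mgx, `*`)
          gx <- sweep(gx, 2, nd$s, `/`)
          accum_grad(nd$inp, array(gx, dim = d))
        }
      },
      relu = if (nd$inp$needs) accum_grad(nd$inp, g * (nd$inp$out > 0)),
      pool = if (nd$inp$needs) {
        d <- nd$indim
        accum_grad(nd$inp, avgpool2_bwd_cpp(g, d[1], d[2], d[3], d[4]))
      },
      up = if (nd$inp$needs) {
        d <- nd$indim
        accum_grad(nd$inp, upsample2_bwd_cpp(g, d[1], d[2], d[3], d[4]))
      },
      concat = {
        d <- dim(nd$out)
        if (nd$a$needs)
          accum_grad(nd$a, array(g[, , , seq_len(nd$ca), drop = FALSE],
                                 dim = c(d[1:3], nd$ca)))
        if (nd$b$needs)
          accum_grad(nd$b, array(g[, , , (nd$ca + 1L):d[4], drop = FALSE],
                                 dim = c(d[1:3], d[4] - nd$ca)))
      },
      softmax = if (nd$inp$needs) {
        d <- dim(nd$out)
        nvox <- prod(d[1:3])
        gm <- matrix(g, nvox, d[4])
        dotg <- rowSums(gm * nd$y)
        accum_grad(nd$inp, array(nd$y * (gm - dotg), dim = d))
      })
    if (nd$op != "input") nd$grad <- NULL  # release
  }
  grads
}

## ---- graph pieces ----------------------------------------------------

t_conv_block <- function(tp, h, prefix, n_convs, norm) {
  for (i in seq_len(n_convs)) {
    p <- sprintf("%s.c%d", prefix, i)
    h <- t_conv(tp, h, p, 3L)
    if (norm) h <- t_inorm(tp, h, p)
    h <- t_relu(tp, h)
  }
  h
}

# Encoder: returns list(skips = list of level nodes, bottleneck = node)
t_encoder <- function(tp, x, spec) {
  skips <- vector("list", spec$levels)
  h <- x
  for (l in seq_len(spec$levels) - 1L) {
    h <- t_conv_block(tp, h, sprintf("enc.l%d", l), spec$convs_per_block, spec$norm)
    skips[[l + 1L]] <- h
    h <- t_pool(tp, h)
  }
  bott <- t_conv_block(tp, h, "bott", spec$convs_per_block, spec$norm)
  list(skips = skips, bottleneck = bott)
}

# Decoder consuming (possibly aggregated) skips and bottleneck.
t_decoder <- function(tp, skips, bottleneck, spec) {
  h <- bottleneck
  for (l in rev(seq_len(spec$levels) - 1L)) {
    h <- t_up(tp, h)
    p <- sprintf("dec.l%d.red", l)
    h <- t_conv(tp, h, p, 3L)
    if (spec$norm) h <- t_inorm(tp, h, p)
    h <- t_relu(tp, h)
    h <- t_concat(tp, h, skips[[l + 1L]])
    h <- t_conv_block(tp, h, sprintf("dec.l%d", l), spec$convs_per_block, spec$norm)
  }
  t_conv(tp, h, "head", 1L)
}

t_aggregate_level <- function(tp, prefix, f1, f2) {
  h <- t_concat(tp, f1, f2)
  h <- t_conv(tp, h, prefix, 1L)
  t_relu(tp, h)
}

## ---- network objects -------------------------------------------------

new_network <- function(spec, kind, params, frozen = character()) {
  structure(list(spec = spec, kind = kind, params = params, frozen = frozen),
            class = "ll_network")
}

#' @export
print.ll_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<ll_network %s: %d levels, base %d, %d parameters%s>\n",
              x$kind, x$spec$levels, x$spec$base_channels, np,
              if (length(x$frozen)) paste0(", frozen: ", paste(x$frozen, collapse = "+"))
              else ""))
  invisible(x)
}

#' Build a single-time-point segmentation U-Net
#'
#' Encoder and decoder linked by skip connections; maps a 1-channel patch to
#' a per-voxel 2-class probability map (softmax over channels).
#'
#' @param spec A [network_spec()].
#' @return An `ll_network` of kind `"segmentation"`.
#' @export
build_segmentation_unet <- function(spec) {
  stopifnot(inherits(spec, "ll_network_spec"))
  new_network(spec, "segmentation", build_params(spec))
}

#' Build the siamese-encoder new-lesion network
#'
#' A shared-weights encoder applied to both time-points; same-level feature
#' maps are aggregated (channel concatenation followed by a 1x1x1
#' convolution back to the original channel count) and fed to a single
#' decoder with skip connections from the aggregated maps.
#'
#' @param spec A [network_spec()].
#' @param encoder_from Optional checkpoint or `ll_network` whose encoder
#'   parameters are copied by layer name (an error is raised on any
#'   unmatched encoder layer) and frozen.
#' @return An `ll_network` of kind `"newlesion"`.
#' @export
build_new_lesion_network <- function(spec, encoder_from = NULL) {
  stopifnot(inherits(spec, "ll_network_spec"))
  net <- new_network(spec, "newlesion", build_params(spec, include_agg = TRUE))
  if (!is.null(net)) net$frozen <- character()
  if (!is.null(encoder_from)) {
    src <- if (inherits(encoder_from, "ll_network")) encoder_from$params
           else encoder_from$params
    enc_names <- grep("^(enc\\.|bott\\.)", names(net$params), value = TRUE)
    src_enc <- grep("^(enc\\.|bott\\.)", names(src), value = TRUE)
    missing_in_src <- setdiff(enc_names, src_enc)
    extra_in_src <- setdiff(src_enc, enc_names)
    if (length(missing_in_src) || length(extra_in_src))
      stopf("encoder layer mismatch during transfer: missing [%s], unexpected [%s]",
            paste(missing_in_src, collapse = ","), paste(extra_in_src, collapse = ","))
    for (nm in enc_names) {
      if (!identical(dim(net$params[[nm]]), dim(src[[nm]])) &&
          !identical(length(net$params[[nm]]), length(src[[nm]])))
        stopf("encoder parameter %s has incompatible shape", nm)
      net$params[[nm]] <- src[[nm]]
    }
    net$frozen <- c("enc.", "bott.")
  }
  net
}

#' Build the lesion-inpainting U-Net (1 input channel, regression output)
#' @param spec A [network_spec()]; `out_channels` is forced to 1.
#' @return An `ll_network` of kind `"regression"`.
#' @export
build_inpainting_unet <- function(spec = network_spec(in_channels = 1L)) {
  spec$in_channels <- 1L; spec$out_channels <- 1L
  new_network(spec, "regression", build_params(spec))
}

#' Build the lesion-generator U-Net (2 input channels, regression output)
#' @param spec A [network_spec()]; `in_channels` forced to 2, `out_channels` to 1.
#' @return An `ll_network` of kind `"regression"`.
#' @export
build_generator_unet <- function(spec = network_spec()) {
  spec$in_channels <- 2L; spec$out_channels <- 1L
  new_network(spec, "regression", build_params(spec))
}

as_input_array <- function(x) {
  a <- if (inherits(x, c("ll_volume", "ll_mask"))) x$data else x
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  a
}

#' Forward pass through a network
#'
#' @param net An `ll_network`.
#' @param ... Input arrays or volumes: one patch for `"segmentation"` /
#'   `"regression"` kinds, the two time-point patches for `"newlesion"`.
#' @param with_tape Keep the computation tape (for training); if `FALSE`
#'   only the output array is returned.
#' @return The output array (x, y, z, out_channels), or a list
#'   `(out, tape, out_node)` when `with_tape = TRUE`.
#' @export
network_forward <- function(net, ..., with_tape = FALSE) {
  inputs <- lapply(list(...), as_input_array)
  size <- dim(inputs[[1]])[1:3]
  check_patch_divisible(size, net$spec$levels)
  tp <- tape_new(net$params, net$frozen, keep_cols = with_tape)
  if (net$kind == "newlesion") {
    if (length(inputs) != 2L) stopf("new-lesion network takes two inputs (tp1, tp2)")
    e1 <- t_encoder(tp, t_input(tp, inputs[[1]]), net$spec)
    e2 <- t_encoder(tp, t_input(tp, inputs[[2]]), net$spec)
    skips <- lapply(seq_len(net$spec$levels), function(l)
      t_aggregate_level(tp, sprintf("agg.l%d", l - 1L), e1$skips[[l]], e2$skips[[l]]))
    bott <- t_aggregate_level(tp, "agg.bott", e1$bottleneck, e2$bottleneck)
    out_node <- t_decoder(tp, skips, bott, net$spec)
    out_node <- t_softmax(tp, out_node)
  } else {
    if (length(inputs) != 1L) stopf("%s network takes one input", net$kind)
    if (dim(inputs[[1]])[4] != net$spec$in_channels)
      stopf("expected %d input channel(s), got %d", net$spec$in_channels,
            dim(inputs[[1]])[4])
    enc <- t_encoder(tp, t_input(tp, inputs[[1]]), net$spec)
    out_node <- t_decoder(tp, enc$skips, enc$bottleneck, net$spec)
    if (net$kind == "segmentation") out_node <- t_softmax(tp, out_node)
  }
  if (with_tape) list(out = out_node$out, tape = tp, out_node = out_node)
  else out_node$out
}

#' Encode a patch into the per-level feature-map set
#'
#' Runs the (shared-weights) encoder only.
#'
#' @param net An `ll_network`.
#' @param patch Input array or volume.
#' @return List of class `ll_feature_maps`: `maps` (one array per level,
#'   level `l` has spatial size `input/2^(l-1)`) and `bottleneck`.
#' @export
encode <- function(net, patch) {
  x <- as_input_array(patch)
  check_patch_divisible(dim(x)[1:3], net$spec$levels)
  tp <- tape_new(net$params, "")   # no gradients needed
  enc <- t_encoder(tp, t_input(tp, x), net$spec)
  structure(list(maps = lapply(enc$skips, function(n) n$out),
                 bottleneck = enc$bottleneck$out),
            class = "ll_feature_maps")
}

#' Aggregate two feature-map sets from the shared encoder
#'
#' Per level, the two maps are concatenated by channel (doubling the channel
#' count) and a 1x1x1 convolution maps them back to the original channel
#' count; the concatenation order (tp1, tp2) is fixed.
#'
#' @param net A `"newlesion"` `ll_network` providing the aggregation weights.
#' @param fm1,fm2 `ll_feature_maps` from [encode()].
#' @return An `ll_feature_maps` with the input channel counts.
#' @export
aggregate <- function(net, fm1, fm2) {
  stopifnot(net$kind == "newlesion")
  if (length(fm1$maps) != length(fm2$maps)) stopf("feature-map level mismatch")
  tp <- tape_new(net$params, "")
  one <- function(prefix, a, b) {
    if (!identical(dim(a), dim(b))) stopf("feature-map shape mismatch")
    na <- tape_add(tp, new_node(op = "input", out = a, needs = FALSE))
    nb <- tape_add(tp, new_node(op = "input", out = b, needs = FALSE))
    t_aggregate_level(tp, prefix, na, nb)$out
  }
  structure(list(maps = lapply(seq_along(fm1$maps), function(l)
    one(sprintf("agg.l%d", l - 1L), fm1$maps[[l]], fm2$maps[[l]])),
    bottleneck = one("agg.bott", fm1$bottleneck, fm2$bottleneck)),
    class = "ll_feature_maps")
}
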