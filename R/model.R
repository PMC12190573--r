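#' Inception block configuration
#'
#' Describes one Inception-style block: three parallel convolution towers with
#' kernel sizes 1, 3 and 5 voxels. The 1-cubed tower captures fine detail, the
#' 3-cubed tower medium structure and the 5-cubed tower large structure; the
#' 3- and 5-cubed towers are preceded by 1-cubed bottleneck reductions so the
#' block stays lightweight. Tower outputs are concatenated along channels, so
#' the block emits `c1 + c3 + c5` channels.
#'
#' @param c1,c3,c5 Output channels of the 1-, 3- and 5-cubed towers.
#' @param reduce3,reduce5 Channels of the 1-cubed bottlenecks feeding the 3-
#'   and 5-cubed convolutions.
#' @return An object of class `inception_block_config`.
#' @examples
#' cfg <- inception_block_config(c1 = 8, c3 = 16, c5 = 8,
#'                               reduce3 = 8, reduce5 = 8)
#' cfg$out_channels # 32
#' @export
inception_block_config <- function(c1, c3, c5, reduce3, reduce5) {
  vals <- c(c1 = c1, c3 = c3, c5 = c5, reduce3 = reduce3, reduce5 = reduce5)
  if (any(vals < 1) || any(vals != round(vals)))
    stop("inception_block_config: all channel counts must be positive integers")
  structure(list(c1 = as.integer(c1), c3 = as.integer(c3), c5 = as.integer(c5),
                 reduce3 = as.integer(reduce3), reduce5 = as.integer(reduce5),
                 out_channels = as.integer(c1 + c3 + c5)),
            class = "inception_block_config")
}

# Default tower split of a block width f: one quarter to the 1-cubed tower,
# one half to the 3-cubed tower, one quarter to the 5-cubed tower, and
# quarter-width bottlenecks before the 3/5 towers.
#' @noRd
.inception_split <- function(f) {
  c1 <- max(1L, as.integer(round(f / 4)))
  c5 <- c1
  c3 <- as.integer(f) - c1 - c5
  if (c3 < 1L) stop("block width too small to split across towers: ", f)
  r <- max(1L, as.integer(round(f / 4)))
  inception_block_config(c1 = c1, c3 = c3, c5 = c5, reduce3 = r, reduce5 = r)
}

#' LIU-Net architecture configuration
#'
#' Five-level 3D encoder-decoder with one Inception block per level,
#' 2x2x2 max-pooling between encoder levels, and a decoder that mirrors the
#' encoder: nearest-neighbour x2 upsampling followed by a 1-cubed
#' channel-adjust convolution, concatenation with the matching encoder skip,
#' and another Inception block. The head is a 1-cubed convolution to
#' `n_classes` with a per-voxel softmax.
#'
#' The default channel schedule (32, 64, 128, 256, 320) keeps the network in
#' the low millions of parameters; every width is configurable. Valid input
#' spatial shapes are multiples of `2^(depth-1)` = 16.
#'
#' @param widths Block output channels per encoder level (length = depth).
#' @param in_channels Input channels (4 MRI modalities).
#' @param n_classes Output classes (background, necrotic/non-enhancing core,
#'   edema, enhancing tumor).
#' @param level_blocks Optional list of [inception_block_config()] objects,
#'   one per level; derived from `widths` by the default quarter/half/quarter
#'   tower split when `NULL`.
#' @param upsample Decoder upsampling mode; `"nearest_conv"` (nearest
#'   neighbour + 1-cubed convolution) is the default.
#' @return An object of class `liunet_arch`.
#' @examples
#' arch <- liunet_arch()
#' arch$depth
#' @export
liunet_arch <- function(widths = c(32, 64, 128, 256, 320),
                        in_channels = 4L, n_classes = 4L,
                        level_blocks = NULL,
                        upsample = c("nearest_conv", "transposed")) {
  upsample <- match.arg(upsample)
  depth <- length(widths)
  if (depth < 2L) stop("liunet_arch: depth must be at least 2")
  if (is.null(level_blocks)) {
    level_blocks <- lapply(widths, .inception_split)
  }
  if (length(level_blocks) != depth)
    stop("liunet_arch: length(level_blocks) must equal length(widths)")
  widths <- vapply(level_blocks, `[[`, integer(1), "out_channels")
  structure(list(depth = as.integer(depth), widths = as.integer(widths),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 level_blocks = level_blocks, upsample = upsample),
            class = "liunet_arch")
}

# ---- parameter construction ------------------------------------------------

#' @noRd
.init_block_params <- function(cfg, c_in) {
  list(
    a_W = nn_init_conv(1L, c_in, cfg$c1), a_bn = nn_init_bn(cfg$c1),
    b_W1 = nn_init_conv(1L, c_in, cfg$reduce3), b_bn1 = nn_init_bn(cfg$reduce3),
    b_W2 = nn_init_conv(3L, cfg$reduce3, cfg$c3), b_bn2 = nn_init_bn(cfg$c3),
    c_W1 = nn_init_conv(1L, c_in, cfg$reduce5), c_bn1 = nn_init_bn(cfg$reduce5),
    c_W2 = nn_init_conv(5L, cfg$reduce5, cfg$c5), c_bn2 = nn_init_bn(cfg$c5)
  )
}

#' @noRd
.init_block_stats <- function(cfg) {
  list(a = nn_init_bn_stats(cfg$c1),
       b1 = nn_init_bn_stats(cfg$reduce3), b2 = nn_init_bn_stats(cfg$c3),
       c1 = nn_init_bn_stats(cfg$reduce5), c2 = nn_init_bn_stats(cfg$c5))
}

# Encoder/decoder input channel bookkeeping shared by the builder, the
# analytic parameter count and the FLOP estimate.
#' @noRd
.arch_plan <- function(arch) {
  d <- arch$depth
  enc_in <- c(arch$in_channels, arch$widths[-d])
  dec_levels <- rev(seq_len(d - 1L)) # built in order d-1, ..., 1
  up_in <- integer(d - 1L)
  up_out <- integer(d - 1L)
  dec_in <- integer(d - 1L)
  prev <- arch$widths[d]
  for (l in dec_levels) {
    up_in[l] <- prev
    up_out[l] <- arch$widths[l]
    dec_in[l] <- arch$widths[l] + arch$widths[l] # channel-adjusted up + skip
    prev <- arch$widths[l]
  }
  list(enc_in = enc_in, up_in = up_in, up_out = up_out, dec_in = dec_in,
       dec_levels = dec_levels)
}

#' Build an untrained LIU-Net
#'
#' Instantiates network weights (He-normal initialisation, drawn from R's
#' RNG; seed it with [set.seed()] for reproducibility) for the given
#' architecture.
#'
#' @param arch A [liunet_arch()] configuration.
#' @return A list with elements `arch`, `params` (trainable arrays) and
#'   `stats` (batch-norm running statistics), of class `liunet_net`.
#' @export
build_liunet <- function(arch = liunet_arch()) {
  stopifnot(inherits(arch, "liunet_arch"))
  plan <- .arch_plan(arch)
  d <- arch$depth
  params <- list(
    enc = lapply(seq_len(d), function(l)
      .init_block_params(arch$level_blocks[[l]], plan$enc_in[l])),
    up = lapply(seq_len(d - 1L), function(l) {
      k <- if (arch$upsample == "transposed") 2L else 1L
      list(W = nn_init_conv(k, plan$up_in[l], plan$up_out[l]),
           bn = nn_init_bn(plan$up_out[l]))
    }),
    dec = lapply(seq_len(d - 1L), function(l)
      .init_block_params(arch$level_blocks[[l]], plan$dec_in[l])),
    head = list(W = nn_init_conv(1L, arch$widths[1L], arch$n_classes),
                b = rep(0, arch$n_classes))
  )
  stats <- list(
    enc = lapply(arch$level_blocks, .init_block_stats),
    up = lapply(seq_len(d - 1L), function(l) nn_init_bn_stats(plan$up_out[l])),
    dec = lapply(seq_len(d - 1L), function(l)
      .init_block_stats(arch$level_blocks[[l]]))
  )
  structure(list(arch = arch, params = params, stats = stats),
            class = "liunet_net")
}

# ---- forward / backward ----------------------------------------------------

#' @noRd
.inc_fwd <- function(x, prm, rs, dims, B, train, keep) {
  a1 <- nn_conv_fwd(x, prm$a_W, dims, B, 1L)$y
  abn <- nn_bn_fwd(a1, prm$a_bn, rs$a, train); rs$a <- abn$rs
  ay <- nn_relu(abn$y)

  b1 <- nn_conv_fwd(x, prm$b_W1, dims, B, 1L)$y
  bbn1 <- nn_bn_fwd(b1, prm$b_bn1, rs$b1, train); rs$b1 <- bbn1$rs
  br <- nn_relu(bbn1$y)
  b2 <- nn_conv_fwd(br, prm$b_W2, dims, B, 3L)$y
  bbn2 <- nn_bn_fwd(b2, prm$b_bn2, rs$b2, train); rs$b2 <- bbn2$rs
  by <- nn_relu(bbn2$y)

  c1 <- nn_conv_fwd(x, prm$c_W1, dims, B, 1L)$y
  cbn1 <- nn_bn_fwd(c1, prm$c_bn1, rs$c1, train); rs$c1 <- cbn1$rs
  cr <- nn_relu(cbn1$y)
  c2 <- nn_conv_fwd(cr, prm$c_W2, dims, B, 5L)$y
  cbn2 <- nn_bn_fwd(c2, prm$c_bn2, rs$c2, train); rs$c2 <- cbn2$rs
  cy <- nn_relu(cbn2$y)

  y <- cbind(ay, by, cy)
  cache <- NULL
  if (keep) {
    cache <- list(x = x, ay = ay, br = br, by = by, cr = cr, cy = cy,
                  a_bn = abn$cache, b_bn1 = bbn1$cache, b_bn2 = bbn2$cache,
                  c_bn1 = cbn1$cache, c_bn2 = cbn2$cache)
  }
  list(y = y, rs = rs, cache = cache)
}

#' @noRd
.inc_bwd <- function(dy, prm, cache, dims, B) {
  nc1 <- ncol(cache$ay); nc3 <- ncol(cache$by); nc5 <- ncol(cache$cy)
  dya <- dy[, seq_len(nc1), drop = FALSE]
  dyb <- dy[, nc1 + seq_len(nc3), drop = FALSE]
  dyc <- dy[, nc1 + nc3 + seq_len(nc5), drop = FALSE]
  x <- cache$x

  da <- nn_bn_bwd(nn_relu_bwd(dya, cache$ay), prm$a_bn, cache$a_bn)
  ca <- nn_conv_bwd(da$dx, x, prm$a_W, dims, B, 1L)

  db2 <- nn_bn_bwd(nn_relu_bwd(dyb, cache$by), prm$b_bn2, cache$b_bn2)
  cb2 <- nn_conv_bwd(db2$dx, cache$br, prm$b_W2, dims, B, 3L)
  db1 <- nn_bn_bwd(nn_relu_bwd(cb2$dx, cache$br), prm$b_bn1, cache$b_bn1)
  cb1 <- nn_conv_bwd(db1$dx, x, prm$b_W1, dims, B, 1L)

  dc2 <- nn_bn_bwd(nn_relu_bwd(dyc, cache$cy), prm$c_bn2, cache$c_bn2)
  cc2 <- nn_conv_bwd(dc2$dx, cache$cr, prm$c_W2, dims, B, 5L)
  dc1 <- nn_bn_bwd(nn_relu_bwd(cc2$dx, cache$cr), prm$c_bn1, cache$c_bn1)
  cc1 <- nn_conv_bwd(dc1$dx, x, prm$c_W1, dims, B, 1L)

  grads <- list(
    a_W = ca$dW, a_bn = list(gamma = da$dgamma, beta = da$dbeta),
    b_W1 = cb1$dW, b_bn1 = list(gamma = db1$dgamma, beta = db1$dbeta),
    b_W2 = cb2$dW, b_bn2 = list(gamma = db2$dgamma, beta = db2$dbeta),
    c_W1 = cc1$dW, c_bn1 = list(gamma = dc1$dgamma, beta = dc1$dbeta),
    c_W2 = cc2$dW, c_bn2 = list(gamma = dc2$dgamma, beta = dc2$dbeta)
  )
  list(dx = ca$dx + cb1$dx + cc1$dx, grads = grads)
}

#' @noRd
.check_spatial <- function(arch, dims) {
  div <- 2^(arch$depth - 1L)
  if (any(dims %% div != 0L))
    stop("input spatial shape (", paste(dims, collapse = "x"),
         ") must be divisible by ", div)
}

# Full forward pass. `x` is a (B*N) x in_channels matrix, `dims` the per-sample
# spatial shape. Returns softmax probabilities; with keep = TRUE also every
# intermediate needed by liunet_backward. Running BN stats are updated when
# train = TRUE, and the updated net is returned.
#' @noRd
liunet_forward <- function(net, x, dims, B = 1L, train = FALSE, keep = FALSE) {
  arch <- net$arch
  .check_spatial(arch, dims)
  d <- arch$depth
  prm <- net$params; rs <- net$stats
  enc_out <- vector("list", d)
  pool_idx <- vector("list", d - 1L)
  dims_l <- vector("list", d)
  cache_enc <- vector("list", d)
  cur <- x; curdims <- as.integer(dims)
  for (l in seq_len(d)) {
    dims_l[[l]] <- curdims
    fw <- .inc_fwd(cur, prm$enc[[l]], rs$enc[[l]], curdims, B, train, keep)
    rs$enc[[l]] <- fw$rs
    enc_out[[l]] <- fw$y
    cache_enc[[l]] <- fw$cache
    if (l < d) {
      mp <- maxpool3d_fwd(fw$y, curdims, as.integer(B))
      cur <- mp$y
      pool_idx[[l]] <- if (keep) mp$idx else NULL
      curdims <- curdims %/% 2L
    }
  }
  cache_up <- vector("list", d - 1L)
  cache_dec <- vector("list", d - 1L)
  cur <- enc_out[[d]]
  for (l in rev(seq_len(d - 1L))) {
    uc <- nn_upconv_fwd(cur, prm$up[[l]]$W, dims_l[[l + 1L]], B, arch$upsample)
    ubn <- nn_bn_fwd(uc$y, prm$up[[l]]$bn, rs$up[[l]], train)
    rs$up[[l]] <- ubn$rs
    uy <- nn_relu(ubn$y)
    cat_ <- cbind(uy, enc_out[[l]])
    fw <- .inc_fwd(cat_, prm$dec[[l]], rs$dec[[l]], dims_l[[l]], B, train, keep)
    rs$dec[[l]] <- fw$rs
    if (keep) {
      cache_up[[l]] <- list(conv = uc$cache, uy = uy, bn = ubn$cache)
      cache_dec[[l]] <- fw$cache
    }
    cur <- fw$y
  }
  logits <- sweep(cur %*% prm$head$W, 2L, prm$head$b, "+")
  probs <- nn_softmax(logits)
  cache <- NULL
  if (keep) {
    cache <- list(enc = cache_enc, dec = cache_dec, up = cache_up,
                  pool_idx = pool_idx, dims_l = dims_l,
                  d1 = cur, B = B)
  }
  net$stats <- rs
  list(net = net, probs = probs, logits = logits, cache = cache)
}

# Backward pass from d(loss)/d(logits). Returns a gradient tree mirroring
# net$params.
#' @noRd
liunet_backward <- function(net, dlogits, cache) {
  arch <- net$arch; prm <- net$params
  d <- arch$depth; B <- cache$B
  g_head <- list(W = crossprod(cache$d1, dlogits), b = colSums(dlogits))
  dcur <- dlogits %*% t(prm$head$W)
  g_up <- vector("list", d - 1L)
  g_dec <- vector("list", d - 1L)
  dskip <- vector("list", d)
  for (l in seq_len(d - 1L)) {
    bw <- .inc_bwd(dcur, prm$dec[[l]], cache$dec[[l]], cache$dims_l[[l]], B)
    g_dec[[l]] <- bw$grads
    ucols <- ncol(cache$up[[l]]$uy)
    duy <- bw$dx[, seq_len(ucols), drop = FALSE]
    dskip[[l]] <- bw$dx[, ucols + seq_len(ncol(bw$dx) - ucols), drop = FALSE]
    dbn <- nn_bn_bwd(nn_relu_bwd(duy, cache$up[[l]]$uy),
                     prm$up[[l]]$bn, cache$up[[l]]$bn)
    ubw <- nn_upconv_bwd(dbn$dx, prm$up[[l]]$W, cache$up[[l]]$conv)
    g_up[[l]] <- list(W = ubw$dW,
                      bn = list(gamma = dbn$dgamma, beta = dbn$dbeta))
    dcur <- ubw$dx
  }
  g_enc <- vector("list", d)
  de <- dcur # gradient w.r.t. enc_out[[d]]
  for (l in rev(seq_len(d))) {
    bw <- .inc_bwd(de, prm$enc[[l]], cache$enc[[l]], cache$dims_l[[l]], B)
    g_enc[[l]] <- bw$grads
    if (l > 1L) {
      dpooled <- maxpool3d_bwd(bw$dx, cache$pool_idx[[l - 1L]],
                               nrow(cache$enc[[l - 1L]]$ay))
      de <- dpooled + dskip[[l - 1L]]
    }
  }
  list(enc = g_enc, up = g_up, dec = g_dec, head = g_head)
}

# ---- accounting ------------------------------------------------------------

#' Count trainable parameters of a built network
#'
#' Walks the actual weight arrays and sums their lengths (convolution kernels,
#' batch-norm gains/shifts, head bias). Batch-norm running statistics are not
#' trainable and are excluded.
#'
#' @param net A `liunet_net` from [build_liunet()], or a fitted `liunet`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  params <- if (inherits(net, "liunet")) net$net$params else net$params
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else total <<- total + length(x)
    invisible(NULL)
  }
  walk(params)
  as.integer(total)
}

# Independent analytic layer-walk count from the configuration alone; used as
# the oracle against count_parameters(). Bias-free convs carry k^3*Cin*Cout
# weights plus 2 batch-norm parameters per output channel; the head adds its
# bias.
#' @rdname count_parameters
#' @param arch A [liunet_arch()] configuration.
#' @export
analytic_parameter_count <- function(arch) {
  stopifnot(inherits(arch, "liunet_arch"))
  plan <- .arch_plan(arch)
  block_count <- function(cfg, c_in) {
    c_in * cfg$c1 + 2 * cfg$c1 +
      c_in * cfg$reduce3 + 2 * cfg$reduce3 +
      27 * cfg$reduce3 * cfg$c3 + 2 * cfg$c3 +
      c_in * cfg$reduce5 + 2 * cfg$reduce5 +
      125 * cfg$reduce5 * cfg$c5 + 2 * cfg$c5
  }
  d <- arch$depth
  total <- 0
  for (l in seq_len(d))
    total <- total + block_count(arch$level_blocks[[l]], plan$enc_in[l])
  kup <- if (arch$upsample == "transposed") 8 else 1
  for (l in seq_len(d - 1L)) {
    total <- total + kup * plan$up_in[l] * plan$up_out[l] + 2 * plan$up_out[l]
    total <- total + block_count(arch$level_blocks[[l]], plan$dec_in[l])
  }
  total <- total + arch$widths[1L] * arch$n_classes + arch$n_classes
  as.integer(total)
}

#' Estimate forward-pass FLOPs
#'
#' Analytic multiply-accumulate count times two, summed over all convolution
#' layers at the given input shape (the standard dense-conv convention;
#' batch-norm, ReLU, pooling and softmax are negligible and excluded). The
#' figure is convention-dependent and meant for order-of-magnitude
#' comparisons, not as an exact benchmark.
#'
#' @param arch A [liunet_arch()] configuration.
#' @param input_shape Spatial input shape, e.g. `c(128, 128, 128)`.
#' @return FLOPs in units of 1e9 (GFLOPs).
#' @export
estimate_flops <- function(arch, input_shape = c(128, 128, 128)) {
  stopifnot(inherits(arch, "liunet_arch"))
  .check_spatial(arch, input_shape)
  plan <- .arch_plan(arch)
  conv_flops <- function(k, c_in, c_out, n_vox) 2 * k^3 * c_in * c_out * n_vox
  block_flops <- function(cfg, c_in, n_vox) {
    conv_flops(1, c_in, cfg$c1, n_vox) +
      conv_flops(1, c_in, cfg$reduce3, n_vox) +
      conv_flops(3, cfg$reduce3, cfg$c3, n_vox) +
      conv_flops(1, c_in, cfg$reduce5, n_vox) +
      conv_flops(5, cfg$reduce5, cfg$c5, n_vox)
  }
  d <- arch$depth
  nvox <- vapply(seq_len(d), function(l) prod(input_shape %/% 2^(l - 1L)),
                 numeric(1))
  total <- 0
  for (l in seq_len(d))
    total <- total + block_flops(arch$level_blocks[[l]], plan$enc_in[l], nvox[l])
  # both upsampling modes cost C_in*C_out MACs per fine-level voxel
  for (l in seq_len(d - 1L)) {
    total <- total + conv_flops(1, plan$up_in[l], plan$up_out[l], nvox[l])
    total <- total + block_flops(arch$level_blocks[[l]], plan$dec_in[l], nvox[l])
  }
  total <- total + conv_flops(1, arch$widths[1L], arch$n_classes, nvox[1L])
  total / 1e9
}

#' Architecture summary
#'
#' @param arch A [liunet_arch()] configuration.
#' @param input_shape Spatial input shape used for the FLOP estimate and the
#'   reported output shape.
#' @return A list with `param_count`, `param_millions`, `approx_gflops` and
#'   `output_shape`, of class `liunet_summary`.
#' @export
summarize_liunet <- function(arch = liunet_arch(),
                             input_shape = c(128, 128, 128)) {
  n <- analytic_parameter_count(arch)
  structure(list(param_count = n, param_millions = n / 1e6,
                 approx_gflops = estimate_flops(arch, input_shape),
                 output_shape = c(input_shape, arch$n_classes)),
            class = "liunet_summary")
}

#' @export
print.liunet_summary <- function(x, ...) {
  cat("LIU-Net model summary\n")
  cat(sprintf("  trainable parameters: %d (%.3f M)\n",
              x$param_count, x$param_millions))
  cat(sprintf("  approx. forward FLOPs: %.2f G at input %s\n",
              x$approx_gflops, paste(x$output_shape[1:3], collapse = "x")))
  cat(sprintf("  output shape: %s (per-voxel softmax)\n",
              paste(x$output_shape, collapse = "x")))
  invisible(x)
}
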