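# Internal neural-network primitives.
#
# Every feature map is a (B*N) x C numeric matrix: B samples stacked row-wise,
# N = prod(dims) voxels per sample in R's column-major array order, one column
# per channel. Convolutions are "same"-padded and bias-free (batch norm
# supplies the shift); the segmentation head is the only biased convolution.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# The k > 1 convolutions run their GEMMs in single precision by default
# (~1e-7 relative rounding, far below training noise); option
# `liunet.conv.double = TRUE` switches to full double precision, which the
# finite-difference gradient oracle requires.
#' @noRd
nn_conv_fwd <- function(x, W, dims, B, k) {
  if (k == 1L) return(list(y = x %*% W))
  list(y = conv3d_fwd(x, W, as.integer(dims), as.integer(k), as.integer(B),
                      use_double = isTRUE(getOption("liunet.conv.double"))))
}

#' @noRd
nn_conv_bwd <- function(dy, x, W, dims, B, k) {
  if (k == 1L) {
    return(list(dx = dy %*% t(W), dW = crossprod(x, dy)))
  }
  conv3d_bwd(dy, x, W, as.integer(dims), as.integer(k), as.integer(B),
             need_dx = TRUE,
             use_double = isTRUE(getOption("liunet.conv.double")))
}

# Batch normalization over all voxels of the batch, per channel.
# `prm` holds trainable gamma/beta; `rs` the running mean/var (not trained).
#' @noRd
nn_bn_fwd <- function(x, prm, rs, train) {
  if (train) {
    mom <- col_moments(x)
    mu <- mom$mean; v <- mom$var
    rs$mean <- (1 - .bn_momentum) * rs$mean + .bn_momentum * mu
    rs$var <- (1 - .bn_momentum) * rs$var + .bn_momentum * v
  } else {
    mu <- rs$mean; v <- rs$var
  }
  invstd <- 1 / sqrt(v + .bn_eps)
  xhat <- col_affine(x, invstd, -mu * invstd)
  y <- col_affine(xhat, prm$gamma, prm$beta)
  list(y = y, rs = rs, cache = list(xhat = xhat, invstd = invstd))
}

#' @noRd
nn_bn_bwd <- function(dy, prm, cache) {
  xhat <- cache$xhat
  dxhat <- col_affine(dy, prm$gamma, numeric(ncol(dy)))
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- bn_backward_x(dxhat, xhat, m1, m2, cache$invstd)
  list(dx = dx,
       dgamma = colSums(dy * xhat),
       dbeta = colSums(dy))
}

#' @noRd
nn_relu <- function(x) relu_fwd(x)

#' @noRd
nn_relu_bwd <- function(dy, y) relu_bwd_c(dy, y)

# Nearest-neighbour x2 upsampling as a row-index gather; the backward pass is
# a rowsum over the same index (each coarse voxel receives the sum of its 8
# children's gradients).
#' @noRd
nn_upsample_map <- function(dims, B) {
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  N <- D * H * W
  d <- rep(seq_len(2 * D), times = 2 * H * 2 * W)
  h <- rep(rep(seq_len(2 * H), each = 2 * D), times = 2 * W)
  w <- rep(seq_len(2 * W), each = 2 * D * 2 * H)
  src <- ((d + 1L) %/% 2L) + D * (((h + 1L) %/% 2L) - 1L) +
    D * H * (((w + 1L) %/% 2L) - 1L)
  if (B > 1L) {
    src <- rep(src, times = B) + rep((seq_len(B) - 1L) * N, each = 8L * N)
  }
  src
}

#' @noRd
nn_upsample_fwd <- function(x, map) {
  x[map, , drop = FALSE]
}

#' @noRd
nn_upsample_bwd <- function(dy, map, nrow_in) {
  out <- rowsum(dy, group = map, reorder = TRUE)
  # every source row appears in `map`, so rowsum yields all nrow_in rows in order
  stopifnot(nrow(out) == nrow_in)
  out
}

# Index sets for a stride-2, kernel-2 transposed convolution: offset o
# (od,oh,ow in 0:1) maps input voxel (d,h,w) to output voxel (2d-1+od, ...).
# Returns 8 row-index vectors into the upsampled map, each aligned with the
# input rows.
#' @noRd
nn_transposed_maps <- function(dims, B) {
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  N <- D * H * W
  d <- rep(seq_len(D), times = H * W)
  h <- rep(rep(seq_len(H), each = D), times = W)
  w <- rep(seq_len(W), each = D * H)
  maps <- vector("list", 8L)
  i <- 1L
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1) {
    idx <- (2L * d - 1L + od) + 2L * D * ((2L * h - 2L + oh)) +
      4L * D * H * ((2L * w - 2L + ow))
    if (B > 1L)
      idx <- rep(idx, times = B) + rep((seq_len(B) - 1L) * 8L * N, each = N)
    maps[[i]] <- idx
    i <- i + 1L
  }
  maps
}

# Upsampling + channel adjustment, both decoder modes. W is ((k^3)*C_in) x
# C_out with k = 1 (nearest_conv: nearest x2 then 1-cubed conv) or k = 2
# (transposed: stride-2 kernel-2 transposed convolution).
#' @noRd
nn_upconv_fwd <- function(x, W, dims, B, mode) {
  if (mode == "nearest_conv") {
    map <- nn_upsample_map(dims, B)
    up <- nn_upsample_fwd(x, map)
    return(list(y = up %*% W, cache = list(mode = mode, map = map, up = up,
                                           n_in = nrow(x))))
  }
  c_in <- ncol(x)
  maps <- nn_transposed_maps(dims, B)
  y <- matrix(0, nrow(x) * 8L, ncol(W))
  for (o in seq_len(8L)) {
    Wo <- W[(o - 1L) * c_in + seq_len(c_in), , drop = FALSE]
    y[maps[[o]], ] <- x %*% Wo
  }
  list(y = y, cache = list(mode = mode, maps = maps, x = x, n_in = nrow(x)))
}

#' @noRd
nn_upconv_bwd <- function(dy, W, cache) {
  if (cache$mode == "nearest_conv") {
    dW <- crossprod(cache$up, dy)
    dup <- dy %*% t(W)
    return(list(dx = nn_upsample_bwd(dup, cache$map, cache$n_in), dW = dW))
  }
  x <- cache$x
  c_in <- ncol(x)
  dW <- matrix(0, nrow(W), ncol(W))
  dx <- matrix(0, nrow(x), c_in)
  for (o in seq_len(8L)) {
    rows <- (o - 1L) * c_in + seq_len(c_in)
    dyo <- dy[cache$maps[[o]], , drop = FALSE]
    dW[rows, ] <- crossprod(x, dyo)
    dx <- dx + dyo %*% t(W[rows, , drop = FALSE])
  }
  list(dx = dx, dW = dW)
}

#' @noRd
nn_softmax <- function(z) softmax_rows(z)

# He-normal initialisation for a convolution stored as (k^3 * C_in) x C_out.
#' @noRd
nn_init_conv <- function(k, c_in, c_out) {
  fan_in <- k^3 * c_in
  matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
         nrow = fan_in, ncol = c_out)
}

#' @noRd
nn_init_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out))
}

#' @noRd
nn_init_bn_stats <- function(c_out) {
  list(mean = rep(0, c_out), var = rep(1, c_out))
}

# Adam over an arbitrarily nested list of numeric parameter arrays. The
# moment trees mirror the parameter tree; `step` is the 1-based step count.
#' @noRd
adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), step = 0L)
}

#' @noRd
adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, step = t))
}
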