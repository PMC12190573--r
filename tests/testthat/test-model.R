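# Architecture: Inception blocks, U-Net assembly, parameter/FLOP accounting.

test_that("inception block concatenates towers and preserves spatial shape", {
  cfg <- inception_block_config(c1 = 8, c3 = 16, c5 = 8,
                                reduce3 = 8, reduce5 = 8)
  expect_identical(cfg$out_channels, 32L)
  arch <- liunet_arch(widths = c(32, 48), level_blocks = list(
    cfg, liunet:::.inception_split(48)))
  set.seed(20)
  net <- build_liunet(arch)
  dims <- c(16L, 16L, 16L)
  x <- matrix(stats::rnorm(prod(dims) * 4), ncol = 4)
  fw <- liunet:::.inc_fwd(x, net$params$enc[[1L]], net$stats$enc[[1L]],
                          dims, 1L, train = TRUE, keep = FALSE)
  expect_identical(ncol(fw$y), 32L)
  expect_identical(nrow(fw$y), as.integer(prod(dims))) # same-padding
  expect_error(inception_block_config(0, 1, 1, 1, 1), "positive")
})

test_that("block parameter count matches the hand-derived layer-walk", {
  # c1=4, reduce3=4, c3=8, reduce5=2, c5=4 at in_channels=4, bias-free convs,
  # BN contributes 2 scalars per channel:
  #  1-cubed tower: 4*4 + 8 = 24
  #  3-cubed tower: 4*4 + 8 + 27*4*8 + 16 = 904
  #  5-cubed tower: 4*2 + 4 + 125*2*4 + 8 = 1020
  cfg <- inception_block_config(c1 = 4, c3 = 8, c5 = 4,
                                reduce3 = 4, reduce5 = 2)
  prm <- liunet:::.init_block_params(cfg, 4L)
  count <- length(rapply(prm, identity, how = "unlist"))
  expect_identical(count, 1948L)
})

test_that("single bias-free 1-cubed conv with BN counts 24 parameters", {
  W <- liunet:::nn_init_conv(1L, 4L, 4L)
  bn <- liunet:::nn_init_bn(4L)
  expect_identical(length(W) + length(bn$gamma) + length(bn$beta), 24L)
})

test_that("framework count equals the analytic oracle on randomized configs", {
  set.seed(21)
  for (rep in 1:10) {
    widths <- sort(sample(8:40, 3)) * 4L
    arch <- liunet_arch(widths = widths,
                        in_channels = sample(1:4, 1),
                        n_classes = sample(2:5, 1),
                        upsample = sample(c("nearest_conv", "transposed"), 1))
    net <- build_liunet(arch)
    expect_identical(count_parameters(net), analytic_parameter_count(arch))
  }
})

test_that("the default network is lighter than the 19.06 M baseline", {
  arch <- liunet_arch()
  expect_identical(arch$depth, 5L)
  n <- analytic_parameter_count(arch)
  net <- build_liunet(arch)
  expect_identical(count_parameters(net), n)
  expect_lt(n / 1e6, 19.06)
})

test_that("parameter count is independent of the input size", {
  arch <- tiny_arch()
  set.seed(22)
  net <- build_liunet(arch)
  n0 <- count_parameters(net)
  for (dims in list(c(16, 16, 16), c(32, 32, 32))) {
    x <- matrix(stats::rnorm(prod(dims) * 4), ncol = 4)
    fw <- liunet:::liunet_forward(net, x, dims, train = TRUE, keep = FALSE)
    expect_identical(count_parameters(fw$net), n0)
  }
})

test_that("softmax head sums to one and the output shape mirrors the input", {
  arch <- tiny_arch()
  set.seed(23)
  net <- build_liunet(arch)
  for (dims in list(c(16L, 16L, 16L), c(32L, 16L, 16L))) {
    x <- matrix(stats::rnorm(prod(dims) * 4), ncol = 4)
    fw <- liunet:::liunet_forward(net, x, dims, train = FALSE)
    expect_identical(dim(fw$probs), c(as.integer(prod(dims)), 4L))
    expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-5)
    expect_true(all(fw$probs >= 0))
  }
})

test_that("transposed-convolution upsampling runs forward and backward", {
  arch <- tiny_arch(upsample = "transposed")
  set.seed(28)
  net <- build_liunet(arch)
  dims <- c(16L, 16L, 16L)
  x <- matrix(stats::rnorm(prod(dims) * 4), ncol = 4)
  fw <- liunet:::liunet_forward(net, x, dims, train = TRUE, keep = TRUE)
  expect_identical(dim(fw$probs), c(as.integer(prod(dims)), 4L))
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-5)
  G <- random_onehot(prod(dims), seed = 29L)
  cfg <- loss_config("combined")
  lg <- liunet:::loss_and_grad(fw$probs, G, cfg)
  gr <- liunet:::liunet_backward(fw$net, lg$dlogits, fw$cache)
  expect_identical(dim(gr$up[[1]]$W), dim(net$params$up[[1]]$W))
  expect_true(all(vapply(gr$up, function(g) all(is.finite(g$W)), logical(1))))
  # gradient of the transposed-conv weights against finite differences
  withr::local_options(liunet.conv.double = TRUE)
  fw <- liunet:::liunet_forward(net, x, dims, train = TRUE, keep = TRUE)
  lg <- liunet:::loss_and_grad(fw$probs, G, cfg)
  gr <- liunet:::liunet_backward(fw$net, lg$dlogits, fw$cache)
  eps <- 1e-5
  for (i in c(2L, 17L)) {
    nt <- fw$net
    v0 <- nt$params$up[[2]]$W[i]
    nt$params$up[[2]]$W[i] <- v0 + eps
    lp <- liunet:::loss_and_grad(
      liunet:::liunet_forward(nt, x, dims, train = TRUE)$probs, G, cfg)$loss
    nt$params$up[[2]]$W[i] <- v0 - eps
    lm <- liunet:::loss_and_grad(
      liunet:::liunet_forward(nt, x, dims, train = TRUE)$probs, G, cfg)$loss
    fd <- (lp - lm) / (2 * eps)
    an <- gr$up[[2]]$W[i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-3)
  }
})

test_that("spatial shapes not divisible by 16 are rejected", {
  arch <- tiny_arch()
  set.seed(24)
  net <- build_liunet(arch)
  x <- matrix(stats::rnorm(30^3 * 4), ncol = 4)
  expect_error(liunet:::liunet_forward(net, x, c(30, 30, 30)), "divisible")
  expect_error(liunet:::.check_spatial(arch, c(30, 30, 30)), "divisible")
  expect_silent(liunet:::.check_spatial(arch, c(32, 32, 32)))
})

test_that("bottleneck spatial shape at 128 cubed is 8 cubed", {
  arch <- liunet_arch()
  expect_identical(as.integer(128 / 2^(arch$depth - 1L)), 8L)
  # verified dynamically on a smaller input: 32 -> 2 at level 5
  set.seed(25)
  net <- build_liunet(tiny_arch())
  x <- matrix(stats::rnorm(32^3 * 4), ncol = 4)
  fw <- liunet:::liunet_forward(net, x, c(32, 32, 32), train = TRUE,
                                keep = TRUE)
  expect_identical(fw$cache$dims_l[[5]], c(2L, 2L, 2L))
})

test_that("FLOP estimate matches hand counts and scales with voxel count", {
  # one 1-cubed conv, 1 -> 1 channel, on a 2x2x2 volume: 2 * 8 = 16 FLOPs,
  # i.e. the conv term of the estimator evaluated by hand
  expect_equal(2 * 1^3 * 1 * 1 * prod(c(2, 2, 2)), 16)
  arch <- tiny_arch()
  f32 <- estimate_flops(arch, c(32, 32, 32))
  f64 <- estimate_flops(arch, c(64, 64, 64))
  expect_equal(f64 / f32, 8, tolerance = 1e-9)
  # default config lands within an order of magnitude of tens of GFLOPs
  f128 <- estimate_flops(liunet_arch(), c(128, 128, 128))
  expect_gt(f128, 10); expect_lt(f128, 1000)
})

test_that("gemm convolution agrees with the explicit patch-matrix path", {
  set.seed(26)
  dims <- c(8L, 6L, 10L)
  for (k in c(3L, 5L)) {
    for (B in c(1L, 2L)) {
      C <- 3L; Cout <- 4L
      x <- matrix(stats::rnorm(prod(dims) * C * B), ncol = C)
      W <- matrix(stats::rnorm(k^3 * C * Cout, sd = 0.2), k^3 * C, Cout)
      fast <- liunet:::conv3d_fwd(x, W, dims, k, B)
      ref <- liunet:::vol2col(x, dims, k, B) %*% W
      expect_equal(fast, ref, tolerance = 1e-5)
      # backward consistency: dW and dx against the patch-matrix adjoint
      dy <- matrix(stats::rnorm(prod(dims) * Cout * B), ncol = Cout)
      bw <- liunet:::conv3d_bwd(dy, x, W, dims, k, B)
      expect_equal(bw$dW, crossprod(liunet:::vol2col(x, dims, k, B), dy),
                   tolerance = 1e-4)
      expect_equal(bw$dx,
                   liunet:::col2vol(dy %*% t(W), dims, k, B),
                   tolerance = 1e-4)
    }
  }
})

test_that("max pooling halves dims and routes gradients to the argmax", {
  set.seed(27)
  dims <- c(4L, 4L, 4L)
  x <- matrix(stats::rnorm(prod(dims) * 2), ncol = 2)
  mp <- liunet:::maxpool3d_fwd(x, dims, 1L)
  expect_identical(dim(mp$y), c(8L, 2L))
  # every pooled value is the max of its 2x2x2 block
  expect_equal(mp$y[cbind(1, 1)], max(x[c(1, 2, 5, 6, 17, 18, 21, 22), 1]))
  dy <- matrix(1, 8, 2)
  dx <- liunet:::maxpool3d_bwd(dy, mp$idx, nrow(x))
  expect_equal(colSums(dx), colSums(dy))
  expect_true(all(dx[dx != 0] == 1))
})

test_that("model summary is reproducible and self-consistent", {
  s1 <- summarize_liunet(liunet_arch(), c(32, 32, 32))
  s2 <- summarize_liunet(liunet_arch(), c(32, 32, 32))
  expect_identical(s1, s2)
  expect_equal(s1$param_millions, s1$param_count / 1e6)
  expect_identical(s1$output_shape, c(32, 32, 32, 4L))
  expect_output(print(s1), "trainable parameters")
})
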