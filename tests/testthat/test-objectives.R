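# Dice / Focal / combined objectives and their gradients.

test_that("soft Dice matches hand-evaluated overlap arithmetic", {
  expect_equal(soft_dice_coefficient(c(1, 1, 0, 0), c(0, 1, 1, 0), eps = 0),
               0.5)
  g <- c(0, 1, 1, 0)
  expect_equal(soft_dice_coefficient(g, g), 1, tolerance = 1e-6)
  # disjoint binary masks: exactly eps / (n + eps)
  p <- c(1, 0, 0, 0); q <- c(0, 1, 0, 0)
  eps <- 1e-6
  expect_equal(soft_dice_coefficient(p, q, eps = eps), eps / (2 + eps))
  expect_error(soft_dice_coefficient(c(1, 0), c(1, 0, 0)), "differ")
})

test_that("dice_loss is 1 minus the coefficient, in [0, 1]", {
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 1, 1, 0), eps = 0), 0.5)
  g <- random_onehot(200, seed = 3L)
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-5)
  p <- random_probs(200, seed = 4L)
  l <- dice_loss(p, g)
  expect_gte(l, 0); expect_lte(l, 1)
})

test_that("focal loss reproduces its closed-form values", {
  expect_equal(focal_loss(rep(1, 50)), 0)
  # single voxel p_t = 0.5, alpha 0.25, gamma 2: 0.25 * 0.25 * ln 2
  expect_equal(focal_loss(0.5, alpha = 0.25, gamma = 2),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_error(focal_loss(0.5, gamma = -1), "gamma")
  expect_error(focal_loss(0.5, alpha = 0), "alpha")
})

test_that("focal loss reduces to cross-entropy at gamma 0, alpha 1", {
  set.seed(5)
  for (rep in 1:5) {
    p <- stats::runif(100, 0.01, 1)
    expect_equal(focal_loss(p, alpha = 1, gamma = 0), mean(-log(p)),
                 tolerance = 1e-9)
  }
})

test_that("focal loss is monotonically non-increasing in p_t", {
  grid <- seq(0.01, 1, by = 0.01)
  vals <- vapply(grid, function(p) focal_loss(p), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  # also for gamma 0 (pure weighted cross-entropy) and large gamma
  for (g in c(0, 0.5, 5)) {
    vals <- vapply(grid, function(p) focal_loss(p, gamma = g), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("binary focal loss evaluates both label branches", {
  # y = 1 branch equals the p_t form; y = 0 branch mirrors it in 1 - p
  expect_equal(focal_loss_binary(1, 0.5, alpha = 0.25, gamma = 2),
               focal_loss(0.5, alpha = 0.25, gamma = 2))
  expect_equal(focal_loss_binary(0, 0.5, alpha = 0.25, gamma = 2),
               0.75 * 0.25 * log(2), tolerance = 1e-9)
})

test_that("multi-class focal loss honours class-wise alpha_t", {
  G <- random_onehot(300, seed = 6L)
  P <- random_probs(300, seed = 7L)
  pt <- rowSums(P * G)
  expect_equal(focal_loss_multiclass(P, G), focal_loss(pt), tolerance = 1e-12)
  at <- c(0.1, 0.3, 0.3, 0.3)
  w <- as.numeric(G %*% at)
  expect_equal(focal_loss_multiclass(P, G, alpha_t = at),
               mean(-w * (1 - pt)^2 * log(pmax(pt, 1e-7))), tolerance = 1e-12)
})

test_that("combined loss is exactly lambda-linear in its components", {
  G <- random_onehot(400, seed = 8L)
  P <- random_probs(400, seed = 9L)
  f <- focal_loss_multiclass(P, G)
  d <- dice_loss(P, G)
  expect_equal(combined_loss(P, G, lambda1 = 0, lambda2 = 1), d,
               tolerance = 1e-12)
  expect_equal(combined_loss(P, G, lambda1 = 1, lambda2 = 0), f,
               tolerance = 1e-12)
  expect_equal(combined_loss(P, G, lambda1 = 1, lambda2 = 1), f + d,
               tolerance = 1e-12)
  expect_equal(combined_loss(P, G, lambda1 = 2.5, lambda2 = 0.3),
               2.5 * f + 0.3 * d, tolerance = 1e-12)
  expect_error(combined_loss(P, G, lambda1 = 0, lambda2 = 0), "not both 0")
})

test_that("loss gradients w.r.t. logits match finite differences", {
  n <- 4^3
  set.seed(10)
  Z <- matrix(stats::rnorm(n * 4), n, 4)
  G <- random_onehot(n, seed = 11L)
  for (loss in c("dice", "focal", "combined")) {
    cfg <- loss_config(loss)
    f <- function(z) {
      P <- liunet:::nn_softmax(z)
      liunet:::loss_and_grad(P, G, cfg)$loss
    }
    an <- liunet:::loss_and_grad(liunet:::nn_softmax(Z), G, cfg)$dlogits
    eps <- 1e-5
    idx <- cbind(sample.int(n, 12), sample.int(4, 12, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      Zp <- Z; Zp[idx[r, 1], idx[r, 2]] <- Z[idx[r, 1], idx[r, 2]] + eps
      Zm <- Z; Zm[idx[r, 1], idx[r, 2]] <- Z[idx[r, 1], idx[r, 2]] - eps
      fd <- (f(Zp) - f(Zm)) / (2 * eps)
      ref <- an[idx[r, 1], idx[r, 2]]
      rel <- abs(fd - ref) / max(abs(fd), abs(ref), 1e-3)
      expect_lt(rel, 1e-3,
                label = sprintf("%s grad rel err at (%d,%d)", loss,
                                idx[r, 1], idx[r, 2]))
    }
  }
})

test_that("all losses are non-negative on random inputs", {
  for (seed in 1:5) {
    G <- random_onehot(150, seed = seed)
    P <- random_probs(150, seed = seed + 100)
    expect_gte(dice_loss(P, G), 0)
    expect_gte(focal_loss_multiclass(P, G), 0)
    expect_gte(combined_loss(P, G), 0)
  }
})
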