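# Training objectives: soft Dice (squared-denominator form), Focal loss with
# class-balance factor alpha and focusing parameter gamma, and their
# lambda-weighted combination. All logarithms are natural; probabilities are
# clipped at 1e-7 before log().

.prob_clip <- 1e-7

#' @noRd
.as_channel_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) <= 1L) return(matrix(as.numeric(x), ncol = 1L))
  if (length(d) == 2L) return(x)
  matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}

#' Soft Dice coefficient
#'
#' Differentiable Dice overlap between predicted probabilities and a binary
#' ground truth, in the squared-denominator form
#' \deqn{D = \frac{2\sum_i p_i g_i + \epsilon}{\sum_i p_i^2 + \sum_i g_i^2 + \epsilon}.}
#' For multi-channel inputs (last dimension = class channels) the coefficient
#' is averaged over the foreground channels (channel 1 = background excluded)
#' unless `foreground_only = FALSE`.
#'
#' @param p Predicted probabilities: a vector, a (voxels x channels) matrix or
#'   a (D,H,W,C) array.
#' @param g Ground truth of the same shape, binary (one-hot for multi-channel).
#' @param eps Smoothing constant added to numerator and denominator.
#' @param foreground_only Average over foreground channels only (default).
#' @return The soft Dice coefficient in `[0, 1]`.
#' @examples
#' soft_dice_coefficient(c(1, 1, 0, 0), c(0, 1, 1, 0), eps = 0) # 0.5
#' @export
soft_dice_coefficient <- function(p, g, eps = 1e-6, foreground_only = TRUE) {
  pm <- .as_channel_matrix(p); gm <- .as_channel_matrix(g)
  if (!identical(dim(pm), dim(gm)))
    stop("soft_dice_coefficient: p and g shapes differ")
  ch <- seq_len(ncol(pm))
  if (foreground_only && ncol(pm) > 1L) ch <- ch[-1L]
  dpc <- vapply(ch, function(c) {
    pc <- pm[, c]; gc <- gm[, c]
    (2 * sum(pc * gc) + eps) / (sum(pc * pc) + sum(gc * gc) + eps)
  }, numeric(1))
  mean(dpc)
}

#' Soft Dice loss
#'
#' `1 -` [soft_dice_coefficient()]; 0 for a perfect prediction, close to 1
#' for a disjoint one.
#'
#' @inheritParams soft_dice_coefficient
#' @return The Dice loss in `[0, 1]`.
#' @export
dice_loss <- function(p, g, eps = 1e-6, foreground_only = TRUE) {
  1 - soft_dice_coefficient(p, g, eps = eps, foreground_only = foreground_only)
}

#' Focal loss
#'
#' Cross-entropy down-weighted on easy voxels:
#' \deqn{FL(p_t) = -\alpha (1 - p_t)^\gamma \log(p_t),}
#' averaged over voxels, where `p_t` is the predicted probability of the true
#' class. `gamma = 0, alpha = 1` recovers plain cross-entropy.
#'
#' @param p_t Per-voxel probabilities of the true class (any numeric array).
#' @param alpha Class-balance factor in `(0, 1]` (default 0.25).
#' @param gamma Focusing parameter, `>= 0` (default 2).
#' @param weights Optional per-voxel weights replacing the scalar `alpha`
#'   (used by the multi-class form with class-wise `alpha_t`).
#' @return Mean focal loss (non-negative).
#' @examples
#' focal_loss(0.5, alpha = 0.25, gamma = 2) # 0.25 * 0.25 * log(2)
#' @export
focal_loss <- function(p_t, alpha = 0.25, gamma = 2.0, weights = NULL) {
  if (gamma < 0) stop("focal_loss: gamma must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("focal_loss: alpha must be in (0, 1]")
  p <- pmin(pmax(as.numeric(p_t), .prob_clip), 1)
  w <- if (is.null(weights)) alpha else as.numeric(weights)
  mean(-w * (1 - p)^gamma * log(p))
}

#' Binary focal loss
#'
#' Two-sided binary form
#' \deqn{FL(y,p) = -\alpha y (1-p)^\gamma \log(p)
#'   - (1-\alpha)(1-y) p^\gamma \log(1-p).}
#'
#' @param y Binary ground truth labels (0/1).
#' @param p Predicted probabilities of class 1.
#' @inheritParams focal_loss
#' @return Mean binary focal loss.
#' @export
focal_loss_binary <- function(y, p, alpha = 0.25, gamma = 2.0) {
  if (gamma < 0) stop("focal_loss_binary: gamma must be >= 0")
  y <- as.numeric(y)
  p <- pmin(pmax(as.numeric(p), .prob_clip), 1 - .prob_clip)
  mean(-alpha * y * (1 - p)^gamma * log(p) -
         (1 - alpha) * (1 - y) * p^gamma * log(1 - p))
}

#' Multi-class focal loss
#'
#' Applies the focal loss to the true-class probability of every voxel, with
#' an optional class-wise weighting factor `alpha_t` (default: uniform
#' `alpha` for all classes).
#'
#' @param p Predicted class probabilities, (voxels x classes) matrix or
#'   (D,H,W,C) array.
#' @param g One-hot ground truth of the same shape.
#' @param alpha_t Optional numeric vector of per-class weights.
#' @inheritParams focal_loss
#' @return Mean focal loss.
#' @export
focal_loss_multiclass <- function(p, g, alpha = 0.25, gamma = 2.0,
                                  alpha_t = NULL) {
  pm <- .as_channel_matrix(p); gm <- .as_channel_matrix(g)
  if (!identical(dim(pm), dim(gm)))
    stop("focal_loss_multiclass: p and g shapes differ")
  p_t <- rowSums(pm * gm)
  w <- NULL
  if (!is.null(alpha_t)) {
    if (length(alpha_t) != ncol(pm))
      stop("focal_loss_multiclass: alpha_t must have one weight per class")
    w <- as.numeric(gm %*% alpha_t)
  }
  focal_loss(p_t, alpha = alpha, gamma = gamma, weights = w)
}

#' Combined Dice + Focal loss
#'
#' The composite training objective
#' `lambda1 * focal + lambda2 * dice_loss`, exactly linear in its components.
#'
#' @inheritParams focal_loss_multiclass
#' @param lambda1 Weight of the focal term (default 1).
#' @param lambda2 Weight of the Dice term (default 1).
#' @param eps Dice smoothing constant.
#' @param foreground_only Dice averaged over foreground channels only.
#' @return The combined loss (non-negative).
#' @export
combined_loss <- function(p, g, lambda1 = 1.0, lambda2 = 1.0,
                          alpha = 0.25, gamma = 2.0, alpha_t = NULL,
                          eps = 1e-6, foreground_only = TRUE) {
  if (lambda1 < 0 || lambda2 < 0 || (lambda1 == 0 && lambda2 == 0))
    stop("combined_loss: lambda1/lambda2 must be >= 0 and not both 0")
  lambda1 * focal_loss_multiclass(p, g, alpha = alpha, gamma = gamma,
                                  alpha_t = alpha_t) +
    lambda2 * dice_loss(p, g, eps = eps, foreground_only = foreground_only)
}

#' Training loss configuration
#'
#' @param loss One of `"dice"`, `"focal"`, `"combined"`.
#' @param lambda1,lambda2 Weights of the focal and Dice terms.
#' @param alpha,gamma Focal-loss parameters.
#' @param alpha_t Optional per-class focal weights.
#' @param eps Dice smoothing constant.
#' @param foreground_only Dice over foreground channels only.
#' @return A list of class `liunet_loss_config`.
#' @export
loss_config <- function(loss = c("combined", "dice", "focal"),
                        lambda1 = 1.0, lambda2 = 1.0,
                        alpha = 0.25, gamma = 2.0, alpha_t = NULL,
                        eps = 1e-6, foreground_only = TRUE) {
  loss <- match.arg(loss)
  if (gamma < 0) stop("loss_config: gamma must be >= 0")
  structure(list(loss = loss, lambda1 = lambda1, lambda2 = lambda2,
                 alpha = alpha, gamma = gamma, alpha_t = alpha_t,
                 eps = eps, foreground_only = foreground_only),
            class = "liunet_loss_config")
}

# ---- loss + gradient w.r.t. logits (training path) -------------------------

# Given softmax probabilities P and one-hot G as (B*N x C) matrices, returns
# the scalar loss and its gradient w.r.t. the pre-softmax logits. Dice sums
# run over the whole batch (batch-global Dice); the focal term is a mean over
# voxels. The softmax Jacobian is applied as dZ = P * (dP - rowSums(dP * P)).
#' @noRd
loss_and_grad <- function(P, G, cfg) {
  nr <- nrow(P); nc <- ncol(P)
  dP <- matrix(0, nr, nc)
  l_dice <- 0; l_focal <- 0
  use_dice <- cfg$loss %in% c("dice", "combined")
  use_focal <- cfg$loss %in% c("focal", "combined")
  w_dice <- if (cfg$loss == "dice") 1 else cfg$lambda2
  w_focal <- if (cfg$loss == "focal") 1 else cfg$lambda1

  if (use_dice) {
    ch <- seq_len(nc)
    if (cfg$foreground_only && nc > 1L) ch <- ch[-1L]
    k <- length(ch)
    dsum <- 0
    for (c in ch) {
      pc <- P[, c]; gc <- G[, c]
      num <- 2 * sum(pc * gc) + cfg$eps
      den <- sum(pc * pc) + sum(gc * gc) + cfg$eps
      dsum <- dsum + num / den
      # d(1 - num/den)/dp = -(2*g*den - num*2*p)/den^2, averaged over channels
      dP[, c] <- dP[, c] - w_dice * (2 * gc * den - num * 2 * pc) / (den^2 * k)
    }
    l_dice <- 1 - dsum / k
  }
  if (use_focal) {
    p_t <- rowSums(P * G)
    clipped <- p_t < .prob_clip
    pt <- pmin(pmax(p_t, .prob_clip), 1)
    w <- if (is.null(cfg$alpha_t)) rep(cfg$alpha, nr)
         else as.numeric(G %*% cfg$alpha_t)
    omp <- 1 - pt
    l_focal <- mean(-w * omp^cfg$gamma * log(pt))
    term1 <- if (cfg$gamma == 0) 0 else -cfg$gamma * omp^(cfg$gamma - 1) * log(pt)
    dldpt <- -w * (term1 + omp^cfg$gamma / pt) / nr
    dldpt[clipped] <- 0
    dP <- dP + w_focal * (G * dldpt)
  }
  loss <- w_dice * l_dice * as.numeric(use_dice) +
    w_focal * l_focal * as.numeric(use_focal)
  dZ <- P * (dP - rowSums(dP * P))
  list(loss = loss, dice = l_dice, focal = l_focal, dlogits = dZ)
}
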