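# Training engine: Adam on the selected objective, fully seeded (weight
# init, data order), CSV-able per-epoch log, best-validation checkpointing.
# CPU determinism is contractual: two runs with identical seeds give
# identical losses.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam, learning rate 1e-4, batch
#' size 2, 100 epochs.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Samples per optimization step (>= 1).
#' @param epochs Number of passes over the training partition (>= 1).
#' @param loss A [loss_config()] (or a string `"dice"`, `"focal"`,
#'   `"combined"`).
#' @param seed Integer seed controlling weight initialisation and data order.
#' @param target_shape Spatial shape volumes are resampled to before
#'   training; must be divisible by 16.
#' @param normalize Intensity normalization mode, `"minmax"` (default) or
#'   `"zscore"`.
#' @param augment_flips Random axis flips during training (default off).
#' @param checkpoint_dir Optional directory for the best-validation
#'   checkpoint.
#' @param device Compute device. Only `"cpu"` is implemented; requesting
#'   `"gpu"` falls back to CPU with a warning.
#' @return A list of class `liunet_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 2L, epochs = 100L,
                         loss = loss_config("combined"), seed = 42L,
                         target_shape = c(128L, 128L, 128L),
                         normalize = c("minmax", "zscore"),
                         augment_flips = FALSE, checkpoint_dir = NULL,
                         device = c("cpu", "gpu")) {
  device <- match.arg(device)
  if (device == "gpu") {
    warning("train_config: no GPU backend available; using cpu")
    device <- "cpu"
  }
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (is.character(loss)) loss <- loss_config(loss)
  stopifnot(inherits(loss, "liunet_loss_config"))
  normalize <- match.arg(normalize)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = "adam",
                 loss = loss, seed = as.integer(seed),
                 target_shape = as.integer(target_shape),
                 normalize = normalize, augment_flips = augment_flips,
                 checkpoint_dir = checkpoint_dir, device = device),
            class = "liunet_train_config")
}

# Flatten a (D,H,W,C) array to the (N x C) matrix layout of the network.
#' @noRd
.tensor_to_matrix <- function(x) {
  d <- dim(x)
  matrix(x, nrow = prod(d[1:3]), ncol = d[4L])
}

#' @noRd
.flip_tensor <- function(x, axes) {
  idx <- lapply(1:3, function(a)
    if (axes[a]) rev(seq_len(dim(x)[a])) else seq_len(dim(x)[a]))
  x[idx[[1L]], idx[[2L]], idx[[3L]], , drop = FALSE]
}

# Load and preprocess the subjects of one partition from a cohort directory.
#' @noRd
.load_partition <- function(data_dir, ids, control) {
  lapply(ids, function(id) {
    sub <- read_subject(brats_subject_record(data_dir, id))
    pp <- preprocess_subject(sub, target_shape = control$target_shape,
                             normalize = control$normalize)
    if (is.null(pp$y))
      stop("subject ", id, " has no segmentation mask")
    list(id = id, x = pp$x, y = pp$y, mask = pp$mask)
  })
}

#' Fit a LIU-Net segmentation model
#'
#' Trains the network on the `train` partition of a BraTS-layout cohort with
#' Adam and the configured Dice/Focal/combined objective, evaluating the
#' validation partition after every epoch. The returned object keeps the
#' weights of the best-validation epoch (by mean foreground soft Dice; the
#' final weights when there is no validation partition) and a per-epoch log.
#'
#' @param data_dir Cohort root directory in BraTS layout.
#' @param split A `dataset_split` (from [make_split()] or [read_manifest()]).
#' @param arch A [liunet_arch()] configuration.
#' @param control A [train_config()].
#' @return An object of class `liunet` with components `net` (weights and
#'   running statistics), `arch`, `control`, `log` (data.frame with one row
#'   per epoch), `best_epoch` and `train_ids`/`val_ids`.
#' @seealso [predict.liunet()], [summary.liunet()], [plot.liunet()]
#' @export
liunet_train <- function(data_dir, split, arch = liunet_arch(),
                         control = train_config()) {
  stopifnot(inherits(split, "dataset_split"),
            inherits(arch, "liunet_arch"),
            inherits(control, "liunet_train_config"))
  if (!length(split$train_ids))
    stop("liunet_train: empty training partition")
  .check_spatial(arch, control$target_shape)

  train_set <- .load_partition(data_dir, split$train_ids, control)
  val_set <- if (length(split$val_ids))
    .load_partition(data_dir, split$val_ids, control) else list()

  with_seed(control$seed, {
    net <- build_liunet(arch)
    opt <- adam_init(net$params)
    n_train <- length(train_set)
    bs <- min(control$batch_size, n_train)
    dims <- control$target_shape
    log <- vector("list", control$epochs)
    best <- list(score = -Inf, net = NULL, epoch = 0L)
    t0 <- proc.time()[["elapsed"]]

    for (epoch in seq_len(control$epochs)) {
      order_ <- sample.int(n_train)
      losses <- c()
      for (start in seq(1L, n_train, by = bs)) {
        take <- order_[start:min(start + bs - 1L, n_train)]
        B <- length(take)
        batch <- train_set[take]
        if (control$augment_flips) {
          batch <- lapply(batch, function(s) {
            axes <- stats::runif(3L) < 0.5
            list(x = .flip_tensor(s$x, axes), y = .flip_tensor(s$y, axes))
          })
        }
        X <- do.call(rbind, lapply(batch, function(s) .tensor_to_matrix(s$x)))
        G <- do.call(rbind, lapply(batch, function(s) .tensor_to_matrix(s$y)))
        fw <- liunet_forward(net, X, dims, B = B, train = TRUE, keep = TRUE)
        net <- fw$net
        lg <- loss_and_grad(fw$probs, G, control$loss)
        if (!is.finite(lg$loss))
          stop("liunet_train: non-finite loss at epoch ", epoch,
               " (loss=", lg$loss, "); aborting")
        grads <- liunet_backward(net, lg$dlogits, fw$cache)
        upd <- adam_update(net$params, grads, opt, control$learning_rate)
        net$params <- upd$params
        opt <- upd$state
        losses <- c(losses, lg$loss)
      }
      val <- .evaluate_partition(net, val_set, dims, control$loss)
      log[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(losses),
        val_loss = val$loss, dice_ET = val$regions[["ET"]],
        dice_TC = val$regions[["TC"]], dice_WT = val$regions[["WT"]],
        elapsed_s = proc.time()[["elapsed"]] - t0)
      score <- if (length(val_set)) val$soft_dice else -epoch # fall back: last
      if (score >= best$score) {
        best <- list(score = score, net = net, epoch = epoch)
      }
      if (!length(val_set)) best <- list(score = score, net = net,
                                         epoch = epoch)
    }
    fit <- structure(list(net = best$net, final_net = net, arch = arch,
                          control = control, log = do.call(rbind, log),
                          best_epoch = best$epoch,
                          train_ids = split$train_ids,
                          val_ids = split$val_ids),
                     class = "liunet")
    if (!is.null(control$checkpoint_dir))
      save_checkpoint(fit, file.path(control$checkpoint_dir,
                                     "liunet_best.rds"))
    fit
  })
}

# Mean loss, soft foreground Dice and per-region soft Dice over a partition
# (evaluation mode: batch-norm running statistics).
#' @noRd
.evaluate_partition <- function(net, subjects, dims, loss_cfg) {
  if (!length(subjects))
    return(list(loss = NA_real_, soft_dice = NA_real_,
                regions = c(ET = NA_real_, TC = NA_real_, WT = NA_real_)))
  losses <- numeric(length(subjects))
  dices <- numeric(length(subjects))
  regs <- matrix(0, length(subjects), 3L,
                 dimnames = list(NULL, c("ET", "TC", "WT")))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    fw <- liunet_forward(net, .tensor_to_matrix(s$x), dims, B = 1L,
                         train = FALSE, keep = FALSE)
    G <- .tensor_to_matrix(s$y)
    losses[i] <- loss_and_grad(fw$probs, G, loss_cfg)$loss
    dices[i] <- soft_dice_coefficient(fw$probs, G)
    regs[i, ] <- soft_region_dice(fw$probs, G)
  }
  list(loss = mean(losses), soft_dice = mean(dices),
       regions = colMeans(regs))
}

#' Mean foreground soft Dice of a fitted model on a set of subjects
#'
#' @param object A `liunet` fit or `liunet_net`.
#' @param data_dir Cohort root directory.
#' @param ids Subject ids to evaluate.
#' @param control A [train_config()] supplying preprocessing settings
#'   (defaults to the fit's own).
#' @return Mean (over subjects) soft Dice averaged over foreground classes.
#' @export
soft_dice_on <- function(object, data_dir, ids, control = NULL) {
  net <- if (inherits(object, "liunet")) object$net else object
  if (is.null(control) && inherits(object, "liunet")) control <- object$control
  if (is.null(control)) control <- train_config()
  subjects <- .load_partition(data_dir, ids, control)
  .evaluate_partition(net, subjects, control$target_shape,
                      control$loss)$soft_dice
}

#' Predict a segmentation mask
#'
#' Runs the fitted network on one subject (evaluation-mode batch norm) and
#' returns the per-voxel argmax as a label volume with values in
#' \{0, 1, 2, 3\}. Deterministic: the same weights and subject always give
#' the identical mask.
#'
#' @param object A fitted `liunet` (or an untrained `liunet_net` via
#'   [predict_net()]).
#' @param newdata A [subject_record()], a list from [read_subject()], a
#'   `phantom_subject`, or a preprocessed `(D,H,W,4)` tensor.
#' @param ... Unused.
#' @return 3D integer label array; softmax probabilities attached as
#'   attribute `"probabilities"` (a (D,H,W,4) array).
#' @export
predict.liunet <- function(object, newdata, ...) {
  predict_net(object$net, newdata, control = object$control)
}

#' @rdname predict.liunet
#' @param net A `liunet_net`.
#' @param control A [train_config()] supplying preprocessing settings.
#' @export
predict_net <- function(net, newdata, control = train_config()) {
  stopifnot(inherits(net, "liunet_net"))
  if (inherits(newdata, "subject_record")) newdata <- read_subject(newdata)
  if (is.list(newdata) && !is.null(newdata$volumes)) {
    newdata <- preprocess_subject(newdata, target_shape = control$target_shape,
                                  normalize = control$normalize)$x
  }
  d <- dim(newdata)
  if (is.null(d) || length(d) != 4L || d[4L] != net$arch$in_channels)
    stop("predict: newdata must be a (D,H,W,", net$arch$in_channels,
         ") tensor or a subject")
  .check_spatial(net$arch, d[1:3])
  fw <- liunet_forward(net, .tensor_to_matrix(newdata), d[1:3], B = 1L,
                       train = FALSE, keep = FALSE)
  lab <- array(max.col(fw$probs, ties.method = "first") - 1L, d[1:3])
  attr(lab, "probabilities") <- array(fw$probs, c(d[1:3], net$arch$n_classes))
  lab
}

#' Save / load a model checkpoint
#'
#' Serialized with R's native RDS format (weights, running statistics,
#' architecture and training configuration). A save/load round trip
#' reproduces predictions bit-identically.
#'
#' @param object A `liunet` fit or `liunet_net`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` the path; `load_checkpoint` the restored object.
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.liunet <- function(x, ...) {
  n <- count_parameters(x)
  cat("LIU-Net segmentation model\n")
  cat(sprintf("  %d trainable parameters (%.3f M), depth %d, widths %s\n",
              n, n / 1e6, x$arch$depth, paste(x$arch$widths, collapse = "/")))
  cat(sprintf("  trained %d epoch(s) on %d subject(s); best epoch %d\n",
              nrow(x$log), length(x$train_ids), x$best_epoch))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final train loss %.4f", last$train_loss))
  if (is.finite(last$val_loss))
    cat(sprintf(", val loss %.4f (soft Dice ET %.3f TC %.3f WT %.3f)",
                last$val_loss, last$dice_ET, last$dice_TC, last$dice_WT))
  cat("\n")
  invisible(x)
}

#' Summary of a fitted LIU-Net
#'
#' @param object A `liunet` fit.
#' @param input_shape Spatial shape for the FLOP estimate (defaults to the
#'   fit's training shape).
#' @param ... Unused.
#' @return A `liunet_summary` (parameter count, millions, GFLOPs, output
#'   shape) with the training log attached as attribute `"log"`.
#' @export
summary.liunet <- function(object, input_shape = object$control$target_shape,
                           ...) {
  s <- summarize_liunet(object$arch, input_shape)
  attr(s, "log") <- object$log
  s
}

#' Plot training curves
#'
#' Training and validation loss per epoch (left axis), with the best epoch
#' marked.
#'
#' @param x A `liunet` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.liunet <- function(x, ...) {
  log <- x$log
  ys <- cbind(train = log$train_loss, val = log$val_loss)
  graphics::matplot(log$epoch, ys, type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", legend = colnames(ys), lty = 1, lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.liunet <- function(object, ...) {
  flat <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- as.character(seq_along(x))
      for (i in seq_along(x)) walk(x[[i]], paste0(prefix, ".", nms[i]))
    } else flat[[sub("^\\.", "", prefix)]] <<- x
  }
  walk(object$net$params, "")
  flat
}
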