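# Training engine: optimization, determinism, checkpointing, prediction.

make_fit <- local({
  cache <- new.env()
  function(epochs = 3L) {
    key <- paste0("fit", epochs)
    if (is.null(cache[[key]])) {
      co <- tiny_cohort(n = 2L, shape = c(16L, 16L, 16L))
      split <- make_split(co$ids, c(0.5, 0.5, 0), seed = 1L)
      ctl <- train_config(epochs = epochs, batch_size = 1L, seed = 3L,
                          target_shape = c(16L, 16L, 16L),
                          learning_rate = 1e-3)
      cache[[key]] <- list(
        fit = liunet_train(co$dir, split, tiny_arch(), ctl),
        co = co, split = split, ctl = ctl)
    }
    cache[[key]]
  }
})

test_that("one optimization step strictly decreases the combined loss", {
  co <- tiny_cohort(n = 1L, shape = c(16L, 16L, 16L))
  sub <- read_subject(brats_subject_record(co$dir, co$ids[1]))
  pp <- preprocess_subject(sub, target_shape = c(16L, 16L, 16L))
  X <- liunet:::.tensor_to_matrix(pp$x)
  G <- liunet:::.tensor_to_matrix(pp$y)
  cfg <- loss_config("combined")
  set.seed(31)
  net <- build_liunet(tiny_arch())
  opt <- liunet:::adam_init(net$params)
  fw1 <- liunet:::liunet_forward(net, X, c(16, 16, 16), train = TRUE,
                                 keep = TRUE)
  l1 <- liunet:::loss_and_grad(fw1$probs, G, cfg)
  gr <- liunet:::liunet_backward(fw1$net, l1$dlogits, fw1$cache)
  upd <- liunet:::adam_update(fw1$net$params, gr, opt, 1e-3)
  net2 <- fw1$net; net2$params <- upd$params
  fw2 <- liunet:::liunet_forward(net2, X, c(16, 16, 16), train = TRUE,
                                 keep = FALSE)
  l2 <- liunet:::loss_and_grad(fw2$probs, G, cfg)
  expect_lt(l2$loss, l1$loss)
})

test_that("the training log has one row per epoch with finite losses", {
  mf <- make_fit()
  fit <- mf$fit
  expect_s3_class(fit, "liunet")
  expect_identical(nrow(fit$log), mf$ctl$epochs)
  expect_identical(fit$log$epoch, seq_len(mf$ctl$epochs))
  expect_true(all(is.finite(fit$log$train_loss)))
  expect_true(all(is.finite(fit$log$val_loss)))
  expect_true(all(is.finite(fit$log$dice_WT)))
})

test_that("training is deterministic on CPU for identical seeds", {
  mf <- make_fit()
  fit2 <- liunet_train(mf$co$dir, mf$split, tiny_arch(), mf$ctl)
  expect_lt(abs(tail(fit2$log$train_loss, 1) -
                  tail(mf$fit$log$train_loss, 1)), 1e-6)
  expect_identical(fit2$log$train_loss, mf$fit$log$train_loss)
})

test_that("predictions are valid label volumes and deterministic", {
  mf <- make_fit()
  co <- mf$co
  sub <- brats_subject_record(co$dir, co$ids[1])
  lab1 <- predict(mf$fit, sub)
  lab2 <- predict(mf$fit, sub)
  expect_identical(dim(lab1), c(16L, 16L, 16L))
  expect_true(all(lab1 %in% 0:3))
  a1 <- lab1; attr(a1, "probabilities") <- NULL
  a2 <- lab2; attr(a2, "probabilities") <- NULL
  expect_identical(a1, a2)
  probs <- attr(lab1, "probabilities")
  expect_identical(dim(probs), c(16L, 16L, 16L, 4L))
  expect_lt(max(abs(apply(probs, 1:3, sum) - 1)), 1e-5)
})

test_that("prediction rejects shapes not divisible by 16", {
  set.seed(33)
  net <- build_liunet(tiny_arch())
  bad <- array(stats::rnorm(24 * 24 * 24 * 4), c(24, 24, 24, 4))
  expect_error(predict_net(net, bad), "divisible")
})

test_that("checkpoints round-trip to bit-identical predictions", {
  mf <- make_fit()
  p <- tempfile(fileext = ".rds")
  save_checkpoint(mf$fit, p)
  back <- load_checkpoint(p)
  sub <- brats_subject_record(mf$co$dir, mf$co$ids[2])
  l1 <- predict(mf$fit, sub)
  l2 <- predict(back, sub)
  expect_identical(l1, l2)
})

test_that("empty training partitions and bad configs are rejected", {
  co <- tiny_cohort(n = 2L, shape = c(16L, 16L, 16L))
  empty <- structure(list(train_ids = character(), val_ids = co$ids,
                          test_ids = character(), fractions = c(0, 1, 0),
                          seed = 1L), class = "dataset_split")
  expect_error(liunet_train(co$dir, empty, tiny_arch(), train_config()),
               "empty training partition")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("S3 methods print, summarize, plot and expose coefficients", {
  mf <- make_fit()
  expect_output(print(mf$fit), "LIU-Net segmentation model")
  s <- summary(mf$fit)
  expect_s3_class(s, "liunet_summary")
  expect_identical(s$param_count, count_parameters(mf$fit))
  expect_s3_class(attr(s, "log"), "data.frame")
  cf <- coef(mf$fit)
  expect_true(length(cf) > 10)
  expect_identical(sum(lengths(cf)), as.integer(count_parameters(mf$fit)))
  pdf(NULL)
  expect_silent(plot(mf$fit))
  dev.off()
})

test_that("axis-flip augmentation keeps image and labels aligned", {
  co <- tiny_cohort(n = 1L, shape = c(16L, 16L, 16L))
  sub <- read_subject(brats_subject_record(co$dir, co$ids[1]))
  pp <- preprocess_subject(sub, target_shape = c(16L, 16L, 16L))
  fx <- liunet:::.flip_tensor(pp$x, c(TRUE, FALSE, TRUE))
  fy <- liunet:::.flip_tensor(pp$y, c(TRUE, FALSE, TRUE))
  expect_identical(dim(fx), dim(pp$x))
  # flipping twice is the identity
  expect_equal(liunet:::.flip_tensor(fx, c(TRUE, FALSE, TRUE)),
               pp$x, ignore_attr = TRUE)
  # labels flipped with the same axes stay in register with the image
  expect_identical(decode_one_hot(fy),
                   liunet:::.flip_tensor(
                     array(pp$mask, c(dim(pp$mask), 1L)),
                     c(TRUE, FALSE, TRUE))[, , , 1L])
})
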