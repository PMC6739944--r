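# Model construction, training mechanics, prediction and metrics.

test_that("build_model honors the configuration and validates geometry", {
  cfg <- model_config(n_tasks = 6, conv_filters = c(8, 4, 4),
                      conv_widths = c(11, 5, 3), pool_sizes = c(4, 4, 4),
                      fc_units = 16, context_size = 1000)
  m <- build_model(cfg)
  layers <- model_layers(m)
  expect_equal(nrow(layers), 5)
  expect_equal(layers$units, c(8L, 4L, 4L, 16L, 6L))
  expect_equal(layers$width[1:3], c(11L, 5L, 3L))
  # too-small context for the receptive field errors
  bad <- model_config(n_tasks = 2, conv_filters = c(4, 4, 4),
                      conv_widths = c(19, 11, 7),
                      pool_sizes = c(4, 4, 4), context_size = 60)
  expect_error(build_model(bad), "receptive field|pooling")
})

test_that("an untrained model refuses to predict; forward is sigmoid", {
  cfg <- toy_config()
  m <- build_model(cfg)
  X1 <- one_hot(toy_seq(200))
  expect_error(predict(m, X1), "not fitted")
  m$fitted <- TRUE                      # forward with random weights
  p <- predict(m, X1)
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(1L, 2L))
  expect_error(predict(m, one_hot(toy_seq(100))), "1000|must be|200")
})

test_that("training reduces loss, restores best weights, is deterministic", {
  tm <- toy_model()
  m <- tm$model
  h <- m$history
  expect_true(any(diff(h$train_loss) < 0))
  expect_lte(m$best_epoch, nrow(h))
  # bit-identical rerun under the same seed
  m2 <- train_model(build_model(toy_config()), tm$dataset)
  expect_identical(m$history, m2$history)
  expect_identical(m$params$fc$W, m2$params$fc$W)
  # empty partitions rejected
  ds_bad <- tm$dataset
  ds_bad$partition <- factor(rep("train", dim(ds_bad$X)[3]),
                             levels = c("train", "val", "test"))
  expect_error(train_model(build_model(toy_config()), ds_bad), "empty")
})

test_that("FC penalty contributes exactly its analytic value to the loss", {
  tm <- toy_model()
  ds <- tm$dataset
  tr <- dataset_partition(ds, "train")
  X <- tr$X[, , 1:16, drop = FALSE]
  Y <- matrix(as.numeric(tr$Y[1:16, ]), 16)
  params <- tm$model$params
  l0 <- epimotif:::.cnn_lossgrad_cpp(params, X, Y, 0, 0)$loss
  l1 <- 1e-3; l2 <- 1e-2
  lr <- epimotif:::.cnn_lossgrad_cpp(params, X, Y, l1, l2)$loss
  pen <- fc_penalty(tm$model, l1, l2)
  expect_lt(abs((lr - l0) - pen), 1e-10)
  expect_identical(fc_penalty(tm$model, 0, 0), 0)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(n_tasks = 2, conv_filters = c(3, 2, 2),
                      conv_widths = c(5, 3, 3), pool_sizes = c(2, 2, 2),
                      fc_units = 4, context_size = 60, rng_seed = 5)
  m <- build_model(cfg)
  set.seed(1)
  B <- 5
  X <- array(0, dim = c(60, 4, B))
  for (i in seq_len(B)) X[, , i] <- one_hot(toy_seq(60))
  Y <- matrix(as.numeric(rbinom(B * 2, 1, 0.5)), B, 2)
  g <- epimotif:::.cnn_lossgrad_cpp(m$params, X, Y, 1e-4, 1e-4)
  eps <- 1e-6
  fd <- function(setter) {
    pp <- setter(m$params, eps)
    pm <- setter(m$params, -eps)
    (epimotif:::.cnn_lossgrad_cpp(pp, X, Y, 1e-4, 1e-4)$loss -
       epimotif:::.cnn_lossgrad_cpp(pm, X, Y, 1e-4, 1e-4)$loss) / (2 * eps)
  }
  # a handful of representative parameters across all layer types
  checks <- list(
    list(g$conv[[1]]$dW[3, 2], function(p, e) {
      p$conv[[1]]$W[3, 2] <- p$conv[[1]]$W[3, 2] + e; p
    }),
    list(g$conv[[2]]$dgamma[1, 2], function(p, e) {
      p$conv[[2]]$gamma[2] <- p$conv[[2]]$gamma[2] + e; p
    }),
    list(g$conv[[3]]$dbeta[1, 1], function(p, e) {
      p$conv[[3]]$beta[1] <- p$conv[[3]]$beta[1] + e; p
    }),
    list(g$dWfc[5, 3], function(p, e) {
      p$fc$W[5, 3] <- p$fc$W[5, 3] + e; p
    }),
    list(g$dWout[2, 1], function(p, e) {
      p$out$W[2, 1] <- p$out$W[2, 1] + e; p
    }))
  for (chk in checks) {
    expect_equal(chk[[1]], fd(chk[[2]]), tolerance = 1e-5)
  }
})

test_that("prediction is deterministic and batch-composition invariant", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  P1 <- predict(tm$model, te$X)
  P2 <- predict(tm$model, te$X)
  expect_identical(P1, P2)
  p_one <- predict(tm$model, te$X[, , 5])
  expect_identical(as.numeric(P1[5, ]), as.numeric(p_one[1, ]))
  expect_true(all(P1 > 0 & P1 < 1))
})

test_that("accuracy implements the confusion-count formula", {
  # TP=2, TN=2, FP=1, FN=0 -> (2+2)/5 = 0.8
  labels <- c(1, 1, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  expect_equal(accuracy(labels, probs)$mean, 0.8)
  expect_equal(accuracy(c(1, 0), c(0.9, 0.1))$mean, 1.0)
  expect_error(accuracy(numeric(0), numeric(0)), "empty")
  expect_error(accuracy(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
})

test_that("accuracy equals a brute-force confusion oracle (fuzz)", {
  set.seed(77)
  for (case in 1:100) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    cut <- runif(1, 0.2, 0.8)
    tp <- sum(p >= cut & y == 1); tn <- sum(p < cut & y == 0)
    fp <- sum(p >= cut & y == 0); fn <- sum(p < cut & y == 1)
    expect_identical(accuracy(y, p, cut)$mean,
                     (tp + tn) / (tp + fn + tn + fp))
  }
})

test_that("AUC equals the O(N^2) pair-counting oracle with midranks", {
  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(88)
  for (case in 1:40) {
    n <- sample(8:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    s <- sample(round(runif(n), 2))       # ties on purpose
    expect_equal(roc_auc(y, s)$per_task, pair_auc(y, s),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # perfectly separated scores
  expect_equal(unname(roc_auc(c(0, 0, 1, 1), c(.1, .2, .8, .9))$per_task), 1)
  # random scores at N = 2000 are near 0.5
  set.seed(99)
  y <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(y, runif(2000))$per_task - 0.5), 0.05)
  # single-class task flagged
  expect_warning(a <- roc_auc(rep(1, 5), runif(5)), "single class")
  expect_true(is.na(a$per_task))
})

test_that("ROC points rise monotonically from the origin", {
  set.seed(3)
  y <- rbinom(100, 1, 0.4)
  r <- roc_auc(y, runif(100))$roc[[1]]
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("evaluate_model counts confusions per task", {
  tm <- toy_model()
  ev <- evaluate_model(tm$model, tm$dataset, "test")
  n <- ev$n
  expect_true(all(ev$confusion$TP + ev$confusion$TN +
                    ev$confusion$FP + ev$confusion$FN == n))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
})

test_that("random_search samples the grid and returns the best trial", {
  grid <- default_trial_grid()
  expect_equal(nrow(grid), 30)
  expect_equal(sort(unique(grid$l1)), c(1e-07, 2e-07, 3e-07, 4e-07,
                                        5e-07, 6e-07))
  expect_equal(grid$l2[grid$l1 == 1e-07][1], 2e-08)
  tm <- toy_model()
  small <- data.frame(l1 = c(0, 1e-6), l2 = c(0, 1e-6),
                      patience = 50L, max_epochs = 1L, batch_size = 32L,
                      overlap_fraction = 0.5)
  expect_warning(
    rs <- random_search(tm$dataset, small, n_trials = 5, seed = 1,
                        base_config = toy_config()),
    "capped")
  expect_equal(nrow(rs$trials), 2)
  expect_equal(rs$best_config$l1,
               rs$trials$l1[which.max(rs$trials$val_accuracy)])
  # grid of one returns that configuration
  rs1 <- random_search(tm$dataset, small[1, ], n_trials = 1, seed = 2,
                       base_config = toy_config())
  expect_equal(rs1$best_config$l1, small$l1[1])
  # seed-fixed sampling reproducible
  rs2 <- random_search(tm$dataset, small[1, ], n_trials = 1, seed = 2,
                       base_config = toy_config())
  expect_equal(rs1$trials$val_accuracy, rs2$trials$val_accuracy)
})

test_that("model checkpoints round-trip through save/load", {
  tm <- toy_model()
  d <- tempfile("ckpt")
  save_model(tm$model, d)
  m2 <- load_model(d)
  expect_true(m2$fitted)
  expect_equal(m2$task_names, tm$model$task_names)
  te <- dataset_partition(tm$dataset, "test")
  expect_equal(predict(m2, te$X[, , 1:4]),
               predict(tm$model, te$X[, , 1:4]))
})
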