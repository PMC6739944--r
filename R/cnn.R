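# Model configuration, construction, training, prediction and evaluation.

#' Configuration for a multi-task sequence CNN
#'
#' Defaults follow the full-scale architecture (320/300/300 convolution
#' filters, 1000 fully connected units) and training protocol (RMSprop,
#' learning rate 0.001, batch 128, at most 20 epochs, early-stopping
#' patience of 5000 validation checks). Convolution widths and pool sizes
#' are configurable; defaults are widths 19/11/7 with 4x max pooling
#' (stride = pool size).
#'
#' @param n_tasks number of output tasks (marks for a cell model, cell
#'   types for a mark model).
#' @param conv_filters filters per convolutional layer.
#' @param conv_widths filter widths (bp at layer 1).
#' @param pool_sizes max-pool window per unit (stride = window).
#' @param fc_units fully connected layer width.
#' @param l1,l2 regularization weights, applied to the fully connected
#'   layer weights only.
#' @param learning_rate RMSprop learning rate.
#' @param batch_size minibatch size.
#' @param patience validation checks without improvement before stopping.
#' @param max_epochs maximum training epochs.
#' @param context_size input sequence length (bp).
#' @param overlap_fraction bin-labeling threshold recorded with the model.
#' @param rng_seed seed for parameter init and shuffling.
#' @return a `model_config` list.
#' @export
model_config <- function(n_tasks, conv_filters = c(320, 300, 300),
                         conv_widths = c(19, 11, 7),
                         pool_sizes = c(4, 4, 4), fc_units = 1000,
                         l1 = 1e-07, l2 = 2e-08, learning_rate = 0.001,
                         batch_size = 128, patience = 5000,
                         max_epochs = 20, context_size = 1000,
                         overlap_fraction = 0.5, rng_seed = 1) {
  stopifnot(n_tasks >= 1, all(conv_filters > 0), all(conv_widths > 0),
            all(pool_sizes > 0), fc_units > 0, l1 >= 0, l2 >= 0,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(n_tasks = as.integer(n_tasks),
                 conv_filters = as.integer(conv_filters),
                 conv_widths = as.integer(conv_widths),
                 pool_sizes = as.integer(pool_sizes),
                 fc_units = as.integer(fc_units),
                 l1 = l1, l2 = l2, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 context_size = as.integer(context_size),
                 overlap_fraction = overlap_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

# per-layer output lengths; errors when the receptive field exceeds input
.layer_dims <- function(config) {
  L <- config$context_size
  dims <- list()
  c_in <- 4L
  for (j in seq_along(config$conv_filters)) {
    L_out <- L - config$conv_widths[j] + 1L
    if (L_out < 1) {
      stop("context_size too small for receptive field at conv layer ", j)
    }
    L_p <- L_out %/% config$pool_sizes[j]
    if (L_p < 1) {
      stop("context_size too small for pooling at conv layer ", j)
    }
    dims[[j]] <- list(L_out = L_out, L_p = L_p, c_in = c_in,
                      c_out = config$conv_filters[j])
    c_in <- config$conv_filters[j]
    L <- L_p
  }
  list(conv = dims, flat = L * c_in)
}

#' Build an untrained multi-task sequence CNN
#'
#' Unit order per convolutional block is conv -> ReLU -> batch
#' normalization -> max pooling; the flattened third block feeds a sigmoid
#' fully connected layer and a sigmoid output unit per task. Parameters
#' are He-initialized under `config$rng_seed`.
#'
#' @param config a [model_config()].
#' @return object of class `sequence_model` (unfitted).
#' @export
build_model <- function(config) {
  dims <- .layer_dims(config)
  old <- .Random.seed_save()
  set.seed(config$rng_seed)
  conv <- vector("list", length(config$conv_filters))
  for (j in seq_along(conv)) {
    d <- dims$conv[[j]]
    fan_in <- config$conv_widths[j] * d$c_in
    conv[[j]] <- list(
      W = matrix(rnorm(fan_in * d$c_out, sd = sqrt(2 / fan_in)),
                 fan_in, d$c_out),
      b = rep(0, d$c_out),
      gamma = rep(1, d$c_out), beta = rep(0, d$c_out),
      run_mean = rep(0, d$c_out), run_var = rep(1, d$c_out),
      width = config$conv_widths[j], pool = config$pool_sizes[j])
  }
  fc <- list(W = matrix(rnorm(dims$flat * config$fc_units,
                              sd = sqrt(1 / dims$flat)),
                        dims$flat, config$fc_units),
             b = rep(0, config$fc_units))
  out <- list(W = matrix(rnorm(config$fc_units * config$n_tasks,
                               sd = sqrt(1 / config$fc_units)),
                         config$fc_units, config$n_tasks),
              b = rep(0, config$n_tasks))
  .Random.seed_restore(old)
  structure(list(config = config,
                 params = list(conv = conv, fc = fc, out = out),
                 dims = dims, fitted = FALSE, history = NULL,
                 task_names = NULL),
            class = "sequence_model")
}

#' Layer inventory of a model
#' @param model a `sequence_model`.
#' @return data frame with one row per layer (type, output length,
#'   channels/units, filter width, pool size).
#' @export
model_layers <- function(model) {
  cfg <- model$config
  rows <- list()
  for (j in seq_along(cfg$conv_filters)) {
    d <- model$dims$conv[[j]]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("conv%d(relu,bn,maxpool)", j),
      out_length = d$L_p, units = d$c_out,
      width = cfg$conv_widths[j], pool = cfg$pool_sizes[j])
  }
  rows[[length(rows) + 1]] <- data.frame(
    layer = "fc(sigmoid)", out_length = 1L, units = cfg$fc_units,
    width = NA_integer_, pool = NA_integer_)
  rows[[length(rows) + 1]] <- data.frame(
    layer = "output(sigmoid)", out_length = 1L, units = cfg$n_tasks,
    width = NA_integer_, pool = NA_integer_)
  do.call(rbind, rows)
}

#' @export
print.sequence_model <- function(x, ...) {
  cat(sprintf("sequence_model (%s): %d tasks, context %d bp\n",
              if (x$fitted) "fitted" else "unfitted",
              x$config$n_tasks, x$config$context_size))
  print(model_layers(x))
  invisible(x)
}

.as_cube <- function(X, context_size) {
  if (is.matrix(X)) X <- array(X, dim = c(nrow(X), ncol(X), 1L))
  if (dim(X)[1] != context_size || dim(X)[2] != 4) {
    stop("input must be ", context_size, " x 4 (x N); got ",
         paste(dim(X), collapse = " x "))
  }
  X
}

#' Train a sequence CNN
#'
#' Minimizes multi-task binary cross entropy with minibatch RMSprop;
#' L1/L2 penalties act on the fully connected layer weights only. One
#' validation check is run per epoch; training stops at `max_epochs` or
#' after `patience` checks without validation-loss improvement, and the
#' best-validation parameters are restored. Fixed
#' `config$rng_seed` gives bit-identical runs on the same machine.
#'
#' @param model an unfitted (or fitted, to continue) `sequence_model`.
#' @param dataset a partitioned [encode_dataset()] result.
#' @param verbose print per-epoch losses.
#' @return the fitted `sequence_model` with `history` (per-epoch train
#'   loss, validation loss, validation accuracy).
#' @export
train_model <- function(model, dataset, verbose = FALSE) {
  if (is.null(dataset$partition)) stop("dataset must be partitioned first")
  tr <- dataset_partition(dataset, "train")
  va <- dataset_partition(dataset, "val")
  if (dim(tr$X)[3] == 0 || dim(va$X)[3] == 0) {
    stop("empty train or validation partition")
  }
  cfg <- model$config
  n_tr <- dim(tr$X)[3]
  old <- .Random.seed_save()
  set.seed(cfg$rng_seed + 1L)
  order <- t(vapply(seq_len(cfg$max_epochs), function(e) sample.int(n_tr),
                    integer(n_tr)))
  .Random.seed_restore(old)
  storage.mode(tr$Y) <- "double"
  storage.mode(va$Y) <- "double"
  res <- .cnn_train_cpp(model$params, tr$X, tr$Y, va$X, va$Y, order,
                        cfg$learning_rate, cfg$batch_size, cfg$l1, cfg$l2,
                        cfg$max_epochs, cfg$patience, 0.9, 1e-8, verbose)
  model$params <- res$params
  model$fitted <- TRUE
  model$task_names <- colnames(dataset$Y)
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              train_loss = res$train_loss,
                              val_loss = res$val_loss,
                              val_accuracy = res$val_accuracy)
  model$best_epoch <- res$best_epoch
  model
}

#' Predict modification probabilities
#'
#' Inference mode: batch normalization uses running statistics, so output
#' is deterministic and independent of batch composition. Optional filter
#' nullification replaces named layer-1 post-ReLU activation maps with
#' constants.
#'
#' @param object fitted `sequence_model`.
#' @param X `context_size` x 4 matrix or `context_size` x 4 x N array.
#' @param nullify optional list with `filters` (1-based layer-1 indices)
#'   and `values` (replacement constants, recycled).
#' @param batch internal batch size.
#' @param ... unused.
#' @return N x n_tasks matrix of probabilities in (0, 1).
#' @export
predict.sequence_model <- function(object, X, nullify = NULL,
                                   batch = 256, ...) {
  if (!object$fitted) stop("model is not fitted")
  X <- .as_cube(X, object$config$context_size)
  if (is.null(nullify) || length(nullify$filters) == 0) {
    idx <- integer(0)
    vals <- numeric(0)
  } else {
    idx <- as.integer(nullify$filters)
    if (any(idx < 1 | idx > object$config$conv_filters[1])) {
      stop("unknown layer-1 filter index")
    }
    vals <- rep_len(as.numeric(nullify$values), length(idx))
    idx <- idx - 1L
  }
  P <- .cnn_predict_cpp(object$params, X, idx, vals, batch)
  colnames(P) <- object$task_names
  P
}

#' Per-task classification accuracy
#'
#' `(TP + TN) / (TP + FN + TN + FP)` per task at the given probability
#' cutoff.
#'
#' @param labels N x n_tasks binary matrix (or vector).
#' @param probs matching probability matrix.
#' @param cutoff positive-call threshold (default 0.5).
#' @return list with `per_task` (named numeric) and `mean`.
#' @export
accuracy <- function(labels, probs, cutoff = 0.5) {
  labels <- as.matrix(labels)
  probs <- as.matrix(probs)
  if (length(labels) == 0) stop("empty input")
  if (!all(dim(labels) == dim(probs))) stop("shape mismatch")
  calls <- probs >= cutoff
  per_task <- colMeans(calls == (labels == 1))
  if (!is.null(colnames(labels))) names(per_task) <- colnames(labels)
  list(per_task = per_task, mean = mean(per_task))
}

#' Per-task ROC AUC
#'
#' AUC via the rank-statistic (Mann-Whitney) formulation with midranks
#' for ties. Tasks with a single class get `NA` and a warning.
#'
#' @param labels binary matrix or vector.
#' @param probs matching score matrix.
#' @return list with `per_task` AUCs, `mean` over defined tasks, and
#'   `roc` (per-task data frames of ROC points `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, probs) {
  labels <- as.matrix(labels)
  probs <- as.matrix(probs)
  if (!all(dim(labels) == dim(probs))) stop("shape mismatch")
  aucs <- numeric(ncol(labels))
  rocs <- vector("list", ncol(labels))
  for (t in seq_len(ncol(labels))) {
    y <- labels[, t] == 1
    s <- probs[, t]
    n1 <- sum(y)
    n0 <- sum(!y)
    if (n1 == 0 || n0 == 0) {
      warning("task ", t, " has a single class; AUC undefined")
      aucs[t] <- NA_real_
      rocs[[t]] <- data.frame(fpr = numeric(), tpr = numeric())
      next
    }
    r <- rank(s)                       # midranks
    aucs[t] <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(y[ord])
    fp <- cumsum(!y[ord])
    keep <- c(diff(s[ord]) != 0, TRUE)  # one point per distinct score
    rocs[[t]] <- data.frame(fpr = c(0, fp[keep] / n0),
                            tpr = c(0, tp[keep] / n1))
  }
  if (!is.null(colnames(labels))) {
    names(aucs) <- colnames(labels)
    names(rocs) <- colnames(labels)
  }
  list(per_task = aucs, mean = mean(aucs, na.rm = TRUE), roc = rocs)
}

#' Evaluate a fitted model on a dataset partition
#'
#' @param model fitted `sequence_model`.
#' @param dataset partitioned dataset.
#' @param split partition to evaluate (default `"test"`).
#' @param cutoff probability cutoff for the confusion counts.
#' @return list with per-task confusion counts (`TP`, `TN`, `FP`, `FN`),
#'   `accuracy`, `auc`, means and `n`.
#' @export
evaluate_model <- function(model, dataset, split = "test", cutoff = 0.5) {
  part <- dataset_partition(dataset, split)
  P <- predict(model, part$X)
  calls <- P >= cutoff
  Y <- part$Y == 1
  tnames <- colnames(part$Y)
  if (is.null(tnames)) tnames <- paste0("task", seq_len(ncol(part$Y)))
  conf <- data.frame(task = tnames,
                     TP = colSums(calls & Y), TN = colSums(!calls & !Y),
                     FP = colSums(calls & !Y), FN = colSums(!calls & Y))
  acc <- accuracy(part$Y, P, cutoff)
  auc <- roc_auc(part$Y, P)
  list(confusion = conf, accuracy = acc$per_task,
       mean_accuracy = acc$mean, auc = auc$per_task,
       mean_auc = auc$mean, roc = auc$roc, n = nrow(P))
}

#' FC-layer regularization penalty of a model
#' @param model `sequence_model`.
#' @param l1,l2 regularization weights.
#' @return `l1 * sum(|W_fc|) + l2 * sum(W_fc^2)`.
#' @export
fc_penalty <- function(model, l1, l2) {
  W <- model$params$fc$W
  l1 * sum(abs(W)) + l2 * sum(W^2)
}

#' Binary cross entropy
#' @param probs probability matrix.
#' @param labels matching binary matrix.
#' @return mean BCE over all entries.
#' @export
binary_cross_entropy <- function(probs, labels) {
  p <- pmin(pmax(as.matrix(probs), 1e-12), 1 - 1e-12)
  y <- as.matrix(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Default hyper-parameter grid for random search
#'
#' Six paired L1/L2 rows (L1 1e-07..6e-07 with L2 2e-08..8e-07), patience
#' 5000, max 20 epochs, batch 128, crossed with overlap fractions
#' 0.5-0.9.
#'
#' @return data frame of configurations (one row per trial candidate).
#' @export
default_trial_grid <- function() {
  rows <- data.frame(
    l1 = c(1e-07, 2e-07, 3e-07, 4e-07, 5e-07, 6e-07),
    l2 = c(2e-08, 4e-08, 8e-08, 2e-07, 4e-07, 8e-07),
    patience = 5000L, max_epochs = 20L, batch_size = 128L)
  grid <- merge(rows, data.frame(overlap_fraction = seq(0.5, 0.9, 0.1)))
  grid[order(grid$l1, grid$overlap_fraction), , drop = FALSE]
}

#' Random hyper-parameter search
#'
#' Samples trials without replacement from a configuration grid, trains a
#' model per trial and returns the configuration with the highest mean
#' validation accuracy.
#'
#' @param data an `encoded_dataset`, or a named list of datasets keyed by
#'   overlap fraction (e.g. `"0.5"`) when the grid crosses fractions.
#' @param trial_grid data frame of candidate rows (default
#'   [default_trial_grid()], restricted to available fractions).
#' @param n_trials number of trials; capped at the grid size with a
#'   warning.
#' @param seed sampling seed.
#' @param base_config `model_config` supplying all non-grid fields.
#' @param verbose print trial progress.
#' @return list with `best_config`, `best_model` and `trials` (the trial
#'   table with mean validation accuracy per trial).
#' @export
random_search <- function(data, trial_grid = NULL, n_trials = 6, seed = 1,
                          base_config, verbose = FALSE) {
  if (inherits(data, "encoded_dataset")) {
    datasets <- list(data)
    names(datasets) <- format(data$overlap_fraction)
  } else {
    datasets <- data
  }
  if (is.null(trial_grid)) {
    trial_grid <- default_trial_grid()
    trial_grid <- trial_grid[
      format(trial_grid$overlap_fraction) %in% names(datasets), ,
      drop = FALSE]
  }
  if (nrow(trial_grid) == 0) stop("empty trial grid")
  if (n_trials > nrow(trial_grid)) {
    warning("n_trials exceeds grid size; capped at ", nrow(trial_grid))
    n_trials <- nrow(trial_grid)
  }
  old <- .Random.seed_save()
  set.seed(seed)
  pick <- sample.int(nrow(trial_grid), n_trials)
  .Random.seed_restore(old)
  trials <- trial_grid[pick, , drop = FALSE]
  trials$val_accuracy <- NA_real_
  best <- NULL
  for (i in seq_len(n_trials)) {
    cfg <- base_config
    cfg$l1 <- trials$l1[i]
    cfg$l2 <- trials$l2[i]
    cfg$patience <- as.integer(trials$patience[i])
    cfg$max_epochs <- as.integer(trials$max_epochs[i])
    cfg$batch_size <- as.integer(trials$batch_size[i])
    cfg$overlap_fraction <- trials$overlap_fraction[i]
    ds <- datasets[[format(cfg$overlap_fraction)]]
    if (is.null(ds)) stop("no dataset for overlap fraction ",
                          cfg$overlap_fraction)
    fit <- train_model(build_model(cfg), ds)
    va <- dataset_partition(ds, "val")
    trials$val_accuracy[i] <-
      accuracy(va$Y, predict(fit, va$X))$mean
    if (verbose) {
      message(sprintf("trial %d/%d: l1=%g l2=%g frac=%.1f val_acc=%.4f",
                      i, n_trials, cfg$l1, cfg$l2, cfg$overlap_fraction,
                      trials$val_accuracy[i]))
    }
    if (is.null(best) || trials$val_accuracy[i] > best$val_accuracy) {
      best <- list(config = cfg, model = fit,
                   val_accuracy = trials$val_accuracy[i])
    }
  }
  list(best_config = best$config, best_model = best$model,
       trials = trials)
}

#' Save a model checkpoint
#'
#' Writes a directory with `config.json` (architecture, hyperparameters,
#' format version) and `parameters.rds` (weights, history).
#'
#' @param model fitted or unfitted `sequence_model`.
#' @param path checkpoint directory (created).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(model$config)
  jsonlite::write_json(
    list(format_version = 1L, config = cfg, fitted = model$fitted,
         task_names = model$task_names),
    file.path(path, "config.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(list(params = model$params, history = model$history,
               best_epoch = model$best_epoch),
          file.path(path, "parameters.rds"), version = 2)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path checkpoint directory.
#' @return a `sequence_model`.
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config[names(meta$config) %in%
                                             names(formals(model_config))])
  blob <- readRDS(file.path(path, "parameters.rds"))
  model <- build_model(cfg)
  model$params <- blob$params
  model$history <- blob$history
  model$best_epoch <- blob$best_epoch
  model$fitted <- isTRUE(meta$fitted)
  model$task_names <- meta$task_names
  model
}
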