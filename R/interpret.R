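# Interpretation of the first convolutional layer: filter-to-PWM
# extraction, nullification influence scores, and pairwise interaction
# coefficients.

#' Extraction configuration for filter-to-PWM conversion
#'
#' @param beta_grid candidate activation-threshold ratios (each in (0,1));
#'   default 0.3 to 0.8 in steps of 0.1.
#' @param pseudocount per-base pseudocount when normalizing k-mer counts.
#' @return an `extraction_config` list.
#' @export
extraction_config <- function(beta_grid = seq(0.3, 0.8, by = 0.1),
                              pseudocount = 0.5) {
  if (any(beta_grid <= 0 | beta_grid >= 1)) {
    stop("beta values must be in (0, 1)")
  }
  structure(list(beta_grid = beta_grid, pseudocount = pseudocount),
            class = "extraction_config")
}

#' Post-ReLU first-layer activation maps
#'
#' The layer-1 activation of filter `k` at position `i` is the ReLU of the
#' filter's convolution with the k-mer starting at `i`; it is computed
#' before batch normalization and pooling.
#'
#' @param model fitted `sequence_model`.
#' @param X `context_size` x 4 (x N) input.
#' @return `L_out` x `n_filters` x N array of nonnegative activations.
#' @export
first_layer_activations <- function(model, X) {
  if (!model$fitted) stop("model is not fitted")
  X <- .as_cube(X, model$config$context_size)
  .cnn_layer1_acts_cpp(model$params, X)
}

#' Per-filter activation statistics over a test set
#'
#' @param model fitted `sequence_model`.
#' @param X test sequences (`context_size` x 4 x N array).
#' @param batch internal batch size.
#' @return list with per-filter `min`, `max` and `mean` post-ReLU layer-1
#'   activation over all positions of all sequences.
#' @export
activation_stats <- function(model, X, batch = 256) {
  if (!model$fitted) stop("model is not fitted")
  X <- .as_cube(X, model$config$context_size)
  st <- .cnn_acts_stats_cpp(model$params, X, batch)
  list(min = as.numeric(st$min), max = as.numeric(st$max),
       mean = as.numeric(st$mean))
}

#' Activation threshold for k-mer selection
#'
#' `(alpha_max - alpha_min) * beta`, where the alphas are the extreme
#' activations of a filter over all positions of all test sequences.
#'
#' @param alpha_max,alpha_min maximum and minimum activations.
#' @param beta ratio constant in (0, 1).
#' @return the threshold.
#' @export
activation_threshold <- function(alpha_max, alpha_min, beta) {
  if (any(beta <= 0 | beta >= 1)) stop("beta must be in (0, 1)")
  if (any(alpha_max < alpha_min)) stop("alpha_max must be >= alpha_min")
  (alpha_max - alpha_min) * beta
}

#' Extract PWMs from first-layer filters
#'
#' For each filter and each candidate beta, collects every k-mer of the
#' test set whose activation exceeds the threshold
#' `(alpha_max - alpha_min) * beta`, accumulates the one-hot submatrices
#' into a count matrix, adds the pseudocount and normalizes. The beta
#' giving the highest information content wins; filters whose best PWM
#' has zero information content (or no k-mer above threshold at any
#' beta) yield `NULL`.
#'
#' @param model fitted `sequence_model`.
#' @param X test sequences (`context_size` x 4 x N array).
#' @param config an [extraction_config()].
#' @param filters 1-based filter indices (default all layer-1 filters).
#' @param batch internal batch size.
#' @param name_prefix motif name prefix (default `"filter"`).
#' @return named list (one element per requested filter) of [pwm_motif()]
#'   objects or `NULL` for discarded filters.
#' @export
extract_pwms <- function(model, X, config = extraction_config(),
                         filters = NULL, batch = 256,
                         name_prefix = "filter") {
  if (!model$fitted) stop("model is not fitted")
  X <- .as_cube(X, model$config$context_size)
  if (dim(X)[3] == 0) stop("empty test set")
  n_filters <- model$config$conv_filters[1]
  if (is.null(filters)) filters <- seq_len(n_filters)
  st <- activation_stats(model, X, batch)
  thr <- outer(config$beta_grid, st$max - st$min) # n_beta x n_filters
  res <- .cnn_pwm_counts_cpp(model$params, X, thr, batch)
  w <- model$config$conv_widths[1]
  out <- vector("list", length(filters))
  names(out) <- sprintf("%s%03d", name_prefix, filters)
  for (fi in seq_along(filters)) {
    k <- filters[fi]
    counts <- res$counts[[k]]          # w x 4 x n_beta
    nsites <- res$n_sites[, k]
    best <- NULL
    for (b in seq_along(config$beta_grid)) {
      if (nsites[b] == 0) next
      freq <- (counts[, , b] + config$pseudocount) /
        (nsites[b] + 4 * config$pseudocount)
      ic <- information_content(freq)
      if (is.null(best) || ic > best$ic) {
        best <- list(freq = freq, ic = ic,
                     beta = config$beta_grid[b], n = nsites[b])
      }
    }
    if (is.null(best) || best$ic <= 0) {
      out[fi] <- list(NULL)
    } else {
      out[[fi]] <- pwm_motif(best$freq, names(out)[fi],
                             n_sites = best$n,
                             beta_used = best$beta,
                             source = sprintf("filter%03d", k))
    }
  }
  out
}

#' Trim uninformative flanking columns from a PWM
#'
#' Removes leading and trailing columns whose information content is
#' below `min_ic` bits. Extracted filter PWMs span the full filter width,
#' so a learned motif is usually flanked by near-uniform columns that
#' dilute column-correlation comparisons; trimming isolates the motif.
#'
#' @param motif a [pwm_motif()].
#' @param min_ic per-column information content cutoff in bits
#'   (default 0.25).
#' @param min_width minimum retained width (default 4); if fewer
#'   informative columns remain, the `min_width` consecutive columns with
#'   the highest total information content are kept.
#' @return a trimmed [pwm_motif()].
#' @export
trim_pwm <- function(motif, min_ic = 0.25, min_width = 4) {
  f <- motif$freq
  ic <- apply(f, 1, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  keep <- which(ic >= min_ic)
  if (length(keep) == 0 || max(keep) - min(keep) + 1 < min_width) {
    w <- min(min_width, nrow(f))
    tot <- vapply(seq_len(nrow(f) - w + 1), function(s) {
      sum(ic[s:(s + w - 1)])
    }, numeric(1))
    s <- which.max(tot)
    lo <- s; hi <- s + w - 1
  } else {
    lo <- min(keep); hi <- max(keep)
  }
  out <- motif
  out$freq <- f[lo:hi, , drop = FALSE]
  out$info_content <- information_content(out$freq)
  out
}

#' Information content of a PWM (bits)
#'
#' `sum over columns of (2 + sum_b p log2 p)` with `0 log 0 = 0`; uniform
#' background.
#'
#' @param pwm a [pwm_motif()] or a width x 4 probability matrix.
#' @return information content in bits (>= 0 up to rounding).
#' @export
information_content <- function(pwm) {
  m <- if (inherits(pwm, "pwm_motif")) pwm$freq else as.matrix(pwm)
  plogp <- ifelse(m > 0, m * log2(m), 0)
  max(0, sum(2 + rowSums(plogp)))
}

#' Nullification constants for layer-1 filters
#'
#' The replacement value for a filter is the mean of its post-ReLU
#' activations over all positions of all test sequences.
#'
#' @param model fitted `sequence_model`.
#' @param X test sequences.
#' @return numeric vector, one value per layer-1 filter.
#' @export
filter_null_values <- function(model, X) {
  activation_stats(model, X)$mean
}

#' Nullified view of a model
#'
#' Returns a copy of the model whose predictions replace the named
#' layer-1 filters' activation maps by constants (their mean test-set
#' activation unless given). The original model is untouched;
#' `nullify(model, integer(0), ...)` is the identity view.
#'
#' @param model fitted `sequence_model`.
#' @param filters 1-based layer-1 filter indices (possibly empty).
#' @param X test sequences used for the mean activations (ignored when
#'   `values` is given).
#' @param values optional explicit replacement constants.
#' @return a `sequence_model` whose `predict` applies the nullification.
#' @export
nullify <- function(model, filters, X = NULL, values = NULL) {
  filters <- as.integer(filters)
  if (any(filters < 1 | filters > model$config$conv_filters[1])) {
    stop("unknown layer-1 filter index")
  }
  if (length(filters) > 0 && is.null(values)) {
    if (is.null(X)) stop("need X or explicit values")
    values <- filter_null_values(model, X)[filters]
  }
  model$nullified <- list(filters = filters,
                          values = if (length(filters)) values else numeric(0))
  model
}

#' @rdname nullify
#' @param object a nullified model view.
#' @param ... passed on.
#' @export
predict_nullified <- function(object, X, ...) {
  predict(object, X, nullify = object$nullified, ...)
}

#' Influence of layer-1 filters on the model's predictions
#'
#' For each filter, predictions are recomputed with the filter's
#' activation map replaced by its mean test-set activation; the per-task
#' influence is the sum over test sequences of the squared change in the
#' task's predicted probability. The `total` score (used to rank motifs)
#' is the across-task sum.
#'
#' @param model fitted `sequence_model`.
#' @param X test sequences.
#' @param filters 1-based filter indices (default all).
#' @param null_values optional precomputed [filter_null_values()].
#' @param batch internal batch size.
#' @return list with `per_task` (filters x tasks influence matrix),
#'   `total` (across-task sum), `per_sequence_mean` (total / N),
#'   `n_sequences` and `null_values`.
#' @export
filter_influences <- function(model, X, filters = NULL,
                              null_values = NULL, batch = 256) {
  if (!model$fitted) stop("model is not fitted")
  X <- .as_cube(X, model$config$context_size)
  n <- dim(X)[3]
  if (n == 0) stop("empty test set")
  if (is.null(filters)) filters <- seq_len(model$config$conv_filters[1])
  if (is.null(null_values)) null_values <- filter_null_values(model, X)
  sets <- lapply(filters, function(k) as.integer(k - 1L))
  res <- .cnn_nullify_predict_cpp(model$params, X, null_values, sets,
                                  batch)
  per_task <- t(vapply(seq_along(sets), function(q) {
    colSums((res$P_pre - res$P_aft[[q]])^2)
  }, numeric(ncol(res$P_pre))))
  rownames(per_task) <- sprintf("filter%03d", filters)
  colnames(per_task) <- model$task_names
  list(per_task = per_task, total = rowSums(per_task),
       per_sequence_mean = rowSums(per_task) / n,
       n_sequences = n, null_values = null_values, filters = filters)
}

#' Influence of one filter (or filter set) on one task
#'
#' @param model fitted `sequence_model`.
#' @param filter_k 1-based filter index (or vector, nullified jointly).
#' @param X test sequences.
#' @param task task name, index, or `"all"` (across-task sum).
#' @param null_values optional precomputed constants.
#' @return list (`filter`, `task`, `influence`, `per_task`,
#'   `n_sequences`).
#' @export
influence <- function(model, filter_k, X, task = "all",
                      null_values = NULL) {
  X <- .as_cube(X, model$config$context_size)
  if (dim(X)[3] == 0) stop("empty test set")
  if (is.null(null_values)) null_values <- filter_null_values(model, X)
  res <- .cnn_nullify_predict_cpp(model$params, X, null_values,
                                  list(as.integer(filter_k - 1L)), 256)
  d2 <- (res$P_pre - res$P_aft[[1]])^2
  per_task <- colSums(d2)
  names(per_task) <- model$task_names
  val <- if (identical(task, "all")) sum(per_task) else {
    if (is.character(task)) per_task[[task]] else per_task[[task]]
  }
  list(filter = filter_k, task = task, influence = val,
       per_task = per_task, n_sequences = dim(X)[3])
}

#' Motif-by-task influence table
#'
#' Rows are motifs ranked by their maximum per-task influence (descending;
#' ties by motif id), columns are tasks; at most `top_n` rows.
#'
#' @param influences result of [filter_influences()].
#' @param top_n maximum number of rows (default 100).
#' @param motif_names optional row names (e.g. extracted motif names);
#'   rows with `NA` names (discarded filters) are dropped.
#' @return numeric matrix of influence scores.
#' @export
influence_heatmap_table <- function(influences, top_n = 100,
                                    motif_names = NULL) {
  m <- influences$per_task
  if (!is.null(motif_names)) {
    keep <- !is.na(motif_names)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- motif_names[keep]
  }
  rmax <- apply(m, 1, max)
  ord <- order(-rmax, rownames(m))
  m[ord[seq_len(min(top_n, nrow(m)))], , drop = FALSE]
}

#' Top motifs by influence score
#'
#' @param scores named numeric vector of influence scores (e.g.
#'   `filter_influences(...)$total`).
#' @param k number of motifs returned (default 50).
#' @return names of the top-`k` motifs, sorted by descending score with
#'   ties broken by motif id.
#' @export
top_motifs <- function(scores, k = 50) {
  ord <- order(-scores, names(scores))
  names(scores)[ord[seq_len(min(k, length(scores)))]]
}

#' Pairwise interaction coefficients between filters
#'
#' For each sampled test sequence, the squared change of the task's
#' predicted probability is computed under nullification of filter i
#' alone, filter j alone, and both jointly. The joint change is regressed
#' on the single changes and their product without intercept,
#' `dP_ij = alpha dP_i + beta dP_j + gamma (dP_i * dP_j)`;
#' `gamma` is the interaction coefficient and its two-sided t-test
#' p-value is reported.
#'
#' @param model fitted `sequence_model`.
#' @param pairs two-column matrix of 1-based filter index pairs (or a
#'   length-2 vector for a single pair).
#' @param task task name or index the probabilities refer to.
#' @param X test sequences to sample from.
#' @param n_sequences sequences sampled (default 2000; sampled with
#'   replacement when the test set is smaller).
#' @param seed sampling seed.
#' @param null_values optional precomputed constants.
#' @param batch internal batch size.
#' @return data frame with one row per pair: `i`, `j`, `task`, `alpha`,
#'   `beta`, `gamma`, `p_value`, `n_sequences`, `seed`, `degenerate`
#'   (TRUE when a regressor is all-zero and no fit is possible).
#' @export
interaction_coefficients <- function(model, pairs, task, X,
                                     n_sequences = 2000, seed = 1,
                                     null_values = NULL, batch = 256) {
  if (!model$fitted) stop("model is not fitted")
  if (is.vector(pairs) && length(pairs) == 2) {
    pairs <- matrix(pairs, ncol = 2)
  }
  pairs <- as.matrix(pairs)
  if (any(pairs[, 1] == pairs[, 2])) stop("pair members must differ")
  if (n_sequences < 10) stop("need at least 10 sequences")
  X <- .as_cube(X, model$config$context_size)
  n_avail <- dim(X)[3]
  old <- .Random.seed_save()
  set.seed(seed)
  idx <- sample.int(n_avail, n_sequences, replace = n_sequences > n_avail)
  .Random.seed_restore(old)
  Xs <- X[, , idx, drop = FALSE]
  if (is.null(null_values)) null_values <- filter_null_values(model, X)
  t_idx <- if (is.character(task)) match(task, model$task_names) else task
  if (is.na(t_idx)) stop("unknown task: ", task)

  singles <- sort(unique(as.vector(pairs)))
  sets <- c(lapply(singles, function(k) as.integer(k - 1L)),
            lapply(seq_len(nrow(pairs)), function(r) {
              as.integer(sort(pairs[r, ]) - 1L)
            }))
  res <- .cnn_nullify_predict_cpp(model$params, Xs, null_values, sets,
                                  batch)
  dsq <- lapply(res$P_aft, function(Pa) {
    (res$P_pre[, t_idx] - Pa[, t_idx])^2
  })
  names(dsq)[seq_along(singles)] <- paste0("s", singles)

  out <- lapply(seq_len(nrow(pairs)), function(r) {
    di <- dsq[[paste0("s", pairs[r, 1])]]
    dj <- dsq[[paste0("s", pairs[r, 2])]]
    dij <- dsq[[length(singles) + r]]
    prod_ij <- di * dj
    if (all(di == 0) || all(dj == 0) || all(prod_ij == 0)) {
      return(data.frame(i = pairs[r, 1], j = pairs[r, 2],
                        task = model$task_names[t_idx],
                        alpha = NA_real_, beta = NA_real_,
                        gamma = NA_real_, p_value = NA_real_,
                        n_sequences = n_sequences, seed = seed,
                        degenerate = TRUE))
    }
    fit <- lm(dij ~ 0 + di + dj + prod_ij)
    sm <- summary(fit)$coefficients
    gp <- if ("prod_ij" %in% rownames(sm)) {
      sm["prod_ij", c(1, 4)]
    } else c(NA_real_, NA_real_)
    data.frame(i = pairs[r, 1], j = pairs[r, 2],
               task = model$task_names[t_idx],
               alpha = unname(coef(fit)["di"]),
               beta = unname(coef(fit)["dj"]),
               gamma = unname(gp[1]), p_value = unname(gp[2]),
               n_sequences = n_sequences, seed = seed,
               degenerate = FALSE)
  })
  do.call(rbind, out)
}
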