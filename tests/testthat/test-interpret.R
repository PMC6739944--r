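# Filter-to-PWM extraction, nullification influence and interactions.

test_that("activation_threshold implements (a_max - a_min) * beta", {
  expect_equal(activation_threshold(1, 0, 0.5), 0.5)
  expect_equal(activation_threshold(2, 0.5, 0.4), 0.6)
  expect_equal(activation_threshold(3, 3, 0.7), 0)
  expect_error(activation_threshold(1, 0, 0), "beta")
  expect_error(activation_threshold(1, 0, 1), "beta")
  expect_error(activation_threshold(0, 1, 0.5), "alpha_max")
})

test_that("extraction_config validates the beta grid", {
  ec <- extraction_config()
  expect_equal(ec$beta_grid, seq(0.3, 0.8, 0.1))
  expect_equal(ec$pseudocount, 0.5)
  expect_error(extraction_config(beta_grid = c(0.5, 1)), "beta")
})

test_that("first-layer activations match direct convolution arithmetic", {
  # engineered 1-filter model: weights = log-odds of a sharp PWM
  pwm <- consensus_pwm("TGACG", 0.9)
  m <- engineered_model(list(pwm), L = 30)
  s <- "ACGTTGACGAAATGCATGCATTGACGTTTT"
  X <- one_hot(s)
  acts <- first_layer_activations(m, X)
  # direct evaluation: ReLU of the position-wise weighted sum
  W <- log2(pmax(pwm, 1e-3) / 0.25)
  direct <- vapply(seq_len(30 - 5 + 1), function(i) {
    max(0, sum(W * one_hot(substr(s, i, i + 4))))
  }, numeric(1))
  expect_equal(as.numeric(acts[, 1, 1]), direct, tolerance = 1e-12)
  expect_true(all(acts >= 0))
  # all-N input: position-independent activations
  actsN <- first_layer_activations(m, one_hot(strrep("N", 30)))
  expect_lt(diff(range(actsN)), 1e-12)
  m2 <- m; m2$fitted <- FALSE
  expect_error(first_layer_activations(m2, X), "not fitted")
})

test_that("extract_pwms equals a brute-force k-mer counting oracle", {
  # engineered filter = exact log-odds of a planted PWM
  pwm <- consensus_pwm("TGACGTCAT", 0.9)
  m <- engineered_model(list(pwm), L = 100)
  set.seed(31)
  n <- 120
  X <- array(0, dim = c(100, 4, n))
  for (i in seq_len(n)) {
    X[, , i] <- one_hot(toy_seq(100, if (i %% 2) pwm else NULL))
  }
  ec <- extraction_config()
  out <- extract_pwms(m, X, ec)
  expect_length(out, 1)
  got <- out[[1]]
  expect_s3_class(got, "pwm_motif")

  # brute-force oracle: scan every k-mer, threshold, count, normalize
  w <- 9
  W <- log2(pmax(pwm, 1e-3) / 0.25)
  acts <- matrix(0, 100 - w + 1, n)
  for (i in seq_len(n)) {
    for (p in seq_len(100 - w + 1)) {
      acts[p, i] <- max(0, sum(W * X[p:(p + w - 1), , i]))
    }
  }
  amax <- max(acts); amin <- min(acts)
  best <- NULL
  for (beta in ec$beta_grid) {
    thr <- (amax - amin) * beta
    sel <- which(acts > thr, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    counts <- matrix(0, w, 4)
    for (r in seq_len(nrow(sel))) {
      counts <- counts + X[sel[r, 1]:(sel[r, 1] + w - 1), , sel[r, 2]]
    }
    freq <- (counts + 0.5) / (nrow(sel) + 2)
    ic <- information_content(freq)
    if (is.null(best) || ic > best$ic) {
      best <- list(freq = freq, ic = ic, beta = beta, n = nrow(sel))
    }
  }
  expect_equal(unname(got$freq), unname(best$freq), tolerance = 1e-9)
  expect_equal(got$beta_used, best$beta)
  expect_equal(got$n_sites, best$n)
  # recovered PWM close to the planted one (per-column total variation)
  tv <- rowSums(abs(got$freq - pwm)) / 2
  expect_true(all(tv <= 0.1))
})

test_that("dead and uniform filters are discarded", {
  pwm <- consensus_pwm("TGACG", 0.9)
  m <- engineered_model(list(pwm, pwm), L = 60)
  # make filter 2 dead: large negative bias
  m$params$conv[[1]]$b <- c(0, -1e6)
  set.seed(5)
  X <- array(0, dim = c(60, 4, 30))
  for (i in 1:30) X[, , i] <- one_hot(toy_seq(60, pwm))
  out <- extract_pwms(m, X)
  expect_s3_class(out[[1]], "pwm_motif")
  expect_null(out[[2]])
})

test_that("information content matches the direct formula", {
  expect_equal(information_content(matrix(0.25, 6, 4)), 0)
  one_base <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(information_content(one_base), 2)
  set.seed(17)
  for (i in 1:25) {
    w <- sample(3:12, 1)
    f <- matrix(rgamma(w * 4, 1), w, 4)
    f <- f / rowSums(f)
    direct <- sum(apply(f, 1, function(p) {
      2 + sum(ifelse(p > 0, p * log2(p), 0))
    }))
    expect_equal(information_content(f), max(0, direct),
                 tolerance = 1e-12)
  }
})

test_that("trim_pwm removes uninformative flanks only", {
  core <- consensus_pwm("TGACGTCA", 0.95)
  flank <- matrix(0.25, 4, 4)
  m <- pwm_motif(rbind(flank, core, flank), "padded")
  tr <- trim_pwm(m)
  expect_equal(nrow(tr$freq), 8)
  expect_equal(unname(tr$freq), unname(core))
  # nothing to trim
  tight <- pwm_motif(core, "tight")
  expect_equal(trim_pwm(tight)$freq, tight$freq)
  # all-uniform motif falls back to the min-width window
  u <- pwm_motif(matrix(0.25, 10, 4), "uniform")
  expect_equal(nrow(trim_pwm(u, min_width = 4)$freq), 4)
})

test_that("nullification constants equal the brute-force activation mean", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X[, , 1:40, drop = FALSE]
  nv <- filter_null_values(tm$model, X)
  acts <- first_layer_activations(tm$model, X)
  brute <- apply(acts, 2, mean)
  expect_equal(nv, brute, tolerance = 1e-12)
})

test_that("nullify is the identity for the empty set and flags bad ids", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X[, , 1:10, drop = FALSE]
  m0 <- nullify(tm$model, integer(0))
  expect_identical(predict_nullified(m0, X), predict(tm$model, X))
  expect_error(nullify(tm$model, 99), "unknown")
  # nullifying a filter changes predictions unless it is dead
  nv <- filter_null_values(tm$model, X)
  m1 <- nullify(tm$model, 1, values = nv[1])
  expect_false(identical(predict_nullified(m1, X),
                         predict(tm$model, X)))
})

test_that("influence is zero iff predictions are unchanged", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X[, , 1:30, drop = FALSE]
  # nullifying with the filter's own constant map: use a dead filter
  m <- tm$model
  # influence of the empty nullification is exactly zero
  r0 <- influence(m, integer(0), X)
  expect_identical(unname(r0$influence), 0)
  # a real filter twice: identical deterministic records
  r1 <- influence(m, 2, X, task = "t1")
  r2 <- influence(m, 2, X, task = "t1")
  expect_identical(r1, r2)
  expect_gte(r1$influence, 0)
  expect_error(influence(m, 1, X[, , 0, drop = FALSE]), "empty")
})

test_that("influence is invariant to test-set ordering", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X[, , 1:24, drop = FALSE]
  nv <- filter_null_values(tm$model, X)
  i1 <- influence(tm$model, 3, X, null_values = nv)
  perm <- sample(24)
  i2 <- influence(tm$model, 3, X[, , perm, drop = FALSE],
                  null_values = nv)
  expect_equal(i1$influence, i2$influence, tolerance = 1e-10)
})

test_that("influence table matches per-filter calls and sorts by row max", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X[, , 1:30, drop = FALSE]
  infl <- filter_influences(tm$model, X, filters = 1:4)
  for (k in 1:4) {
    single <- influence(tm$model, k, X, null_values = infl$null_values)
    expect_equal(unname(infl$per_task[k, ]), unname(single$per_task),
                 tolerance = 1e-10)
    expect_equal(unname(infl$total[k]), unname(sum(single$per_task)))
  }
  hm <- influence_heatmap_table(infl, top_n = 3)
  expect_equal(nrow(hm), 3)
  rmax <- apply(hm, 1, max)
  expect_true(all(diff(rmax) <= 0))
  # fewer motifs than top_n keeps all rows
  expect_equal(nrow(influence_heatmap_table(infl, top_n = 100)), 4)
})

test_that("top_motifs sorts descending with id tie-breaks", {
  sc <- c(b = 2, a = 2, c = 5, d = 1)
  expect_equal(top_motifs(sc, 3), c("c", "a", "b"))
  expect_equal(top_motifs(sc, 10), c("c", "a", "b", "d"))
})

test_that("interaction records are deterministic and symmetric in (i, j)", {
  tm <- toy_model()
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X
  r1 <- interaction_coefficients(tm$model, c(1, 2), "t1", X,
                                 n_sequences = 200, seed = 4)
  r1b <- interaction_coefficients(tm$model, c(1, 2), "t1", X,
                                  n_sequences = 200, seed = 4)
  expect_identical(r1, r1b)
  r2 <- interaction_coefficients(tm$model, c(2, 1), "t1", X,
                                 n_sequences = 200, seed = 4)
  expect_equal(r1$gamma, r2$gamma, tolerance = 1e-10)
  expect_error(interaction_coefficients(tm$model, c(1, 1), "t1", X),
               "differ")
  expect_error(interaction_coefficients(tm$model, c(1, 2), "t1", X,
                                        n_sequences = 5), "at least 10")
  expect_error(interaction_coefficients(tm$model, c(1, 2), "zz", X),
               "unknown task")
})

test_that("a duplicated filter interacts; degenerate regressors are flagged", {
  tm <- toy_model()
  m <- tm$model
  te <- dataset_partition(tm$dataset, "test")
  X <- te$X
  # duplicate filter 1 into filter 2's slot: j is an exact copy of i
  m2 <- m
  C1 <- m$params$conv[[1]]
  m2$params$conv[[1]]$W[, 2] <- C1$W[, 1]
  m2$params$conv[[1]]$b[2] <- C1$b[1]
  m2$params$conv[[1]]$gamma[2] <- C1$gamma[1]
  m2$params$conv[[1]]$beta[2] <- C1$beta[1]
  m2$params$conv[[1]]$run_mean[2] <- C1$run_mean[1]
  m2$params$conv[[1]]$run_var[2] <- C1$run_var[1]
  dup <- interaction_coefficients(m2, c(1, 2), "t1", X,
                                  n_sequences = 300, seed = 2)
  expect_false(dup$degenerate)
  expect_true(abs(dup$gamma) > 0)
  # degenerate case: an engineered model with a constant-output filter
  # whose nullification (by its own constant) changes nothing
  pwm <- consensus_pwm("TGACG", 0.9)
  em <- engineered_model(list(pwm, pwm), L = 60, n_tasks = 1)
  em$params$conv[[1]]$W[, 2] <- 0      # filter 2 constant 0 everywhere
  em$params$conv[[1]]$b[2] <- 0
  set.seed(8)
  Xe <- array(0, dim = c(60, 4, 40))
  for (i in 1:40) Xe[, , i] <- one_hot(toy_seq(60, pwm))
  r <- interaction_coefficients(em, c(1, 2), 1, Xe, n_sequences = 40,
                                seed = 1, null_values = c(1, 0))
  expect_true(r$degenerate)
  expect_true(is.na(r$gamma))
})
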