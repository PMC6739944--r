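# Shared fixtures: everything is generated in code at test time.

.toy_bases <- c("A", "C", "G", "T")

# random DNA string, optionally with one motif instance implanted
toy_seq <- function(L = 200, motif = NULL, rc = FALSE) {
  s <- sample(.toy_bases, L, replace = TRUE)
  if (!is.null(motif)) {
    w <- nrow(motif)
    pos <- sample.int(L - w, 1)
    inst <- vapply(seq_len(w), function(i) {
      sample(.toy_bases, 1, prob = motif[i, ])
    }, character(1))
    if (rc) {
      inst <- rev(chartr("ACGT", "TGCA", inst))
    }
    s[(pos + 1):(pos + w)] <- inst
  }
  paste(s, collapse = "")
}

# two-motif / two-task toy dataset: class 0 has motif A (task 1),
# class 1 has motif B (task 2), class 2 is background
toy_dataset <- function(n = 600, L = 200, seed = 42,
                        dominant = 0.95) {
  set.seed(seed)
  motA <- consensus_pwm("TGACGTCA", dominant)
  motB <- consensus_pwm("GGGACTTT", dominant)
  X <- array(0, dim = c(L, 4, n))
  Y <- matrix(0L, n, 2, dimnames = list(NULL, c("t1", "t2")))
  for (i in seq_len(n)) {
    cls <- i %% 3
    if (cls == 0) {
      X[, , i] <- one_hot(toy_seq(L, motA))
      Y[i, 1] <- 1L
    } else if (cls == 1) {
      X[, , i] <- one_hot(toy_seq(L, motB))
      Y[i, 2] <- 1L
    } else {
      X[, , i] <- one_hot(toy_seq(L))
    }
  }
  ds <- structure(list(X = X, Y = Y,
                       coords = data.frame(chrom = "toy",
                                           start = seq_len(n),
                                           end = seq_len(n) + L),
                       task_names = colnames(Y), partition = NULL,
                       split_seed = NA_integer_, bin_size = L,
                       context_size = L, overlap_fraction = 0.5),
                  class = "encoded_dataset")
  split_dataset(ds, seed = 7)
}

toy_config <- function(n_tasks = 2, L = 200, ...) {
  model_config(n_tasks = n_tasks, conv_filters = c(8, 4, 4),
               conv_widths = c(11, 5, 3), pool_sizes = c(4, 4, 8),
               fc_units = 8, context_size = L, batch_size = 16,
               learning_rate = 0.01, max_epochs = 4, rng_seed = 3, ...)
}

# fitted toy model, trained once per session and cached
.toy_cache <- new.env(parent = emptyenv())

toy_model <- function() {
  if (is.null(.toy_cache$model)) {
    ds <- toy_dataset()
    .toy_cache$dataset <- ds
    .toy_cache$model <- train_model(build_model(toy_config()), ds)
  }
  list(model = .toy_cache$model, dataset = .toy_cache$dataset)
}

# hand-built single-block model whose layer-1 filters are the log-odds of
# given PWMs (useful as an engineered, non-trained oracle model)
engineered_model <- function(pwm_list, L = 200, fc_units = 4,
                             n_tasks = 1, pool = NULL) {
  wmax <- max(vapply(pwm_list, nrow, integer(1)))
  if (is.null(pool)) pool <- L - wmax + 1      # global max pool
  pad <- function(S) rbind(S, matrix(0, wmax - nrow(S), 4))
  W <- vapply(pwm_list, function(f) {
    as.numeric(t(pad(log2(pmax(f, 1e-3) / 0.25))))
  }, numeric(wmax * 4))
  C <- length(pwm_list)
  cfg <- model_config(n_tasks = n_tasks, conv_filters = C,
                      conv_widths = wmax, pool_sizes = pool,
                      fc_units = fc_units, context_size = L, rng_seed = 1)
  m <- build_model(cfg)
  m$params$conv[[1]]$W <- W
  m$params$conv[[1]]$b <- rep(0, C)
  m$fitted <- TRUE
  m$task_names <- paste0("task", seq_len(n_tasks))
  m
}

# small synthetic study spec that keeps pipeline tests fast
mini_spec <- function(...) {
  grammar_spec(chrom_sizes = c(chrA = 150000, chrB = 150000),
               peaks_per_track = 60, n_blacklist = 2,
               blacklist_length = 2000, ...)
}

expect_file_identical <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)),
                   info = paste("files differ:", basename(a)))
}
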