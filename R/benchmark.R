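# Reproducible desk-scale benchmark: simulate a planted-motif study,
# build the dataset, train the reduced cell model, and interpret it.
# This is the study the acceptance checks and the worked examples run.

#' Desk-scale model configuration
#'
#' The reduced configuration used for desk-scale studies: 32/16/16
#' convolution filters, near-global final pooling (4/4/12), 32 fully
#' connected units, RMSprop at learning rate 0.01 on minibatches of 16,
#' at most 10 epochs. See the methods vignette for the rationale.
#'
#' @param n_tasks number of tasks.
#' @param seed RNG seed.
#' @param ... overrides passed to [model_config()].
#' @return a `model_config`.
#' @export
desk_config <- function(n_tasks, seed = 1, ...) {
  model_config(n_tasks = n_tasks, conv_filters = c(32, 16, 16),
               conv_widths = c(19, 11, 7), pool_sizes = c(4, 4, 12),
               fc_units = 32, learning_rate = 0.01, batch_size = 16,
               max_epochs = 10, rng_seed = seed, ...)
}

#' Run the planted-motif benchmark study
#'
#' Generates a synthetic epigenome bundle, consolidates the first cell
#' type's peak tracks (q/length filter, blacklist removal, two-replicate
#' consensus, merge), encodes and partitions the dataset, trains the
#' reduced cell model, evaluates it on the test split, extracts and trims
#' the first-layer filter PWMs, matches them against the planted motif
#' database (E-value = permutation p times database size), and computes
#' per-filter nullification influences.
#'
#' @param seed root seed for generation, partitioning and training.
#' @param spec a [grammar_spec()] (default: the standard study).
#' @param dir bundle directory (default temporary).
#' @param e_match E-value threshold calling a filter
#'   planted-motif-matching (default 0.1).
#' @param n_perm permutations for motif comparison (default 1000).
#' @param keep_bundle keep the bundle directory (default FALSE: deleted
#'   on exit, the returned object holds everything needed).
#' @return list with `model`, `dataset`, `evaluation`, `pwms` (raw),
#'   `trimmed` (IC-trimmed PWMs), `planted` (truth motifs), `matches`
#'   (filter x planted E-value matrix), `match_of_filter` (best planted
#'   match at `e_match`, else `NA`), `task_of_motif`, `influences`,
#'   `rules`, and `seed`.
#' @export
run_planted_benchmark <- function(seed = 1, spec = grammar_spec(),
                                  dir = tempfile("benchmark"),
                                  e_match = 0.1, n_perm = 1000,
                                  keep_bundle = FALSE) {
  bundle <- generate_study(spec, seed = seed, dir = dir)
  if (!keep_bundle) on.exit(unlink(dir, recursive = TRUE))
  sizes <- read_chrom_sizes(bundle$chrom_sizes)
  blacklist <- read_bed(bundle$blacklist, qvalue_col = NA)
  tracks <- grep("^cell1\\.", names(bundle$peak_files), value = TRUE)
  reps <- lapply(bundle$peak_files[tracks], function(f) {
    lapply(f, read_bed)
  })
  ts <- build_track_set(reps, blacklist = blacklist, chrom_sizes = sizes,
                        genome_id = "synthetic")
  genome <- read_genome(bundle$genome)
  dataset <- split_dataset(encode_dataset(genome, ts, sizes), seed = seed)
  model <- train_model(build_model(desk_config(ncol(dataset$Y),
                                               seed = seed)), dataset)
  evaluation <- evaluate_model(model, dataset, "test")
  te <- dataset_partition(dataset, "test")
  pwms <- extract_pwms(model, te$X)
  trimmed <- lapply(Filter(Negate(is.null), pwms), trim_pwm)
  planted <- read_meme(bundle$motifs)
  matches <- matrix(NA_real_, length(pwms), length(planted),
                    dimnames = list(names(pwms), names(planted)))
  for (fn in names(trimmed)) {
    for (mn in names(planted)) {
      ov <- min(7, nrow(trimmed[[fn]]$freq), nrow(planted[[mn]]$freq))
      matches[fn, mn] <- compare_motifs(
        trimmed[[fn]], planted[[mn]], min_overlap = ov, n_perm = n_perm,
        seed = seed + match(fn, names(pwms)),
        n_targets = length(planted))$e_value
    }
  }
  match_of_filter <- apply(matches, 1, function(e) {
    if (all(is.na(e)) || min(e, na.rm = TRUE) >= e_match) {
      NA_character_
    } else {
      names(which.min(e))
    }
  })
  rules <- lapply(bundle$spec$rules[tracks], identity)
  task_of_motif <- list()
  for (tr in tracks) {
    for (mn in rules[[tr]]$motifs) {
      task_of_motif[[mn]] <- c(task_of_motif[[mn]], tr)
    }
  }
  influences <- filter_influences(model, te$X)
  list(model = model, dataset = dataset, evaluation = evaluation,
       pwms = pwms, trimmed = trimmed, planted = planted,
       matches = matches, match_of_filter = match_of_filter,
       task_of_motif = task_of_motif, influences = influences,
       rules = rules, tracks = tracks, seed = seed,
       bundle_dir = if (keep_bundle) dir else NULL,
       truth_sites = bundle$truth_sites,
       conservation_file = if (keep_bundle) bundle$conservation else NULL)
}

#' Influence discrimination between matched and unmatched filters
#'
#' For every planted motif recovered by at least one filter, compares the
#' mean influence of its matching filters on the motif's task against the
#' mean influence, on the same task, of filters matching no planted
#' motif.
#'
#' @param bench result of [run_planted_benchmark()].
#' @return list with `per_motif` (data frame: motif, task, matched and
#'   non-matched mean influence, ratio) and `pooled_ratio` (ratio of the
#'   pooled means).
#' @export
influence_discrimination <- function(bench) {
  infl <- bench$influences$per_task
  mof <- bench$match_of_filter
  unmatched <- which(is.na(mof))
  rows <- list()
  mv <- nv <- c()
  for (mn in names(bench$task_of_motif)) {
    mi <- which(mof == mn)
    if (length(mi) == 0) next
    for (task in bench$task_of_motif[[mn]]) {
      if (!(task %in% colnames(infl))) next
      m_mean <- mean(infl[mi, task])
      n_mean <- mean(infl[unmatched, task])
      rows[[length(rows) + 1]] <- data.frame(
        motif = mn, task = task, matched_mean = m_mean,
        unmatched_mean = n_mean, ratio = m_mean / n_mean)
      mv <- c(mv, infl[mi, task])
      nv <- c(nv, infl[unmatched, task])
    }
  }
  list(per_motif = do.call(rbind, rows),
       pooled_ratio = mean(mv) / mean(nv))
}

#' Interaction analysis of the planted cooperative pair
#'
#' Locates the most influential matching filter for each member of the
#' planted AND-pair, estimates the interaction coefficient across
#' several sampling seeds, and compares its magnitude against a null of
#' independent filter pairs (filters matched to different, non-partner
#' planted motifs).
#'
#' @param bench result of [run_planted_benchmark()].
#' @param seeds sampling seeds for the cooperative pair (default 1:5).
#' @param n_null independent pairs in the null (default 20).
#' @param n_sequences sequences per regression (default 2000).
#' @return list with `pair` (filter names), `task`, `gammas`,
#'   `sign_consistent`, `null_gammas`, `null_q95` and
#'   `exceeds_null_q95`; `NULL` when an AND-pair member was not
#'   recovered.
#' @export
cooperative_pair_analysis <- function(bench, seeds = 1:5, n_null = 20,
                                      n_sequences = 2000) {
  and_track <- names(bench$rules)[vapply(bench$rules, function(r) {
    r$type == "and"
  }, logical(1))]
  if (length(and_track) != 1) stop("no planted AND-pair task")
  members <- bench$rules[[and_track]]$motifs
  mof <- bench$match_of_filter
  infl <- bench$influences$per_task
  te <- dataset_partition(bench$dataset, "test")
  pick <- function(mn) {
    cand <- which(mof == mn)
    if (length(cand) == 0) return(NA_integer_)
    cand[which.max(infl[cand, and_track])]
  }
  fi <- pick(members[1])
  fj <- pick(members[2])
  if (is.na(fi) || is.na(fj)) return(NULL)
  gammas <- vapply(seeds, function(s) {
    interaction_coefficients(
      bench$model, c(fi, fj), and_track, te$X,
      n_sequences = n_sequences, seed = s,
      null_values = bench$influences$null_values)$gamma
  }, numeric(1))
  # independent pairs: filters matched to different planted motifs,
  # excluding pairs joining the two AND members
  mm <- which(!is.na(mof))
  prs <- t(utils::combn(mm, 2))
  keep <- apply(prs, 1, function(p) {
    a <- mof[p[1]]; b <- mof[p[2]]
    a != b && !setequal(c(a, b), members)
  })
  prs <- prs[keep, , drop = FALSE]
  old <- .Random.seed_save()
  set.seed(bench$seed)
  prs <- prs[sample.int(nrow(prs), min(n_null, nrow(prs))), ,
             drop = FALSE]
  .Random.seed_restore(old)
  null_g <- interaction_coefficients(
    bench$model, prs, and_track, te$X, n_sequences = n_sequences,
    seed = seeds[1], null_values = bench$influences$null_values)$gamma
  q95 <- stats::quantile(abs(null_g), 0.95, na.rm = TRUE, names = FALSE)
  list(pair = rownames(infl)[c(fi, fj)], task = and_track,
       gammas = gammas,
       sign_consistent = length(unique(sign(gammas))) == 1,
       null_gammas = null_g, null_q95 = q95,
       exceeds_null_q95 = abs(gammas[1]) > q95)
}
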