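# Seed-reproducible toy epigenomes: genome, per-(cell, mark) peak tracks
# with replicates, blacklist, conservation track and ground-truth motif
# grammars, emulating the structure of multi-cell-type/multi-mark
# ChIP-seq peak studies at desk scale.

#' Build a sharp PWM from a consensus string
#'
#' @param consensus DNA string.
#' @param dominant probability of the consensus base per position; the
#'   remainder is spread over the other three bases.
#' @return width x 4 frequency matrix.
#' @export
consensus_pwm <- function(consensus, dominant = 0.88) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  idx <- match(chars, .BASES)
  if (anyNA(idx)) stop("consensus must be over ACGT")
  m <- matrix((1 - dominant) / 3, length(idx), 4,
              dimnames = list(NULL, .BASES))
  m[cbind(seq_along(idx), idx)] <- dominant
  m
}

.default_planted_motifs <- function() {
  cons <- c(motifA = "TGACGTCATC", motifB = "GGGACTTTCCGT",
            motifC = "CACGTGACT", motifD = "AGGTCAAGGT",
            motifE = "TTCCGGAAGTA", motifF = "CCAATCAGGC")
  lapply(seq_along(cons), function(i) {
    pwm_motif(consensus_pwm(cons[[i]], dominant = 0.92), names(cons)[i],
              n_sites = 100L, source = "planted")
  }) |> stats::setNames(names(cons))
}

#' Specification of a synthetic planted-motif study
#'
#' Defaults describe the desk-scale default bundle: 2 cell types x 3
#' marks over a 2 Mbp two-chromosome genome, six planted motifs of widths
#' 9-12 (one cooperative AND-pair task, one motif shared between cells),
#' two jittered replicates per track, q-value and length decoy peaks,
#' blacklisted decoy regions, and a per-base conservation track elevated
#' at planted sites.
#'
#' @param n_cells,n_marks study dimensions (default 2 x 3).
#' @param chrom_sizes named vector (default two 1 Mbp chromosomes).
#' @param motifs named list of planted [pwm_motif()]s (>= needed by the
#'   rules).
#' @param rules named list (track -> list(type, motifs)); `type` is
#'   `"single"` or `"and"`; defaults plant one motif per track, an
#'   AND-pair on cell1.mark3, and share the mark1 motif across cells.
#' @param peaks_per_track consensus peaks per track (default 350).
#' @param peak_length length-range of peaks in bp (default 600-900).
#' @param instances_per_peak motif instances implanted per peak per motif
#'   (default 4).
#' @param prevalence_positive probability a peak carries its implants
#'   (default 1).
#' @param prevalence_negative expected background implants per kb of
#'   genome per motif (default 0.02).
#' @param background a [fit_background()] model genomes are sampled from;
#'   default an order-0 model at 41% GC.
#' @param share_frac fraction of a later cell's peaks reusing the first
#'   cell's same-mark regions when both carry the same motif rule
#'   (default 0.6).
#' @param and_negative_rate probability that a peak of another track
#'   receives a lone AND-member half-site decoy (default 0, i.e. off);
#'   raising it forces strictly conjunctive logic.
#' @param and_single_frac fraction of AND-task peaks carrying only one
#'   pair member (default 0.5, split evenly between members); this makes
#'   both members individually necessary so both are learned, while
#'   both-present peaks carry the redundancy that the interaction
#'   coefficient detects.
#' @param n_replicates replicates per track (default 2).
#' @param jitter_sd replicate boundary jitter (bp, default 25).
#' @param q_decoy_frac fraction of per-replicate peaks given a failing
#'   q-value (default 0.05).
#' @param n_long_decoys over-length (12 kb) decoy peaks per track.
#' @param n_blacklist blacklist regions per chromosome (default 3).
#' @param blacklist_length blacklist region length (default 5000).
#' @param conservation_baseline range of background conservation scores.
#' @param conservation_site range of conservation at planted sites.
#' @return a `grammar_spec` list.
#' @export
grammar_spec <- function(n_cells = 2, n_marks = 3,
                         chrom_sizes = c(chrA = 1000000, chrB = 1000000),
                         motifs = .default_planted_motifs(),
                         rules = NULL,
                         peaks_per_track = 350,
                         peak_length = c(600, 900),
                         instances_per_peak = 4,
                         prevalence_positive = 1,
                         prevalence_negative = 0.02,
                         background = NULL,
                         share_frac = 0.6, and_negative_rate = 0,
                         and_single_frac = 0.5,
                         n_replicates = 2, jitter_sd = 25,
                         q_decoy_frac = 0.05, n_long_decoys = 2,
                         n_blacklist = 3, blacklist_length = 5000,
                         conservation_baseline = c(0.05, 0.35),
                         conservation_site = c(0.7, 0.95)) {
  if (n_cells < 1 || n_marks < 1) stop("need at least one cell and mark")
  if (prevalence_positive <= 0 || prevalence_positive > 1 ||
      prevalence_negative < 0 || prevalence_negative > 1) {
    stop("prevalences must be in [0, 1], positive prevalence > 0")
  }
  chrom_sizes <- unlist(chrom_sizes)      # tolerate YAML list form
  cells <- paste0("cell", seq_len(n_cells))
  marks <- paste0("mark", seq_len(n_marks))
  tracks <- as.vector(outer(cells, marks, paste, sep = "."))
  if (is.null(rules)) {
    nm <- names(motifs)
    reserved <- if (length(nm) >= 4) c("motifC", "motifD") else character(0)
    cand <- setdiff(nm, reserved)
    rules <- list()
    k <- 1
    for (mk in marks) {
      for (ce in cells) {
        tr <- paste(ce, mk, sep = ".")
        if (ce == "cell1" && mk == "mark3" && length(reserved) == 2) {
          rules[[tr]] <- list(type = "and", motifs = reserved)
        } else if (ce != "cell1" && mk == "mark1") {
          # shared motif: same mark in a related cell type reuses the
          # cell1 motif, as shared motifs across cell models do
          rules[[tr]] <- list(type = "single",
                              motifs = rules[["cell1.mark1"]]$motifs)
        } else {
          rules[[tr]] <- list(type = "single",
                              motifs = cand[(k - 1) %% length(cand) + 1])
          k <- k + 1
        }
      }
    }
    rules <- rules[tracks]
  }
  if (is.null(background)) {
    background <- structure(
      list(order = 0,
           cond = list(matrix(c(0.295, 0.205, 0.205, 0.295), 1, 4,
                              dimnames = list("", .BASES))),
           n_bases = 0),
      class = "markov_background")
  }
  structure(list(n_cells = n_cells, n_marks = n_marks, cells = cells,
                 marks = marks, tracks = tracks,
                 chrom_sizes = chrom_sizes, motifs = motifs,
                 rules = rules, peaks_per_track = peaks_per_track,
                 peak_length = peak_length,
                 instances_per_peak = instances_per_peak,
                 prevalence_positive = prevalence_positive,
                 prevalence_negative = prevalence_negative,
                 background = background, share_frac = share_frac,
                 and_negative_rate = and_negative_rate,
                 and_single_frac = and_single_frac,
                 n_replicates = n_replicates,
                 jitter_sd = jitter_sd, q_decoy_frac = q_decoy_frac,
                 n_long_decoys = n_long_decoys,
                 n_blacklist = n_blacklist,
                 blacklist_length = blacklist_length,
                 conservation_baseline = conservation_baseline,
                 conservation_site = conservation_site),
            class = "grammar_spec")
}

.sample_pwm_instance <- function(freq) {
  paste(vapply(seq_len(nrow(freq)), function(i) {
    sample(.BASES, 1, prob = freq[i, ])
  }, character(1)), collapse = "")
}

.revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# sample n non-overlapping intervals on one chromosome avoiding `avoid`
.place_intervals <- function(n, lens, chrom_len, avoid, margin = 600,
                             max_tries = 50) {
  placed <- matrix(integer(0), 0, 2)
  taken <- avoid
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      s <- sample.int(chrom_len - lens[i] - 2 * margin, 1) + margin
      e <- s + lens[i]
      clash <- nrow(taken) > 0 && any(s < taken[, 2] & e > taken[, 1])
      if (!clash) {
        placed <- rbind(placed, c(s, e))
        taken <- rbind(taken, c(s, e))
        break
      }
    }
  }
  placed
}

#' Generate a synthetic planted-motif study bundle
#'
#' Samples a genome from the background model, places per-track peaks,
#' implants motif instances according to each track's rule, emits
#' jittered replicate peak calls with q-values (including q-value,
#' over-length and blacklist decoys), a blacklist, a per-base
#' conservation track elevated at planted sites, the ground-truth motifs
#' in MEME format, and a JSON manifest. Byte-identical under identical
#' seed.
#'
#' @param spec a [grammar_spec()].
#' @param seed integer seed for all randomness.
#' @param dir output directory (created).
#' @return list with `dir`, file paths (`genome`, `chrom_sizes`,
#'   `blacklist`, `conservation`, `motifs`, `manifest`, `truth_sites_file`),
#'   plus in-memory `truth_sites`
#'   data frame and `truth_peaks` list.
#' @export
generate_study <- function(spec, seed = 1, dir = tempfile("study")) {
  if (length(spec$tracks) == 0) stop("spec defines zero tasks")
  wmax <- max(vapply(spec$motifs, function(m) nrow(m$freq), integer(1)))
  if (wmax > spec$peak_length[1]) stop("motif wider than shortest peak")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  old <- .Random.seed_save()
  set.seed(seed)

  chroms <- names(spec$chrom_sizes)
  # 1. genome (as character vectors for in-place implanting)
  bg0 <- spec$background$cond[[1]][1, ]
  gchars <- lapply(chroms, function(ch) {
    if (spec$background$order == 0) {
      sample(.BASES, spec$chrom_sizes[[ch]], replace = TRUE, prob = bg0)
    } else {
      strsplit(sample_background(spec$background, spec$chrom_sizes[[ch]],
                                 seed = sample.int(1e6, 1)), "")[[1]]
    }
  })
  names(gchars) <- chroms

  # 2. blacklist
  bl <- do.call(rbind, lapply(chroms, function(ch) {
    p <- .place_intervals(spec$n_blacklist,
                          rep(spec$blacklist_length, spec$n_blacklist),
                          spec$chrom_sizes[[ch]],
                          matrix(integer(0), 0, 2))
    data.frame(chrom = ch, start = p[, 1], end = p[, 2],
               stringsAsFactors = FALSE)
  }))

  # 3. consensus peaks per track (avoid blacklist). cell1 tracks are
  # placed fresh; later cells reuse a share_frac of cell1's same-mark
  # regions (lightly shifted) and place the rest fresh, mirroring how the
  # same mark overlaps substantially across related cell types.
  place_fresh <- function(n) {
    per_chrom <- list()
    n_ch <- length(chroms)
    n_each <- diff(round(seq(0, n, length.out = n_ch + 1)))
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      avoid <- as.matrix(bl[bl$chrom == ch, c("start", "end")])
      lens <- sample(spec$peak_length[1]:spec$peak_length[2], n_each[ci],
                     replace = TRUE)
      p <- .place_intervals(n_each[ci], lens, spec$chrom_sizes[[ch]],
                            avoid)
      per_chrom[[ci]] <- data.frame(chrom = ch, start = p[, 1],
                                    end = p[, 2], stringsAsFactors = FALSE)
    }
    do.call(rbind, per_chrom)
  }
  truth_peaks <- list()
  for (mk in spec$marks) {
    for (ce in spec$cells) {
      tr <- paste(ce, mk, sep = ".")
      if (!(tr %in% spec$tracks)) next
      base_tr <- paste(spec$cells[1], mk, sep = ".")
      shares <- ce != spec$cells[1] &&
        identical(spec$rules[[tr]]$motifs, spec$rules[[base_tr]]$motifs)
      if (shares && !is.null(truth_peaks[[base_tr]])) {
        base <- truth_peaks[[base_tr]]
        n_shared <- round(spec$share_frac * nrow(base))
        keep <- sort(sample.int(nrow(base), n_shared))
        shared <- base[keep, c("chrom", "start", "end")]
        sh <- round(rnorm(n_shared, 0, spec$jitter_sd))
        shared$start <- pmax(0L, shared$start + sh)
        shared$end <- shared$end + sh
        tp <- rbind(shared, place_fresh(spec$peaks_per_track - n_shared))
      } else {
        tp <- place_fresh(spec$peaks_per_track)
      }
      tp <- tp[order(tp$chrom, tp$start), , drop = FALSE]
      tp$peak_id <- sprintf("%s:%03d", tr, seq_len(nrow(tp)))
      truth_peaks[[tr]] <- tp
    }
  }
  truth_peaks <- truth_peaks[spec$tracks]

  # 4. implant motif instances per rule
  sites <- list()
  for (tr in spec$tracks) {
    rule <- spec$rules[[tr]]
    tp <- truth_peaks[[tr]]
    for (r in seq_len(nrow(tp))) {
      if (runif(1) > spec$prevalence_positive) next
      members <- rule$motifs
      if (rule$type == "and" && length(members) == 2) {
        u <- runif(1)
        if (u < spec$and_single_frac / 2) {
          members <- members[1]
        } else if (u < spec$and_single_frac) {
          members <- members[2]
        }
      }
      for (mn in members) {
        freq <- spec$motifs[[mn]]$freq
        w <- nrow(freq)
        for (k in seq_len(spec$instances_per_peak)) {
          pos <- tp$start[r] + sample.int(tp$end[r] - tp$start[r] - w, 1)
          strand <- sample(c("+", "-"), 1)
          inst <- .sample_pwm_instance(freq)
          if (strand == "-") inst <- .revcomp_str(inst)
          gchars[[tp$chrom[r]]][(pos + 1):(pos + w)] <-
            strsplit(inst, "")[[1]]
          sites[[length(sites) + 1]] <- data.frame(
            chrom = tp$chrom[r], start = pos, end = pos + w,
            strand = strand, motif = mn, track = tr,
            peak_id = tp$peak_id[r], stringsAsFactors = FALSE)
        }
      }
    }
  }

  # 5. background decoy implants (not recorded as truth sites)
  for (mn in names(spec$motifs)) {
    freq <- spec$motifs[[mn]]$freq
    w <- nrow(freq)
    for (ch in chroms) {
      n_dec <- stats::rpois(1, spec$prevalence_negative *
                              spec$chrom_sizes[[ch]] / 1000)
      if (n_dec == 0) next
      for (k in seq_len(n_dec)) {
        pos <- sample.int(spec$chrom_sizes[[ch]] - w, 1)
        inst <- .sample_pwm_instance(freq)
        if (runif(1) < 0.5) inst <- .revcomp_str(inst)
        gchars[[ch]][(pos + 1):(pos + w)] <- strsplit(inst, "")[[1]]
      }
    }
  }

  # 6. decoy signal inside blacklist regions (task motifs implanted so
  # that skipping blacklist removal would corrupt the labels)
  for (tr in spec$tracks) {
    mn <- spec$rules[[tr]]$motifs[1]
    freq <- spec$motifs[[mn]]$freq
    w <- nrow(freq)
    for (bi in seq_len(nrow(bl))) {
      pos <- bl$start[bi] + sample.int(bl$end[bi] - bl$start[bi] - w, 1)
      inst <- .sample_pwm_instance(freq)
      gchars[[bl$chrom[bi]]][(pos + 1):(pos + w)] <- strsplit(inst, "")[[1]]
    }
  }

  # 4b. AND-pair half-site decoys: peaks of other tracks receive single
  # member motifs so that one member alone does not predict the AND task
  # (the conjunction, not either motif, carries the label)
  for (tr in spec$tracks) {
    rule <- spec$rules[[tr]]
    if (rule$type != "and") next
    for (other in setdiff(spec$tracks, tr)) {
      tp <- truth_peaks[[other]]
      for (r in seq_len(nrow(tp))) {
        if (runif(1) > spec$and_negative_rate) next
        mn <- sample(rule$motifs, 1)
        freq <- spec$motifs[[mn]]$freq
        w <- nrow(freq)
        for (k in seq_len(2)) {
          pos <- tp$start[r] + sample.int(tp$end[r] - tp$start[r] - w, 1)
          inst <- .sample_pwm_instance(freq)
          if (runif(1) < 0.5) inst <- .revcomp_str(inst)
          gchars[[tp$chrom[r]]][(pos + 1):(pos + w)] <-
            strsplit(inst, "")[[1]]
        }
      }
    }
  }

  truth_sites <- do.call(rbind, sites)

  # 7. replicate peak calls: jittered truth peaks + q decoys + length
  # decoys + blacklist decoy peaks + replicate-only noise peaks
  peak_files <- list()
  for (tr in spec$tracks) {
    tp <- truth_peaks[[tr]]
    for (rep_i in seq_len(spec$n_replicates)) {
      sh <- round(rnorm(nrow(tp), 0, spec$jitter_sd))
      sh2 <- round(rnorm(nrow(tp), 0, spec$jitter_sd))
      rp <- data.frame(chrom = tp$chrom,
                       start = pmax(0L, tp$start + sh),
                       end = tp$end + sh2, stringsAsFactors = FALSE)
      rp$end <- pmax(rp$end, rp$start + 100L)
      rp$neglog10_q <- 2 + rgamma(nrow(rp), shape = 3, rate = 1)
      ndec <- max(1L, round(spec$q_decoy_frac * nrow(rp)))
      rp$neglog10_q[sample.int(nrow(rp), ndec)] <-
        runif(ndec, 0, 1.9)
      # over-length decoys (both replicates carry them, high q)
      for (k in seq_len(spec$n_long_decoys)) {
        ch <- chroms[1 + (k - 1) %% length(chroms)]
        s <- 20000 + k * 30000
        rp <- rbind(rp, data.frame(chrom = ch, start = s, end = s + 12000,
                                   neglog10_q = 8))
      }
      # peaks over blacklist decoy signal
      blx <- bl[seq_len(min(2, nrow(bl))), , drop = FALSE]
      rp <- rbind(rp, data.frame(chrom = blx$chrom,
                                 start = blx$start - 100,
                                 end = blx$start + 700,
                                 neglog10_q = 6))
      # replicate-specific noise peaks (killed by the 2-replicate rule)
      nn <- 10
      nz <- do.call(rbind, lapply(seq_len(nn), function(k) {
        ch <- sample(chroms, 1)
        s <- sample.int(spec$chrom_sizes[[ch]] - 1000, 1)
        data.frame(chrom = ch, start = s, end = s + 500,
                   neglog10_q = 3 + runif(1, 0, 2))
      }))
      rp <- rbind(rp, nz)
      f <- file.path(dir, "peaks",
                     sprintf("%s_rep%d.bed", gsub("\\.", "_", tr), rep_i))
      df <- data.frame(chrom = rp$chrom, start = rp$start, end = rp$end,
                       name = sprintf("%s_rep%d_%04d",
                                      gsub("\\.", "_", tr), rep_i,
                                      seq_len(nrow(rp))),
                       score = 0, strand = ".",
                       signal = 0, pval = 0, qval = rp$neglog10_q,
                       stringsAsFactors = FALSE)
      ord <- order(df$chrom, df$start, df$end)
      lines <- do.call(paste, c(df[ord, ], sep = "\t"))
      writeLines(lines, f)
      peak_files[[tr]] <- c(peak_files[[tr]], f)
    }
  }

  # 8. conservation track: baseline noise, elevated at planted sites
  conservation <- lapply(chroms, function(ch) {
    round(runif(spec$chrom_sizes[[ch]], spec$conservation_baseline[1],
                spec$conservation_baseline[2]), 3)
  })
  names(conservation) <- chroms
  for (i in seq_len(nrow(truth_sites))) {
    idx <- (truth_sites$start[i] + 1):truth_sites$end[i]
    conservation[[truth_sites$chrom[i]]][idx] <-
      round(runif(length(idx), spec$conservation_site[1],
                  spec$conservation_site[2]), 3)
  }

  .Random.seed_restore(old)

  # 9. write the bundle
  genome <- vapply(gchars, paste, character(1), collapse = "")
  paths <- list(
    dir = dir,
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    blacklist = file.path(dir, "blacklist.bed"),
    conservation = file.path(dir, "conservation.wig"),
    motifs = file.path(dir, "motifs_truth.meme"),
    truth_sites_file = file.path(dir, "truth_sites.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_fasta(genome, paths$genome)
  write_chrom_sizes(spec$chrom_sizes, paths$chrom_sizes)
  write_bed(bl, paths$blacklist)
  write_wiggle(conservation, paths$conservation, digits = 3)
  write_meme(spec$motifs, paths$motifs, background = bg0)
  write.table(truth_sites, paths$truth_sites_file, sep = "	",
              quote = FALSE, row.names = FALSE)
  truth_peak_files <- list()
  for (tr in spec$tracks) {
    f <- file.path(dir, "peaks",
                   sprintf("%s_truth.bed", gsub("\\.", "_", tr)))
    tp <- truth_peaks[[tr]]
    writeLines(paste(tp$chrom, tp$start, tp$end, tp$peak_id, sep = "\t"),
               f)
    truth_peak_files[[tr]] <- f
  }
  manifest <- list(
    seed = seed,
    chrom_sizes = as.list(spec$chrom_sizes),
    tracks = spec$tracks,
    rules = lapply(spec$rules, function(r) r[c("type", "motifs")]),
    motif_widths = lapply(spec$motifs, function(m) nrow(m$freq)),
    peaks_per_track = spec$peaks_per_track,
    n_replicates = spec$n_replicates,
    n_truth_sites = nrow(truth_sites),
    files = lapply(paths[-1], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  c(paths, list(peak_files = peak_files,
                truth_peak_files = truth_peak_files,
                truth_sites = truth_sites, truth_peaks = truth_peaks,
                spec = spec, seed = seed))
}

#' Ground-truth bin labels and planted sites for a bundle
#'
#' Recomputes per-bin ground-truth labels from the pre-jitter truth peak
#' intervals, and lists for each positive bin the planted sites of the
#' peaks that made it positive.
#'
#' @param bundle result of [generate_study()].
#' @param tracks track subset (default all).
#' @param bin_size,overlap_fraction binning parameters (defaults 200 and
#'   0.5).
#' @return list with `bins`, `Y` (binary matrix over `tracks`) and
#'   `bin_sites` (list, per bin, of truth-site row indices in
#'   `bundle$truth_sites`).
#' @export
truth_table <- function(bundle, tracks = NULL, bin_size = 200,
                        overlap_fraction = 0.5) {
  if (is.null(tracks)) tracks <- names(bundle$truth_peaks)
  ts <- structure(list(tracks = lapply(bundle$truth_peaks[tracks],
                                       merge_intervals),
                       genome_id = "synthetic"),
                  class = "track_set")
  sizes <- read_chrom_sizes(bundle$chrom_sizes)
  lab <- label_bins(bin_genome(sizes, bin_size), ts, overlap_fraction)
  sites <- bundle$truth_sites
  bin_sites <- vector("list", nrow(lab$bins))
  for (b in seq_len(nrow(lab$bins))) {
    pos_tracks <- tracks[lab$Y[b, ] == 1]
    hits <- integer(0)
    for (tr in pos_tracks) {
      tp <- bundle$truth_peaks[[tr]]
      ov <- tp$chrom == lab$bins$chrom[b] &
        tp$start < lab$bins$end[b] & tp$end > lab$bins$start[b]
      pid <- tp$peak_id[ov]
      hits <- c(hits, which(sites$peak_id %in% pid))
    }
    bin_sites[[b]] <- unique(hits)
  }
  list(bins = lab$bins, Y = lab$Y, bin_sites = bin_sites)
}
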