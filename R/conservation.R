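# High-order Markov backgrounds, PWM scanning with dynamic-programming
# p-values, per-site conservation, and the influence/conservation
# correlation.

.BASES <- c("A", "C", "G", "T")

.all_contexts <- function(k) {
  if (k == 0) return("")
  do.call(paste0, expand.grid(rep(list(.BASES), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' Fit a high-order Markov background model
#'
#' Maximum-likelihood conditional probabilities with add-one smoothing
#' for every order 0..`order`; lower orders double as the fallback chain
#' for short flanks.
#'
#' @param sequences character vector of DNA sequences (non-ACGT bases are
#'   skipped at counting).
#' @param order model order (default 5).
#' @return object of class `markov_background`: list with `order`,
#'   `cond` (per order `k`, a 4^k x 4 matrix of conditionals with context
#'   rownames) and `n_bases` (training bases).
#' @export
fit_background <- function(sequences, order = 5) {
  if (length(sequences) == 0 || all(nchar(sequences) == 0)) {
    stop("empty input")
  }
  sequences <- toupper(sequences)
  total <- sum(nchar(sequences))
  if (total <= 4^order) {
    warning("training sequence shorter than 4^order bases; ",
            "estimates rely heavily on smoothing")
  }
  cond <- vector("list", order + 1)
  for (k in 0:order) {
    ctx <- .all_contexts(k)
    counts <- matrix(1, length(ctx), 4,            # add-one smoothing
                     dimnames = list(ctx, .BASES))
    for (s in sequences) {
      L <- nchar(s)
      if (L < k + 1) next
      kmers <- substring(s, seq_len(L - k), seq_len(L - k) + k)
      ok <- !grepl("[^ACGT]", kmers)
      kmers <- kmers[ok]
      if (length(kmers) == 0) next
      ctxs <- substr(kmers, 1, k)
      nxt <- substr(kmers, k + 1, k + 1)
      tab <- table(factor(ctxs, levels = ctx), factor(nxt, levels = .BASES))
      counts <- counts + matrix(as.numeric(tab), nrow(counts), 4)
    }
    cond[[k + 1]] <- counts / rowSums(counts)
  }
  structure(list(order = order, cond = cond, n_bases = total),
            class = "markov_background")
}

#' Sample a sequence from a Markov background
#'
#' @param background a [fit_background()] model.
#' @param length sequence length (bp).
#' @param seed RNG seed.
#' @return a DNA string.
#' @export
sample_background <- function(background, length, seed = 1) {
  old <- .Random.seed_save()
  set.seed(seed)
  k <- background$order
  if (k == 0) {
    p <- background$cond[[1]][1, ]
    s <- paste(sample(.BASES, length, replace = TRUE, prob = p),
               collapse = "")
    .Random.seed_restore(old)
    return(s)
  }
  out <- character(length)
  for (i in seq_len(length)) {
    ko <- min(k, i - 1)
    p <- if (ko == 0) {
      background$cond[[1]][1, ]     # order-0 row ("" never matches by name)
    } else {
      ctx <- paste(out[(i - ko):(i - 1)], collapse = "")
      background$cond[[ko + 1]][ctx, ]
    }
    out[i] <- sample(.BASES, 1, prob = p)
  }
  .Random.seed_restore(old)
  paste(out, collapse = "")
}

# integerized log-odds score system for one PWM against a 0-order
# background; returns the integer score matrix, the bin width, the
# offset (sum of per-position minima) and the tail p-value lookup
.score_system <- function(freq, bg0, pseudocount = 0.01, n_bins = 1000) {
  fr <- (freq + pseudocount) / (1 + 4 * pseudocount)
  S <- log2(sweep(fr, 2, bg0, `/`))
  mins <- apply(S, 1, min)
  Sp <- S - mins
  rng <- sum(apply(Sp, 1, max))
  if (rng <= 0) {
    return(list(iscore = matrix(0L, nrow(S), 4), binwidth = 0,
                offset = sum(mins), p_tail = c(1), degenerate = TRUE))
  }
  bw <- rng / n_bins
  iscore <- matrix(as.integer(round(Sp / bw)), nrow(S), 4)
  # DP over the integer score distribution under the background
  maxint <- sum(apply(iscore, 1, max))
  pmf <- c(1, numeric(maxint))
  for (i in seq_len(nrow(iscore))) {
    new <- numeric(maxint + 1)
    for (b in 1:4) {
      sh <- iscore[i, b]
      idx <- seq_len(maxint + 1 - sh)
      new[idx + sh] <- new[idx + sh] + pmf[idx] * bg0[b]
    }
    pmf <- new
  }
  p_tail <- rev(cumsum(rev(pmf)))
  list(iscore = iscore, binwidth = bw, offset = sum(mins),
       p_tail = p_tail, degenerate = FALSE)
}

.encode_seq_int <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .BASES)
  v[is.na(v)] <- 0L
  as.integer(v - 1L)                 # 0..3, -1 for non-ACGT
}

.revcomp_freq <- function(freq) {
  freq[rev(seq_len(nrow(freq))), rev(seq_len(ncol(freq))), drop = FALSE]
}

#' Scan sequences for motif sites
#'
#' Both strands are scanned with the log-odds score
#' `sum log2(p_motif(b) / p_bg(b))` against the 0-order marginal of the
#' background; p-values come from dynamic programming over the
#' discretized score distribution (1000 bins); sites with
#' `p <= p_threshold` are reported. Sites on both strands at the same
#' position are both kept.
#'
#' @param pwm a [pwm_motif()].
#' @param sequences named character vector (names become `chrom`).
#' @param background a [fit_background()] model (its 0-order marginal is
#'   used for the score).
#' @param p_threshold maximum site p-value (default 1e-5).
#' @param pseudocount motif pseudo-frequency guard (default 0.01).
#' @param n_bins score discretization bins (default 1000).
#' @return data frame of sites: `chrom`, `start`, `end` (0-based
#'   half-open within the sequence), `strand`, `score` (log2 odds),
#'   `p_value`, `motif`.
#' @export
scan_pwm <- function(pwm, sequences, background, p_threshold = 1e-5,
                     pseudocount = 0.01, n_bins = 1000) {
  if (is.null(background)) stop("background model required")
  freq <- if (inherits(pwm, "pwm_motif")) pwm$freq else as.matrix(pwm)
  mname <- if (inherits(pwm, "pwm_motif")) pwm$name else "pwm"
  w <- nrow(freq)
  if (any(nchar(sequences) < w)) stop("pwm wider than a target sequence")
  bg0 <- background$cond[[1]][1, ]
  systems <- list(`+` = .score_system(freq, bg0, pseudocount, n_bins),
                  `-` = .score_system(.revcomp_freq(freq), bg0,
                                      pseudocount, n_bins))
  rows <- list()
  for (strand in c("+", "-")) {
    sys <- systems[[strand]]
    if (sys$degenerate) next
    cutoff <- which(sys$p_tail <= p_threshold)
    if (length(cutoff) == 0) next
    cutoff <- min(cutoff) - 1L        # integer score cutoff (0-based)
    for (nm in names(sequences)) {
      enc <- .encode_seq_int(sequences[[nm]])
      hit <- .scan_int_cpp(sys$iscore, enc, cutoff)
      if (length(hit$pos) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = nm, start = hit$pos, end = hit$pos + w,
        strand = strand,
        score = hit$score * sys$binwidth + sys$offset,
        p_value = sys$p_tail[hit$score + 1L],
        motif = mname, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Write motif sites as 6-column BED
#'
#' The BED score column holds `-log10(p)`.
#'
#' @param sites data frame from [scan_pwm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(chrom = sites$chrom, start = sites$start,
                   end = sites$end, name = sites$motif,
                   score = -log10(pmax(sites$p_value, 1e-300)),
                   strand = sites$strand, stringsAsFactors = FALSE)
  write_bed(df, path)
}

#' Per-motif conservation of binding sites
#'
#' Each site's conservation is the mean of the per-base track scores over
#' the site; a motif's conservation is the mean over its sites. Sites
#' touching positions the track does not cover are skipped and counted.
#'
#' @param sites data frame from [scan_pwm()] (possibly several motifs).
#' @param track conservation track from [read_wiggle()] (named list of
#'   per-base vectors).
#' @return data frame per motif: `motif`, `n_sites`, `n_skipped`,
#'   `mean_conservation`.
#' @export
site_conservation <- function(sites, track) {
  out <- lapply(split(sites, sites$motif), function(ss) {
    vals <- numeric(0)
    skipped <- 0L
    for (i in seq_len(nrow(ss))) {
      tv <- track[[ss$chrom[i]]]
      if (is.null(tv) || ss$end[i] > length(tv)) {
        skipped <- skipped + 1L
        next
      }
      v <- tv[(ss$start[i] + 1L):ss$end[i]]
      if (anyNA(v)) {
        skipped <- skipped + 1L
        next
      }
      vals <- c(vals, mean(v))
    }
    data.frame(motif = ss$motif[1], n_sites = length(vals),
               n_skipped = skipped,
               mean_conservation = if (length(vals)) mean(vals) else NA_real_,
               stringsAsFactors = FALSE)
  })
  ret <- do.call(rbind, out)
  rownames(ret) <- NULL
  ret
}

#' Correlation between motif influence and conservation
#'
#' Pearson correlation between the motifs' influence scores and mean
#' conservation, with a two-tailed p-value from the t-distribution
#' transform. Motifs with zero sites (NA conservation) are excluded.
#'
#' @param records data frame with columns `influence` and
#'   `mean_conservation` (e.g. a join of [filter_influences()] and
#'   [site_conservation()] outputs).
#' @return list with `r`, `p_value` and `n`.
#' @export
influence_conservation_correlation <- function(records) {
  ok <- stats::complete.cases(records[, c("influence",
                                          "mean_conservation")])
  I <- records$influence[ok]
  C <- records$mean_conservation[ok]
  n <- length(I)
  if (n < 3) stop("need at least 3 motifs with defined values")
  if (sd(I) == 0 || sd(C) == 0) stop("zero variance; r undefined")
  r <- cor(I, C)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tt), df = n - 2), n = n)
}
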