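# Genome binning, bin labeling, one-hot encoding and dataset partitioning.

#' Segment a genome into fixed-width bins
#'
#' Consecutive non-overlapping bins per chromosome; a trailing partial bin
#' is dropped.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 200).
#' @return data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
bin_genome <- function(chrom_sizes, bin_size = 200) {
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  out <- lapply(names(chrom_sizes), function(chrom) {
    n <- floor(chrom_sizes[[chrom]] / bin_size)
    if (n == 0) return(NULL)
    starts <- (seq_len(n) - 1L) * bin_size
    data.frame(chrom = chrom, start = as.integer(starts),
               end = as.integer(starts + bin_size),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Label bins with per-task peak overlap
#'
#' Task bit `t` is 1 iff the fraction of the bin covered by that task's
#' merged peaks is at least `overlap_fraction` (denominator is the bin
#' length; boundary inclusive). Bins with all-zero label vectors are
#' removed.
#'
#' @param bins data frame from [bin_genome()].
#' @param track_set a `track_set` whose tracks define the tasks.
#' @param overlap_fraction minimum covered fraction in (0, 1].
#' @return list with `bins` (retained rows) and `Y` (binary matrix, one
#'   column per track, in `names(track_set$tracks)` order).
#' @export
label_bins <- function(bins, track_set, overlap_fraction = 0.5) {
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in (0, 1]")
  }
  tasks <- names(track_set$tracks)
  bin_size <- bins$end - bins$start
  Y <- matrix(0L, nrow = nrow(bins), ncol = length(tasks),
              dimnames = list(NULL, tasks))
  for (t in seq_along(tasks)) {
    trk <- track_set$tracks[[tasks[t]]]
    for (chrom in unique(bins$chrom)) {
      bi <- which(bins$chrom == chrom)
      iv <- trk[trk$chrom == chrom, , drop = FALSE]
      if (nrow(iv) == 0) next
      maxend <- max(c(iv$end, bins$end[bi]))
      covered <- integer(maxend)
      for (k in seq_len(nrow(iv))) {
        covered[(iv$start[k] + 1L):iv$end[k]] <- 1L
      }
      cs <- c(0, cumsum(covered))
      covbp <- cs[bins$end[bi] + 1L] - cs[bins$start[bi] + 1L]
      Y[bi, t] <- as.integer(covbp / bin_size[bi] >= overlap_fraction)
    }
  }
  keep <- rowSums(Y) > 0
  list(bins = bins[keep, , drop = FALSE], Y = Y[keep, , drop = FALSE])
}

#' Extend bins to a fixed sequence context
#'
#' Each context is centered on the bin midpoint and has exactly
#' `context_size` bp. Bins whose context would cross a chromosome end are
#' dropped (no padding).
#'
#' @param bins data frame with `chrom`, `start`, `end`.
#' @param context_size context width in bp (default 1000).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return data frame of bins with added `ctx_start`, `ctx_end` columns;
#'   rows whose context falls off-chromosome are removed. The attribute
#'   `"kept"` holds the logical keep mask over the input rows.
#' @export
extend_bin <- function(bins, context_size = 1000, chrom_sizes) {
  if (any(context_size < bins$end - bins$start)) {
    stop("context_size must be >= bin size")
  }
  mid <- (bins$start + bins$end) %/% 2L
  half <- context_size %/% 2L
  ctx_start <- mid - half
  ctx_end <- ctx_start + context_size
  lens <- unname(chrom_sizes[bins$chrom])
  keep <- ctx_start >= 0L & ctx_end <= lens
  out <- bins[keep, , drop = FALSE]
  out$ctx_start <- as.integer(ctx_start[keep])
  out$ctx_end <- as.integer(ctx_end[keep])
  attr(out, "kept") <- keep
  out
}

#' One-hot encode a DNA sequence
#'
#' Canonical bases become unit vectors over columns A, C, G, T;
#' `N` becomes `[0.25, 0.25, 0.25, 0.25]`. Case-insensitive.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @return length(seq) x 4 numeric matrix with unit row sums.
#' @export
one_hot <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    stop("invalid base '", chars[which(is.na(idx))[1]], "' at position ",
         which(is.na(idx))[1])
  }
  lut <- rbind(diag(4), rep(0.25, 4))
  m <- lut[idx, , drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  m
}

#' Decode a one-hot matrix back to a DNA string
#' @param m L x 4 one-hot matrix.
#' @return DNA string; uniform rows decode to `"N"`.
#' @export
decode_one_hot <- function(m) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    if (max(r) < 0.5) "N" else bases[which.max(r)]
  }, character(1)), collapse = "")
}

#' Build an encoded dataset from a genome and a TrackSet
#'
#' Bins the genome, labels bins against the tracks, extends kept bins to
#' the sequence context and one-hot encodes the context sequences.
#'
#' @param genome named character vector of chromosome sequences.
#' @param track_set `track_set` defining the tasks.
#' @param chrom_sizes named vector; defaults to `nchar(genome)`.
#' @param bin_size bin width (default 200).
#' @param context_size context width (default 1000).
#' @param overlap_fraction labeling threshold (default 0.5).
#' @return object of class `encoded_dataset`: list with `X`
#'   (`context_size` x 4 x N array), `Y` (N x n_tasks binary matrix),
#'   `coords` (bin + context coordinates), `task_names`, `bin_size`,
#'   `context_size`, `overlap_fraction`; `partition` is `NULL` until
#'   [split_dataset()] is applied.
#' @export
encode_dataset <- function(genome, track_set, chrom_sizes = NULL,
                           bin_size = 200, context_size = 1000,
                           overlap_fraction = 0.5) {
  if (is.null(chrom_sizes)) {
    chrom_sizes <- nchar(genome)
  }
  bins <- bin_genome(chrom_sizes, bin_size)
  lab <- label_bins(bins, track_set, overlap_fraction)
  coords <- extend_bin(lab$bins, context_size, chrom_sizes)
  Y <- lab$Y[attr(coords, "kept"), , drop = FALSE]
  n <- nrow(coords)
  X <- array(0, dim = c(context_size, 4L, n))
  for (i in seq_len(n)) {
    s <- substr(genome[[coords$chrom[i]]], coords$ctx_start[i] + 1L,
                coords$ctx_end[i])
    X[, , i] <- one_hot(s)
  }
  structure(list(X = X, Y = Y, coords = coords,
                 task_names = colnames(Y), partition = NULL,
                 split_seed = NA_integer_, bin_size = bin_size,
                 context_size = context_size,
                 overlap_fraction = overlap_fraction),
            class = "encoded_dataset")
}

#' Partition a dataset into train/validation/test
#'
#' Random permutation under a fixed seed with proportional assignment
#' (default ratio 2:1:1): train gets `floor(N * r1/sum)`, validation
#' `floor(N * r2/sum)`, and the remainder is test. An optional
#' chromosome-holdout mode assigns whole chromosomes to validation/test.
#'
#' @param dataset `encoded_dataset`.
#' @param ratios length-3 numeric ratio (default `c(2, 1, 1)`).
#' @param seed integer seed controlling the permutation.
#' @param method `"random"` (default) or `"chromosome"`.
#' @param holdout chromosome-holdout only: list with `val` and `test`
#'   chromosome name vectors.
#' @return the dataset with `partition` set (factor of
#'   train/val/test) and `split_seed` recorded.
#' @export
split_dataset <- function(dataset, ratios = c(2, 1, 1), seed = 1,
                          method = c("random", "chromosome"),
                          holdout = NULL) {
  method <- match.arg(method)
  n <- dim(dataset$X)[3]
  if (n < 4) stop("need at least 4 examples to partition")
  part <- rep("train", n)
  if (method == "random") {
    n_train <- floor(n * ratios[1] / sum(ratios))
    n_val <- floor(n * ratios[2] / sum(ratios))
    old <- .Random.seed_save()
    set.seed(seed)
    ord <- sample.int(n)
    .Random.seed_restore(old)
    part[ord[seq_len(n_train)]] <- "train"
    part[ord[n_train + seq_len(n_val)]] <- "val"
    part[ord[(n_train + n_val + 1L):n]] <- "test"
  } else {
    if (is.null(holdout)) stop("chromosome holdout needs `holdout`")
    part[dataset$coords$chrom %in% holdout$val] <- "val"
    part[dataset$coords$chrom %in% holdout$test] <- "test"
  }
  dataset$partition <- factor(part, levels = c("train", "val", "test"))
  dataset$split_seed <- as.integer(seed)
  dataset
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Subset an encoded dataset by partition
#' @param dataset partitioned `encoded_dataset`.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return list with `X`, `Y`, `coords` restricted to the partition.
#' @export
dataset_partition <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (is.null(dataset$partition)) stop("dataset is not partitioned")
  idx <- dataset$partition == which
  list(X = dataset$X[, , idx, drop = FALSE],
       Y = dataset$Y[idx, , drop = FALSE],
       coords = dataset$coords[idx, , drop = FALSE])
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf(
    "encoded_dataset: %d examples, context %d bp, %d tasks (%s)\n",
    dim(x$X)[3], x$context_size, ncol(x$Y),
    paste(x$task_names, collapse = ", ")))
  if (!is.null(x$partition)) print(table(x$partition))
  invisible(x)
}
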