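# Peak ingestion, filtering, replicate consolidation and merging.
#
# Peaks are data frames with columns chrom, start, end (0-based half-open),
# neglog10_q and track. Interval arithmetic is delegated to IRanges
# (1-based closed; converted at the boundary).

validate_peaks <- function(peaks) {
  bad <- which(peaks$end <= peaks$start)
  if (length(bad) > 0) {
    stop("malformed intervals (end <= start) at record(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(peaks$neglog10_q) &&
      any(peaks$neglog10_q < 0, na.rm = TRUE)) {
    stop("neglog10_q must be >= 0")
  }
  invisible(peaks)
}

.to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.from_iranges <- function(ir, chrom) {
  data.frame(chrom = chrom,
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

#' Filter peaks on q-value and length
#'
#' Retains peaks with \eqn{-\log_{10}(q) \ge} `min_neglog10_q` and length
#' \eqn{\le} `max_length` bp, preserving input order. Defaults discard
#' peaks with \eqn{-\log_{10}(q) < 2} or length over 10,000 bp.
#'
#' @param peaks peak data frame.
#' @param min_neglog10_q minimum \eqn{-\log_{10}(q)} kept (default 2).
#' @param max_length maximum peak length in bp kept (default 10000).
#' @return filtered peak data frame.
#' @export
filter_peaks <- function(peaks, min_neglog10_q = 2, max_length = 10000) {
  if (nrow(peaks) == 0) return(peaks)
  validate_peaks(peaks)
  keep <- peaks$neglog10_q >= min_neglog10_q &
    (peaks$end - peaks$start) <= max_length
  peaks[keep, , drop = FALSE]
}

#' Remove peaks overlapping a blacklist
#'
#' Any peak sharing at least one base with a blacklist interval is dropped
#' entirely (no trimming).
#'
#' @param peaks peak data frame.
#' @param blacklist data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_sizes optional named vector; blacklist entries on unknown
#'   chromosomes trigger a warning and are ignored.
#' @return peak data frame without blacklisted peaks.
#' @export
subtract_blacklist <- function(peaks, blacklist, chrom_sizes = NULL) {
  if (nrow(peaks) == 0 || is.null(blacklist) || nrow(blacklist) == 0) {
    return(peaks)
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(blacklist$chrom), names(chrom_sizes))
    if (length(unknown) > 0) {
      warning("blacklist chromosomes absent from genome, ignored: ",
              paste(unknown, collapse = ", "))
      blacklist <- blacklist[!(blacklist$chrom %in% unknown), , drop = FALSE]
    }
  }
  drop <- rep(FALSE, nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chrom)
    bl <- blacklist[blacklist$chrom == chrom, , drop = FALSE]
    if (nrow(bl) == 0) next
    hits <- IRanges::overlapsAny(.to_iranges(peaks[pi, , drop = FALSE]),
                                 .to_iranges(bl))
    drop[pi] <- hits
  }
  peaks[!drop, , drop = FALSE]
}

#' Merge intervals into a minimal sorted disjoint set
#'
#' Union semantics: overlapping and abutting intervals are merged; the
#' total number of covered bases is conserved.
#'
#' @param peaks data frame with `chrom`, `start`, `end`.
#' @return data frame of sorted disjoint intervals (`chrom`, `start`, `end`).
#' @export
merge_intervals <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(sort(unique(peaks$chrom)), function(chrom) {
    ir <- .to_iranges(peaks[peaks$chrom == chrom, , drop = FALSE])
    .from_iranges(IRanges::reduce(ir), chrom)
  })
  do.call(rbind, out)
}

#' Consensus intervals across replicates
#'
#' With a single replicate its merged intervals are returned unchanged;
#' with two or more, the maximal intervals covered by at least two
#' replicates are returned (per-replicate coverage counts each replicate
#' once regardless of internal overlap).
#'
#' @param replicates list of peak data frames, one per replicate.
#' @return data frame of sorted disjoint consensus intervals.
#' @export
replicate_consensus <- function(replicates) {
  if (length(replicates) == 0) stop("need at least one replicate")
  if (length(replicates) == 1) return(merge_intervals(replicates[[1]]))
  merged <- lapply(replicates, merge_intervals)
  chroms <- sort(unique(unlist(lapply(merged, function(m) m$chrom))))
  out <- lapply(chroms, function(chrom) {
    irl <- lapply(merged, function(m) {
      .to_iranges(m[m$chrom == chrom, , drop = FALSE])
    })
    maxend <- max(c(0L, unlist(lapply(irl, IRanges::end))))
    if (maxend == 0L) return(NULL)
    cov <- Reduce(`+`, lapply(irl, IRanges::coverage, width = maxend))
    sl <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
    if (length(sl) == 0) return(NULL)
    .from_iranges(sl, chrom)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a clean TrackSet from raw replicate peak files
#'
#' Applies, per track: q/length filtering, blacklist removal, replicate
#' consensus (intersection of at least two replicates when more than one
#' is available), and a final merge. Filtering precedes the replicate
#' intersection.
#'
#' @param replicate_peaks named list: track label -> list of peak data
#'   frames (one per replicate).
#' @param blacklist optional blacklist data frame.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param min_neglog10_q,max_length see [filter_peaks()].
#' @param genome_id assembly label stored on the result.
#' @return object of class `track_set`: list with `tracks` (named list of
#'   sorted disjoint interval data frames) and `genome_id`.
#' @export
build_track_set <- function(replicate_peaks, blacklist = NULL,
                            chrom_sizes = NULL, min_neglog10_q = 2,
                            max_length = 10000, genome_id = "custom") {
  tracks <- lapply(replicate_peaks, function(reps) {
    reps <- lapply(reps, filter_peaks, min_neglog10_q = min_neglog10_q,
                   max_length = max_length)
    if (!is.null(blacklist)) {
      reps <- lapply(reps, subtract_blacklist, blacklist = blacklist,
                     chrom_sizes = chrom_sizes)
    }
    merge_intervals(replicate_consensus(reps))
  })
  structure(list(tracks = tracks, genome_id = genome_id),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set (%s): %d tracks\n", x$genome_id, length(x$tracks)))
  for (nm in names(x$tracks)) {
    t <- x$tracks[[nm]]
    cat(sprintf("  %s: %d intervals, %d bp\n", nm, nrow(t),
                sum(t$end - t$start)))
  }
  invisible(x)
}
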