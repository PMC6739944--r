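#' @useDynLib epimotif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rgamma cor pt sd lm coef predict
#' @importFrom utils read.table write.table head tail
NULL

# All genomic coordinates inside the package are 0-based, half-open
# (BED-native). 1-based formats (wiggle fixedStep/variableStep, IRanges)
# are converted at the readers/writers.

#' Read a BED-like peak file
#'
#' Reads a tab-separated BED-like file (narrowPeak, broadPeak or plain BED)
#' into a peak data frame. The \eqn{-\log_{10}(q)} column index is
#' configurable and defaults to column 9, the narrowPeak/broadPeak
#' convention.
#'
#' @param path file path.
#' @param qvalue_col 1-based column index holding \eqn{-\log_{10}(q)};
#'   set to `NA` for files without one (filled with `Inf`, i.e. never
#'   filtered on q).
#' @param track optional track label `"cell:mark"` attached to every peak.
#' @return data frame with columns `chrom`, `start`, `end`, `neglog10_q`,
#'   `track` (0-based half-open coordinates).
#' @export
read_bed <- function(path, qvalue_col = 9, track = NA_character_) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  q <- if (!is.na(qvalue_col) && ncol(df) >= qvalue_col) {
    as.numeric(df[[qvalue_col]])
  } else {
    rep(Inf, nrow(df))
  }
  peaks <- data.frame(chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]),
                      end   = as.integer(df[[3]]),
                      neglog10_q = q,
                      track = track,
                      stringsAsFactors = FALSE)
  validate_peaks(peaks)
  peaks
}

#' Write intervals as sorted BED
#'
#' @param x data frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand` columns are written as BED columns 4-6.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  ord <- order(x$chrom, x$start, x$end)
  x <- x[ord, , drop = FALSE]
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name)) {
    cols <- c(cols, list(x$name))
    if (!is.null(x$score)) {
      cols <- c(cols, list(formatC(x$score, format = "g", digits = 6)))
      if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
    }
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#'
#' @param path file path (chromosome name, length in bp).
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  sizes <- as.integer(df[[2]])
  if (any(sizes <= 0)) stop("chromosome sizes must be positive")
  names(sizes) <- as.character(df[[1]])
  sizes
}

#' Write a chrom.sizes table
#' @param sizes named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

# ---- wiggle / bedGraph --------------------------------------------------

#' Read a per-base signal track (wiggle or bedGraph)
#'
#' Supports fixedStep and variableStep wiggle (with `span`/`step`) and
#' 4-column bedGraph. Returns dense per-chromosome vectors; bases the file
#' does not cover are `NA`.
#'
#' @param path file path.
#' @param chrom_sizes optional named vector; when given, each vector is
#'   allocated at full chromosome length.
#' @return named list of numeric vectors; element `i` of a vector is the
#'   score of 0-based position `i - 1`.
#' @export
read_wiggle <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- grepl("^(fixedStep|variableStep|track)", lines)
  out <- list()
  ensure <- function(out, chrom, upto) {
    n0 <- if (is.null(out[[chrom]])) 0L else length(out[[chrom]])
    target <- if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
      max(upto, chrom_sizes[[chrom]])
    } else {
      upto
    }
    if (n0 < target) out[[chrom]] <- c(out[[chrom]], rep(NA_real_, target - n0))
    out
  }
  # bedGraph: no header lines and 4 columns
  first_data <- lines[!is_hdr][1]
  if (!any(is_hdr) && length(strsplit(first_data, "[ \t]+")[[1]]) == 4) {
    df <- read.table(text = lines, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(df))) {
      chrom <- df[[1]][i]
      out <- ensure(out, chrom, df[[3]][i])
      out[[chrom]][(df[[2]][i] + 1L):df[[3]][i]] <- df[[4]][i]
    }
    return(out)
  }
  hdr_idx <- which(is_hdr)
  hdr_idx <- hdr_idx[!grepl("^track", lines[hdr_idx])]
  if (length(hdr_idx) == 0) stop("not a wiggle file: ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (h in seq_along(hdr_idx)) {
    hdr <- lines[hdr_idx[h]]
    body <- lines[(hdr_idx[h] + 1L):(bounds[h + 1L] - 1L)]
    body <- body[!grepl("^track", body)]
    kv <- regmatches(hdr, gregexpr("[A-Za-z]+=\\S+", hdr))[[1]]
    opts <- list()
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      opts[[parts[1]]] <- parts[2]
    }
    chrom <- opts$chrom
    span <- if (is.null(opts$span)) 1L else as.integer(opts$span)
    if (grepl("^fixedStep", hdr)) {
      start1 <- as.integer(opts$start)      # wiggle is 1-based
      step <- if (is.null(opts$step)) span else as.integer(opts$step)
      vals <- as.numeric(body)
      last <- start1 + (length(vals) - 1L) * step + span - 1L
      out <- ensure(out, chrom, last)
      for (k in seq_along(vals)) {
        s <- start1 + (k - 1L) * step
        out[[chrom]][s:(s + span - 1L)] <- vals[k]
      }
    } else {
      df <- read.table(text = body, stringsAsFactors = FALSE)
      out <- ensure(out, chrom, max(df[[1]]) + span - 1L)
      for (k in seq_len(nrow(df))) {
        s <- df[[1]][k]
        out[[chrom]][s:(s + span - 1L)] <- df[[2]][k]
      }
    }
  }
  out
}

#' Write a per-base track as fixedStep wiggle
#'
#' @param track named list of per-chromosome numeric vectors (element `i`
#'   is the score at 0-based position `i - 1`).
#' @param path output path.
#' @param digits decimal digits written (default 4).
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path, digits = 4) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
    writeLines(formatC(round(track[[chrom]], digits), format = "fg",
                       digits = digits, drop0trailing = TRUE), con)
  }
  invisible(path)
}

# ---- MEME minimal motif format ------------------------------------------

#' Construct a PWM motif object
#'
#' @param freq width x 4 matrix of per-position base probabilities
#'   (columns A, C, G, T; rows sum to 1).
#' @param name motif identifier.
#' @param n_sites number of sites/k-mers supporting the matrix.
#' @param beta_used activation-threshold ratio used at extraction, if any.
#' @param source provenance string (e.g. `"model1/filter007"`).
#' @return object of class `pwm_motif`.
#' @export
pwm_motif <- function(freq, name, n_sites = NA_integer_,
                      beta_used = NA_real_, source = NA_character_) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4) stop("PWM must have 4 columns (A,C,G,T)")
  if (nrow(freq) < 1) stop("PWM must have width >= 1")
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9)) stop("PWM rows must sum to 1")
  colnames(freq) <- c("A", "C", "G", "T")
  structure(list(name = name, freq = freq,
                 n_sites = n_sites, beta_used = beta_used,
                 info_content = information_content(freq),
                 source = source),
            class = "pwm_motif")
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("pwm_motif %s  width=%d  IC=%.2f bits  n_sites=%s\n",
              x$name, nrow(x$freq), x$info_content,
              ifelse(is.na(x$n_sites), "?", x$n_sites)))
  invisible(x)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of [pwm_motif] objects.
#' @param path output path.
#' @param background length-4 background frequencies written in the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  if (inherits(motifs, "pwm_motif")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (m in motifs) {
    ns <- if (is.na(m$n_sites)) 20L else as.integer(m$n_sites)
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$freq), ns), con)
    writeLines(apply(m$freq, 1, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' @param path file path.
#' @return named list of [pwm_motif] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME motif file: ", path)
  }
  midx <- grep("^MOTIF", lines)
  motifs <- list()
  for (i in seq_along(midx)) {
    name <- strsplit(trimws(lines[midx[i]]), "[ \t]+")[[1]][2]
    j <- midx[i] + 1L
    while (j <= length(lines) && !grepl("^letter-probability", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) stop("MOTIF ", name, " has no probability matrix")
    hdr <- lines[j]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
    ns <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites= *([0-9]+).*", "\\1", hdr))
    } else NA_integer_
    rows <- lines[(j + 1L):(j + w)]
    freq <- do.call(rbind, lapply(strsplit(trimws(rows), "[ \t]+"),
                                  as.numeric))
    freq <- freq / rowSums(freq)   # tolerate rounding in the file
    motifs[[name]] <- pwm_motif(freq, name, n_sites = ns)
  }
  motifs
}

# ---- FASTA (via Biostrings) ---------------------------------------------

#' Read a genome FASTA into character vectors
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}
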