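# Motif comparison, bidirectional-best-hit merging, known-motif
# annotation, and motif-profile clustering of models.

.perm_matrix <- function(w, n_perm, seed) {
  old <- .Random.seed_save()
  set.seed(seed)
  m <- vapply(seq_len(n_perm), function(i) sample.int(w) - 1L,
              integer(w))
  .Random.seed_restore(old)
  m
}

#' Compare two motifs over all offsets and orientations
#'
#' Scans every alignment offset with at least `min_overlap` aligned
#' columns, in both orientations (the target is reverse-complemented for
#' the minus orientation); the score of an offset is the mean per-column
#' Pearson correlation of the frequency vectors. The p-value comes from a
#' permutation null in which the target's columns are shuffled and the
#' best score recomputed.
#'
#' @param query,target [pwm_motif()] objects.
#' @param min_overlap minimum aligned columns (default 7).
#' @param n_perm permutations for the null (default 1000).
#' @param seed permutation seed.
#' @param n_targets number of targets in the search the comparison is
#'   part of; the reported E-value is `p * n_targets`.
#' @return list (class `motif_match`): `query`, `target`, `score`,
#'   `offset` (target start in query coordinates), `orientation`,
#'   `overlap`, `p_value`, `e_value`.
#' @export
compare_motifs <- function(query, target, min_overlap = 7, n_perm = 1000,
                           seed = 1, n_targets = 1) {
  if (nrow(query$freq) < min_overlap || nrow(target$freq) < min_overlap) {
    stop("motif width below min_overlap")
  }
  perms <- .perm_matrix(nrow(target$freq), n_perm, seed)
  res <- .motif_compare_cpp(query$freq, target$freq, as.integer(min_overlap),
                            perms)
  structure(list(query = query$name, target = target$name,
                 score = res$score, offset = res$offset,
                 orientation = res$orientation, overlap = res$overlap,
                 p_value = res$p_value,
                 e_value = res$p_value * n_targets),
            class = "motif_match")
}

#' Bidirectional-best-hit graph over a motif set
#'
#' Each motif's best hit is its lowest-E match (ties broken by longer
#' overlap, then name); an edge joins `a` and `b` iff each is the other's
#' best hit and both E-values are below `e_threshold`.
#'
#' @param motifs named list of [pwm_motif()] (at least 2).
#' @param e_threshold merge threshold on the E-value (default 0.1).
#' @param min_overlap minimum aligned columns (default 7).
#' @param n_perm,seed permutation-null parameters.
#' @return list with `edges` (data frame `a`, `b`, `e_a`, `e_b`) and
#'   `matches` (all pairwise comparisons as a data frame).
#' @export
bbh_graph <- function(motifs, e_threshold = 0.1, min_overlap = 7,
                      n_perm = 1000, seed = 1) {
  if (length(motifs) < 2) stop("need at least 2 motifs")
  nms <- names(motifs)
  n_targets <- length(motifs) - 1   # each motif is searched against rest
  rows <- list()
  for (a in seq_along(motifs)) {
    for (b in seq_along(motifs)) {
      if (a == b) next
      m <- compare_motifs(motifs[[a]], motifs[[b]], min_overlap, n_perm,
                          seed = seed + a, n_targets = n_targets)
      rows[[length(rows) + 1]] <- data.frame(
        query = nms[a], target = nms[b], score = m$score,
        overlap = m$overlap, orientation = m$orientation,
        offset = m$offset, p_value = m$p_value, e_value = m$e_value,
        stringsAsFactors = FALSE)
    }
  }
  matches <- do.call(rbind, rows)
  best_hit <- function(q) {
    mm <- matches[matches$query == q, , drop = FALSE]
    mm <- mm[order(mm$e_value, -mm$overlap, -mm$score, mm$target),
             , drop = FALSE]
    mm[1, , drop = FALSE]
  }
  bests <- do.call(rbind, lapply(nms, best_hit))
  edges <- list()
  for (i in seq_along(nms)) {
    a <- nms[i]
    ba <- bests[bests$query == a, ]
    b <- ba$target
    bb <- bests[bests$query == b, ]
    if (bb$target == a && a < b &&
        ba$e_value < e_threshold && bb$e_value < e_threshold) {
      edges[[length(edges) + 1]] <- data.frame(
        a = a, b = b, e_a = ba$e_value, e_b = bb$e_value,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), e_a = numeric(),
               e_b = numeric(), stringsAsFactors = FALSE)
  list(edges = edges, matches = matches)
}

#' Connected components of the BBH graph as motif clusters
#'
#' Components partition the motif set; motifs without edges form
#' singleton clusters (model-specific motifs).
#'
#' @param edges data frame with columns `a`, `b` (motif names).
#' @param motifs named list of all motifs in the set.
#' @return list of clusters, each a list with `members` (names),
#'   `is_singleton`, and `merged` (a [pwm_motif()]; the member itself for
#'   singletons, otherwise [merge_cluster_pwm()]).
#' @export
connected_components <- function(edges, motifs) {
  nms <- names(motifs)
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nms))
  comp <- igraph::components(g)
  clusters <- lapply(seq_len(comp$no), function(ci) {
    members <- nms[comp$membership == ci]
    merged <- if (length(members) == 1) {
      motifs[[members]]
    } else {
      merge_cluster_pwm(motifs[members],
                        name = paste0("cluster_", ci))
    }
    list(members = members, is_singleton = length(members) == 1,
         merged = merged)
  })
  clusters
}

#' Merge a cluster of motifs into one PWM
#'
#' Members are aligned to the first member at their best pairwise offset
#' (reverse-complemented when the best orientation is minus); per-member
#' site counts (`freq * n_sites`) are pooled over the aligned columns and
#' renormalized. The merged width covers the union of aligned columns.
#'
#' @param members named list of [pwm_motif()] (cluster members).
#' @param name name of the merged motif.
#' @param min_overlap,n_perm,seed alignment parameters (permutations are
#'   only used for the reported p-values, not the offsets).
#' @return a [pwm_motif()].
#' @export
merge_cluster_pwm <- function(members, name = "merged", min_overlap = 7,
                              n_perm = 100, seed = 1) {
  if (length(members) == 0) stop("empty cluster")
  if (length(members) == 1) return(members[[1]])
  ref <- members[[1]]
  placed <- list(list(freq = ref$freq,
                      n = ifelse(is.na(ref$n_sites), 20, ref$n_sites),
                      at = 0L))
  for (i in seq(2, length(members))) {
    m <- members[[i]]
    cmp <- compare_motifs(ref, m, min_overlap, n_perm, seed)
    fr <- m$freq
    if (cmp$orientation == "-") fr <- fr[rev(seq_len(nrow(fr))),
                                         rev(seq_len(ncol(fr)))]
    colnames(fr) <- c("A", "C", "G", "T")
    placed[[i]] <- list(freq = fr,
                        n = ifelse(is.na(m$n_sites), 20, m$n_sites),
                        at = cmp$offset)
  }
  lo <- min(vapply(placed, function(p) p$at, numeric(1)))
  hi <- max(vapply(placed, function(p) p$at + nrow(p$freq), numeric(1)))
  w <- hi - lo
  counts <- matrix(0, w, 4)
  for (p in placed) {
    rows <- (p$at - lo + 1):(p$at - lo + nrow(p$freq))
    counts[rows, ] <- counts[rows, ] + p$freq * p$n
  }
  counts <- counts + 0.5                          # pseudocount
  freq <- counts / rowSums(counts)
  pwm_motif(freq, name,
            n_sites = sum(vapply(placed, function(p) p$n, numeric(1))),
            source = paste(names(members), collapse = "+"))
}

#' Annotate motifs against a known-motif database
#'
#' For each motif, the best database match (lowest E-value, i.e. p-value
#' times database size) is reported; motifs whose best E exceeds the
#' threshold are called novel.
#'
#' @param motifs named list of [pwm_motif()].
#' @param known_db named list of [pwm_motif()] (e.g. from [read_meme()]).
#' @param e_threshold maximum E-value for a match (default 0.5).
#' @param min_overlap,n_perm,seed comparison parameters.
#' @return data frame: `motif`, `match` (database name or `NA` for
#'   novel), `score`, `e_value`, `novel`.
#' @export
match_known <- function(motifs, known_db, e_threshold = 0.5,
                        min_overlap = 7, n_perm = 1000, seed = 1) {
  if (length(known_db) == 0) {
    return(data.frame(motif = names(motifs), match = NA_character_,
                      score = NA_real_, e_value = NA_real_,
                      novel = TRUE, stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(motifs), function(i) {
    best <- NULL
    for (j in seq_along(known_db)) {
      ov <- min(min_overlap, nrow(motifs[[i]]$freq),
                nrow(known_db[[j]]$freq))
      m <- compare_motifs(motifs[[i]], known_db[[j]], ov, n_perm,
                          seed = seed + i, n_targets = length(known_db))
      if (is.null(best) || m$e_value < best$e_value ||
          (m$e_value == best$e_value && m$overlap > best$overlap)) {
        best <- m
      }
    }
    hit <- best$e_value <= e_threshold
    data.frame(motif = names(motifs)[i],
               match = if (hit) best$target else NA_character_,
               score = best$score, e_value = best$e_value,
               novel = !hit, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster models by their motif-sharing profiles
#'
#' Computes pairwise Hamming distances between the models' binary
#' unique-motif presence profiles and builds an average-linkage
#' (UPGMA) tree.
#'
#' @param presence binary matrix, models x unique motifs.
#' @return list with `hclust` (the tree), `newick` (serialized tree) and
#'   `dist` (the Hamming distance matrix).
#' @export
model_profile_clustering <- function(presence) {
  if (nrow(presence) < 2) stop("need at least 2 models")
  d <- stats::dist(presence, method = "manhattan")  # = Hamming on 0/1
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy), dist = d)
}

#' Motif sharing across models
#'
#' @param clusters cluster list from [connected_components()].
#' @param motif_models named character vector mapping each original motif
#'   name to its source model.
#' @return list with `histogram` (named vector: number of unique motifs
#'   shared by exactly 1..M models) and `combinations` (counts per model
#'   combination, Venn-style).
#' @export
sharing_summary <- function(clusters, motif_models) {
  model_sets <- lapply(clusters, function(cl) {
    sort(unique(unname(motif_models[cl$members])))
  })
  n_shared <- vapply(model_sets, length, integer(1))
  models <- sort(unique(unname(motif_models)))
  hist <- vapply(seq_along(models), function(k) sum(n_shared == k),
                 integer(1))
  names(hist) <- as.character(seq_along(models))
  combos <- table(vapply(model_sets, paste, character(1),
                         collapse = "+"))
  list(histogram = hist, combinations = combos)
}
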