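# Motif comparison, BBH merging, known-motif annotation and
# motif-profile clustering.

rand_pwm <- function(w, name, conc = 1) {
  f <- matrix(rgamma(w * 4, conc), w, 4)
  pwm_motif(f / rowSums(f), name)
}

test_that("a motif matches itself perfectly, in either orientation", {
  set.seed(41)
  m <- pwm_motif(consensus_pwm("TTTGCAGGA", 0.9), "self")
  hit <- compare_motifs(m, m, n_perm = 200)
  expect_equal(hit$score, 1, tolerance = 1e-12)
  expect_equal(hit$offset, 0)
  expect_equal(hit$orientation, "+")
  expect_equal(hit$p_value, 1 / 201)     # minimal attainable
  # vs its reverse complement: same best score, minus orientation
  rc <- pwm_motif(m$freq[9:1, 4:1], "rc")
  hit_rc <- compare_motifs(m, rc, n_perm = 200)
  expect_equal(hit_rc$score, 1, tolerance = 1e-12)
  expect_equal(hit_rc$orientation, "-")
  expect_error(compare_motifs(m, rand_pwm(4, "short")), "min_overlap")
})

test_that("best offset and score agree with exhaustive enumeration", {
  col_cor0 <- function(a, b) {
    if (sd(a) < 1e-7 || sd(b) < 1e-7) return(0)
    cor(a, b)
  }
  brute <- function(Q, T, min_ov) {
    best <- -Inf; off <- NA
    for (s in (min_ov - nrow(T)):(nrow(Q) - min_ov)) {
      q0 <- max(0, s); t0 <- max(0, -s)
      len <- min(nrow(Q) - q0, nrow(T) - t0)
      if (len < min_ov) next
      sc <- mean(vapply(seq_len(len) - 1, function(j) {
        col_cor0(Q[q0 + j + 1, ], T[t0 + j + 1, ])
      }, numeric(1)))
      if (sc > best) { best <- sc; off <- s }
    }
    list(score = best, offset = off)
  }
  set.seed(42)
  for (i in 1:20) {
    q <- rand_pwm(8, "q", conc = 0.5)
    t <- rand_pwm(8, "t", conc = 0.5)
    got <- compare_motifs(q, t, min_overlap = 7, n_perm = 10)
    fw <- brute(q$freq, t$freq, 7)
    rv <- brute(q$freq, t$freq[8:1, 4:1], 7)
    want <- if (fw$score >= rv$score) fw else rv
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$offset, want$offset)
  }
})

test_that("comparison score is symmetric under query/target swap", {
  set.seed(43)
  for (i in 1:10) {
    a <- rand_pwm(9, "a"); b <- rand_pwm(11, "b")
    sa <- compare_motifs(a, b, n_perm = 10)$score
    sb <- compare_motifs(b, a, n_perm = 10)$score
    expect_equal(sa, sb, tolerance = 1e-12)
  }
})

test_that("BBH graph joins exactly the mutual best hits below E", {
  set.seed(44)
  core <- consensus_pwm("TGACGTCATC", 0.9)
  dup1 <- pwm_motif(core, "dup1")
  jit <- pmax(core + rnorm(40, 0, 0.01), 1e-3)
  dup2 <- pwm_motif(jit / rowSums(jit), "dup2")
  r1 <- rand_pwm(10, "r1"); r2 <- rand_pwm(10, "r2")
  g <- bbh_graph(list(dup1 = dup1, dup2 = dup2, r1 = r1, r2 = r2),
                 n_perm = 500, seed = 9)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(c(g$edges$a, g$edges$b), c("dup1", "dup2"))
  # all-dissimilar random motifs: no edges (permutation-null calibration)
  set.seed(45)
  rs <- lapply(1:4, function(i) rand_pwm(10, paste0("x", i), conc = 0.5))
  names(rs) <- paste0("x", 1:4)
  g2 <- bbh_graph(rs, n_perm = 500, seed = 10)
  expect_equal(nrow(g2$edges), 0)
  expect_error(bbh_graph(rs[1]), "at least 2")
})

test_that("best-hit asymmetry prevents an edge", {
  # b sits between a and c: a's best is b, b's best is c
  set.seed(46)
  base <- consensus_pwm("TGACGTCATC", 0.95)
  drift <- function(f, k, sd) {
    g <- pmax(f + matrix(rnorm(length(f), 0, sd), nrow(f)), 1e-3)
    pwm_motif(g / rowSums(g), k)
  }
  a <- drift(base, "a", 0.22)
  b <- drift(base, "b", 0.05)
  c <- drift(b$freq, "c", 0.01)
  g <- bbh_graph(list(a = a, b = b, c = c), n_perm = 300, seed = 3)
  # b and c are mutual best hits; a-b must not be an edge
  if (nrow(g$edges) > 0) {
    expect_false(any(g$edges$a == "a" | g$edges$b == "a"))
  }
  m <- g$matches[g$matches$query == "b", ]
  m <- m[order(m$e_value, -m$overlap, -m$score, m$target), ]
  expect_equal(m$target[1], "c")
})

test_that("connected components partition the motif set", {
  set.seed(47)
  motifs <- lapply(1:5, function(i) rand_pwm(8, paste0("m", i)))
  names(motifs) <- paste0("m", 1:5)
  # no edges -> all singletons
  none <- data.frame(a = character(), b = character())
  cl <- connected_components(none, motifs)
  expect_length(cl, 5)
  expect_true(all(vapply(cl, function(x) x$is_singleton, logical(1))))
  # triangle -> one 3-cluster plus 2 singletons
  tri <- data.frame(a = c("m1", "m2", "m3"), b = c("m2", "m3", "m1"))
  cl2 <- connected_components(tri, motifs)
  sizes <- sort(vapply(cl2, function(x) length(x$members), integer(1)))
  expect_equal(sizes, c(1L, 1L, 3L))
  # every motif in exactly one cluster
  all_members <- unlist(lapply(cl2, function(x) x$members))
  expect_setequal(all_members, names(motifs))
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("components equal a depth-first-search oracle on random graphs", {
  dfs_components <- function(nodes, edges) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (r in seq_len(nrow(edges))) {
      adj[[edges$a[r]]] <- c(adj[[edges$a[r]]], edges$b[r])
      adj[[edges$b[r]]] <- c(adj[[edges$b[r]]], edges$a[r])
    }
    comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
    cid <- 0L
    for (n in nodes) {
      if (!is.na(comp[n])) next
      cid <- cid + 1L
      stack <- n
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        stack <- c(stack, adj[[v]])
      }
    }
    comp
  }
  set.seed(48)
  motifs <- lapply(1:8, function(i) rand_pwm(8, paste0("n", i)))
  names(motifs) <- paste0("n", 1:8)
  for (case in 1:100) {
    ne <- sample(0:8, 1)
    edges <- data.frame(a = sample(names(motifs), ne, TRUE),
                        b = sample(names(motifs), ne, TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    cl <- connected_components(edges, motifs)
    oracle <- dfs_components(names(motifs), edges)
    # same partition: members together iff same oracle component
    got <- setNames(rep(NA_integer_, 8), names(motifs))
    for (i in seq_along(cl)) got[cl[[i]]$members] <- i
    expect_equal(length(unique(got)), length(unique(oracle)))
    same_got <- outer(got, got, "==")
    same_orc <- outer(oracle, oracle, "==")
    expect_identical(same_got, same_orc)
  }
})

test_that("cluster merging pools aligned counts", {
  core <- pwm_motif(consensus_pwm("TGACGTCA", 0.95), "core",
                    n_sites = 50L)
  # singleton: unchanged
  expect_identical(merge_cluster_pwm(list(core = core)), core)
  # two identical members: same PWM (up to the count pseudocount)
  twin <- merge_cluster_pwm(list(a = core, b = core), name = "twin")
  expect_lt(max(abs(twin$freq - core$freq)), 0.03)
  expect_equal(twin$n_sites, 100)
  # shifted copies: merged width covers the union of aligned columns
  left <- pwm_motif(rbind(consensus_pwm("GG", 0.95),
                          consensus_pwm("TGACGTCA", 0.95)), "left",
                    n_sites = 50L)
  merged <- merge_cluster_pwm(list(left = left, core = core),
                              name = "m")
  expect_equal(nrow(merged$freq), 10)   # union of 10 and 8 at offset +2
})

test_that("known-motif annotation finds self-matches and flags novels", {
  set.seed(49)
  known <- list(K1 = pwm_motif(consensus_pwm("TGACGTCATC", 0.9), "K1"),
                K2 = pwm_motif(consensus_pwm("GGGACTTTCC", 0.9), "K2"))
  q <- list(hit = pwm_motif(known$K1$freq, "hit"),
            miss = rand_pwm(10, "miss", conc = 0.5))
  ann <- match_known(q, known, n_perm = 500)
  expect_equal(ann$match[ann$motif == "hit"], "K1")
  expect_false(ann$novel[ann$motif == "hit"])
  expect_true(ann$novel[ann$motif == "miss"])
  # empty database: everything is novel
  ann0 <- match_known(q, list())
  expect_true(all(ann0$novel))
})

test_that("model-profile clustering reproduces hand-computed UPGMA", {
  # 4 models, binary profiles with known Hamming distances
  P <- rbind(m1 = c(1, 1, 0, 0, 0),
             m2 = c(1, 1, 0, 0, 1),    # d(m1,m2) = 1
             m3 = c(0, 0, 1, 1, 0),    # d(m1,m3) = 4, d(m2,m3) = 5
             m4 = c(0, 0, 1, 1, 1))    # d(m3,m4) = 1, d(m1,m4)=5, d(m2,m4)=4
  res <- model_profile_clustering(P)
  hc <- res$hclust
  # first merges: (m1,m2) and (m3,m4) at height 1
  expect_equal(sort(hc$height), c(1, 1, 4.5))
  # final merge at mean cross distance (4+5+5+4)/4 = 4.5
  expect_equal(max(hc$height), 4.5)
  # heights non-decreasing along merges (average-linkage ultrametric)
  expect_true(all(diff(hc$height) >= 0))
  expect_match(res$newick, "^\\(")
  expect_match(res$newick, "m1")
  # identical profiles merge first at distance 0
  P2 <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0))
  hc2 <- model_profile_clustering(P2)$hclust
  expect_equal(min(hc2$height), 0)
  # complementary profiles are maximally distant
  P3 <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(as.numeric(model_profile_clustering(P3)$dist), 4)
  expect_error(model_profile_clustering(P[1, , drop = FALSE]),
               "at least 2")
})

test_that("sharing summary counts motifs by number of source models", {
  clusters <- list(
    list(members = c("A.m1", "B.m1"), is_singleton = FALSE),
    list(members = "A.m2", is_singleton = TRUE),
    list(members = c("A.m3", "B.m2", "C.m1"), is_singleton = FALSE),
    list(members = "C.m2", is_singleton = TRUE))
  mm <- c(A.m1 = "A", B.m1 = "B", A.m2 = "A", A.m3 = "A",
          B.m2 = "B", C.m1 = "C", C.m2 = "C")
  sh <- sharing_summary(clusters, mm)
  expect_equal(unname(sh$histogram), c(2L, 1L, 1L))
  expect_equal(unname(sh$combinations[["A+B+C"]]), 1L)
  # disjoint models: all shared-by-1
  cl1 <- list(list(members = "A.m1"), list(members = "B.m1"))
  sh1 <- sharing_summary(cl1, mm)
  expect_equal(unname(sh1$histogram[1]), 2L)
  # fuzz vs set-algebra oracle
  set.seed(50)
  models <- c("M1", "M2", "M3")
  for (case in 1:50) {
    n <- sample(3:10, 1)
    motif_models <- setNames(sample(models, n, TRUE),
                             paste0("mm", seq_len(n)))
    split_sizes <- diff(sort(unique(c(0, sample(seq_len(n), 3), n))))
    idx <- split(sample(names(motif_models)),
                 rep(seq_along(split_sizes), split_sizes))
    cls <- lapply(idx, function(m) list(members = m))
    sh <- sharing_summary(cls, motif_models)
    n_models <- length(unique(unname(motif_models)))
    oracle <- table(factor(vapply(idx, function(m) {
      length(unique(motif_models[m]))
    }, integer(1)), levels = seq_len(n_models)))
    expect_equal(unname(sh$histogram), as.integer(oracle))
  }
})
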