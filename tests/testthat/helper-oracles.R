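# Independent oracles and small fixtures used across the suite.

# Brute-force Mk tree likelihood: sum over every assignment of states to
# internal nodes, multiplying root prior and per-edge transition
# probabilities from the closed-form ER matrix.
enum_mk_lik <- function(tree, tip_state, q, k, prior = rep(1 / k, k)) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  grids <- do.call(expand.grid, rep(list(seq_len(k)), nn))
  pm <- lapply(tree$edge.length, function(t) melinvade:::er_pmatrix(q, t, k))
  tot <- 0
  for (r in seq_len(nrow(grids))) {
    assign <- c(tip_state, as.integer(grids[r, ]))
    lik <- prior[assign[ntip + 1]]
    for (ei in seq_len(nrow(tree$edge))) {
      lik <- lik * pm[[ei]][assign[tree$edge[ei, 1]], assign[tree$edge[ei, 2]]]
    }
    tot <- tot + lik
  }
  tot
}

# Brute-force marginal posteriors at internal nodes by the same enumeration.
enum_mk_marginals <- function(tree, tip_state, q, k, prior = rep(1 / k, k)) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  grids <- do.call(expand.grid, rep(list(seq_len(k)), nn))
  pm <- lapply(tree$edge.length, function(t) melinvade:::er_pmatrix(q, t, k))
  w <- numeric(nrow(grids))
  for (r in seq_len(nrow(grids))) {
    assign <- c(tip_state, as.integer(grids[r, ]))
    lik <- prior[assign[ntip + 1]]
    for (ei in seq_len(nrow(tree$edge))) {
      lik <- lik * pm[[ei]][assign[tree$edge[ei, 1]], assign[tree$edge[ei, 2]]]
    }
    w[r] <- lik
  }
  m <- matrix(0, nn, k)
  for (j in seq_len(nn)) {
    for (s in seq_len(k)) m[j, s] <- sum(w[grids[, j] == s])
  }
  m / rowSums(m)
}

# Brute-force per-pair Gower distance (observed ranges, pairwise deletion).
brute_gower <- function(m) {
  rng <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) 0 else max(v) - min(v)
  })
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0; cnt <- 0
      for (c in seq_len(ncol(m))) {
        if (!is.na(m[i, c]) && !is.na(m[j, c]) && rng[c] > 0) {
          s <- s + abs(m[i, c] - m[j, c]) / rng[c]
          cnt <- cnt + 1
        }
      }
      D[i, j] <- s / cnt
    }
  }
  D
}

# Exact tail probability that a uniformly drawn 3-subset of `values` has a
# sum strictly greater than `threshold` (counts all C(n,3) subsets via a
# sort + binary search, no sampling).
exact_triple_tail <- function(values, threshold) {
  v <- sort(values)
  n <- length(v)
  total <- choose(n, 3)
  cnt <- 0
  for (i in seq_len(n - 2)) {
    j <- seq(i + 1, n - 1)
    thr <- threshold - v[i] - v[j]
    pos <- findInterval(thr, v)  # last index with v <= thr
    cnt <- cnt + sum(n - pmax(j, pos))
  }
  cnt / total
}

# Random valid character matrix (complete data) for distance property tests.
random_score_matrix <- function(n, seed) {
  def <- canonical_character_set()
  withr::with_seed(seed, {
    m <- sapply(seq_len(nrow(def)), function(i) {
      sample(def$states[[i]], n, replace = TRUE)
    })
    colnames(m) <- def$code
    rownames(m) <- paste0("s", seq_len(n))
    storage.mode(m) <- "double"
    m
  })
}

# Small rooted random tree with its tip states, for enumeration tests.
random_mk_case <- function(seed) {
  withr::with_seed(seed, {
    ntip <- sample(3:6, 1)
    k <- sample(2:3, 1)
    tree <- ape::rtree(ntip)
    list(tree = tree, k = k,
         tip_state = sample.int(k, ntip, replace = TRUE),
         q = runif(1, 0.05, 1.5))
  })
}
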