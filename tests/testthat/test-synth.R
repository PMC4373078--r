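test_that("generators are pure functions of their seeds", {
  t1 <- simulate_yule_tree(20, 2, seed = 5)
  t2 <- simulate_yule_tree(20, 2, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(simulate_yule_tree(20, 2, seed = 6)),
                         ape::write.tree(t1)))
  s1 <- simulate_mk_states(t1, 0.2, c("A", "B"), seed = 7)
  s2 <- simulate_mk_states(t1, 0.2, c("A", "B"), seed = 7)
  expect_identical(s1, s2)
  g1 <- simulate_population_grid(15, 15, seed = 8)
  g2 <- simulate_population_grid(15, 15, seed = 8)
  expect_identical(g1$values, g2$values)
  m1 <- simulate_character_matrix(3, 4, 0.3, seed = 9)
  m2 <- simulate_character_matrix(3, 4, 0.3, seed = 9)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("Yule trees match pure-birth expectations", {
  expect_error(simulate_yule_tree(1, 1), "n_tips")
  # 2 tips: a single cherry
  ch <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(ch$tip.label), 2)
  expect_equal(ch$Nnode, 1)
  # E[total length] = (n-1)/lambda; E[height] = sum_{i=2..n} 1/(i lambda)
  n <- 40; lam <- 2
  stats_ <- vapply(1:300, function(r) {
    tr <- simulate_yule_tree(n, lam, seed = 3000 + r)
    c(sum(tr$edge.length), max(ape::node.depth.edgelength(tr)))
  }, numeric(2))
  expect_equal(mean(stats_[1, ]), (n - 1) / lam, tolerance = 0.06)
  expect_equal(mean(stats_[2, ]), sum(1 / ((2:n) * lam)), tolerance = 0.08)
})

test_that("region evolution follows the ER transition law", {
  expect_error(simulate_mk_states(simulate_yule_tree(5, 1, seed = 1), -1,
                                  c("A", "B")), "q_true")
  # q = 0: every tip inherits the root state
  tr <- simulate_yule_tree(30, 1, seed = 11)
  s0 <- simulate_mk_states(tr, 0, c("A", "B", "C"), seed = 12)
  expect_equal(length(unique(s0$regions$region)), 1)
  # on single branches, P(child == parent) matches the closed form
  cherry <- ape::read.tree(text = "(A:0.8,B:0.8);")
  k <- 3; q <- 0.4
  same <- vapply(1:1500, function(r) {
    sim <- simulate_mk_states(cherry, q, LETTERS[1:k], seed = 4000 + r)
    st <- sim$node_states
    c(st[1] == st[3], st[2] == st[3])
  }, logical(2))
  expect_equal(mean(same), melinvade:::er_pmatrix(q, 0.8, k)[1, 1],
               tolerance = 0.03)
})

test_that("planted invasions relabel one clade and record the truth", {
  tr <- simulate_yule_tree(100, 8, seed = 21)
  sim <- simulate_mk_states(tr, 0.1, c("Africa", "Asia", "America"),
                            seed = 22, root_state = "Asia",
                            planted_invasion = list(
                              clade_size = 5, focal_region = "Africa",
                              source_region = "Asia"))
  expect_equal(sum(sim$truth$planted), 5)
  planted_tips <- sim$truth$tip_label[sim$truth$planted]
  expect_true(all(sim$regions$region[sim$regions$tip_label %in%
                                       planted_tips] == "Africa"))
  node <- attr(sim$truth, "planted_node")
  expect_false(is.na(node))
  # the stem of the planted clade retains the source state
  expect_equal(sim$node_states[node], "Asia")
  # the planted tips form exactly the clade below that node
  below <- tr$tip.label[melinvade:::tip_descendants(tr, node)]
  expect_setequal(below, planted_tips)
})

test_that("clonal morph matrices respect the scoring schema", {
  m0 <- simulate_character_matrix(4, 5, plasticity = 0, seed = 31)
  expect_s3_class(m0, "character_matrix")  # construction passed validation
  num <- collapse_multistate(m0)
  # zero plasticity: specimens of a morph are identical
  d <- suppressWarnings(mixed_distance(num))
  dm <- as.matrix(d)
  for (morph in unique(m0$population_code)) {
    ids <- m0$specimen_id[m0$population_code == morph]
    expect_true(all(dm[ids, ids] == 0))
  }
  expect_error(simulate_character_matrix(2, 2, plasticity = 1.5),
               "plasticity")
})

test_that("within-morph disparity increases with plasticity", {
  mean_within <- function(pi_, seed) {
    m <- simulate_character_matrix(5, 6, plasticity = pi_, seed = seed)
    dm <- as.matrix(suppressWarnings(mixed_distance(collapse_multistate(m))))
    vals <- unlist(lapply(unique(m$population_code), function(morph) {
      ids <- m$specimen_id[m$population_code == morph]
      dm[ids, ids][upper.tri(diag(length(ids)))]
    }))
    mean(vals)
  }
  for (seed in 1:8) {
    w0 <- mean_within(0, 500 + seed)
    w2 <- mean_within(0.2, 500 + seed)
    w5 <- mean_within(0.5, 500 + seed)
    expect_lt(w0, w2)
    expect_lt(w2, w5)
  }
})

test_that("population grids have masked borders, hotspots and heavy tails", {
  g <- simulate_population_grid(60, 60, n_hotspots = 5, border = 2,
                                seed = 61)
  expect_false(any(g$mask[1:2, ]))
  expect_false(any(g$mask[, 59:60]))
  expect_true(all(g$values[g$mask] >= 0))
  # heavy right tail: a few percent of cells above 100 people/km2
  frac_high <- density_split(g, 100)$n_high / sum(g$mask)
  expect_gt(frac_high, 0.02)
  expect_lt(frac_high, 0.3)
  # ESRI round-trip of a simulated grid
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, tmp)
  g2 <- read_ascii_grid(tmp)
  expect_equal(g2$values, g$values, ignore_attr = TRUE)
})

test_that("placement bias behaves as its exponent dictates", {
  g <- simulate_population_grid(12, 12, n_hotspots = 2, seed = 71)
  # beta = 0: uniform over masked cells (chi-squared goodness of fit)
  idx <- which(g$mask)
  hits <- table(factor(unlist(lapply(1:2000, function(r) {
    s <- place_invasions(g, 3, beta = 0, seed = 8000 + r)
    (s$col - 1) * nrow(g$values) + s$row
  })), levels = idx))
  chi <- suppressWarnings(stats::chisq.test(as.vector(hits)))
  expect_gt(chi$p.value, 0.01)
  # beta large: all k sites in the k most populous cells
  counts <- g$values[idx]
  top3 <- idx[order(counts, decreasing = TRUE)[1:3]]
  s <- place_invasions(g, 3, beta = 50, seed = 81)
  expect_setequal((s$col - 1) * nrow(g$values) + s$row, top3)
  expect_error(place_invasions(g, 1e6, beta = 0), "more sites")
})
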