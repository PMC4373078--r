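fit_at <- function(tree, regions, q, states) {
  # fixed-rate fit object, for tests that pin q
  structure(list(q = q, log_likelihood = NA_real_, k = length(states),
                 states = states, root_prior = rep(1 / length(states),
                                                   length(states)),
                 tree = tree,
                 assignment = regions[tree$tip.label]),
            class = "mk_fit")
}

test_that("marginal posteriors match enumeration on random small trees", {
  for (seed in 1:25) {
    case <- random_mk_case(seed + 40)
    states <- LETTERS[seq_len(case$k)]
    reg <- setNames(states[case$tip_state], case$tree$tip.label)
    fit <- fit_at(case$tree, reg, case$q, states)
    anc <- marginal_ancestral_states(fit)
    ref <- enum_mk_marginals(case$tree, case$tip_state, case$q, case$k)
    expect_equal(unclass(anc), ref, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(rowSums(anc), rep(1, nrow(anc)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("a symmetric cherry with opposite states is maximally uncertain", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  fit <- fit_at(cherry, c(A = "x", B = "y"), q = 0.3, c("x", "y"))
  anc <- marginal_ancestral_states(fit)
  expect_equal(as.vector(anc), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("marginals are invariant under tip reordering and relabeling", {
  case <- random_mk_case(77)
  states <- LETTERS[seq_len(case$k)]
  reg <- setNames(states[case$tip_state], case$tree$tip.label)
  fit <- fit_at(case$tree, reg, case$q, states)
  anc <- marginal_ancestral_states(fit)
  # rotating the tree permutes nothing in the node marginals
  rot <- ape::rotateConstr(case$tree, rev(case$tree$tip.label))
  fit2 <- fit_at(rot, reg, case$q, states)
  anc2 <- marginal_ancestral_states(fit2)
  m1 <- unclass(anc)[order(as.integer(rownames(anc))), ]
  m2 <- unclass(anc2)[order(as.integer(rownames(anc2))), ]
  expect_equal(m1, m2, tolerance = 1e-9)
  # relabeling states permutes the output columns identically
  perm <- rev(states)
  reg2 <- setNames(perm[case$tip_state], case$tree$tip.label)
  anc3 <- marginal_ancestral_states(fit_at(case$tree, reg2, case$q, states))
  expect_equal(unclass(anc)[, states], unclass(anc3)[, perm],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("marginals approach uniform as the rate grows", {
  # branch lengths bounded away from zero so q t -> infinity on every edge
  tree <- simulate_yule_tree(30, 1, seed = 91)
  tree$edge.length <- withr::with_seed(93, runif(length(tree$edge.length),
                                                 0.5, 1.5))
  sim <- simulate_mk_states(tree, 0.3, c("A", "B", "C"), seed = 92)
  h <- max(ape::node.depth.edgelength(tree))
  fit <- fit_at(tree, setNames(sim$regions$region, sim$regions$tip_label),
                1e3 / h, c("A", "B", "C"))
  anc <- marginal_ancestral_states(fit)
  expect_equal(as.vector(unclass(anc)),
               rep(1 / 3, length(anc)), tolerance = 1e-3)
})

test_that("tidy() returns one probability row per node-state pair", {
  case <- random_mk_case(55)
  states <- LETTERS[seq_len(case$k)]
  reg <- setNames(states[case$tip_state], case$tree$tip.label)
  anc <- marginal_ancestral_states(fit_at(case$tree, reg, case$q, states))
  td <- tidy(anc)
  expect_equal(nrow(td), nrow(anc) * ncol(anc))
  sums <- tapply(td$probability, td$node, sum)
  expect_equal(as.vector(sums), rep(1, nrow(anc)), tolerance = 1e-9)
})

test_that("invasion calls flag contradicted lineages and only those", {
  # an African tip hanging shallowly inside an Asian clade is flagged;
  # Asian tips never are; a deeply diverged African clade is not
  txt <- "(((inv:0.05,as1:0.05):0.05,(as2:0.1,as3:0.1):0.5):1.0,(af1:0.4,af2:0.4):2.0);"
  tree <- ape::read.tree(text = txt)
  reg <- c(inv = "Africa", as1 = "Asia", as2 = "Asia", as3 = "Asia",
           af1 = "Africa", af2 = "Africa")
  fit <- fit_at(tree, reg, q = 0.15, c("Africa", "Asia"))
  anc <- marginal_ancestral_states(fit)
  calls <- call_invasions(fit, anc, "Africa", threshold = 0.9)
  expect_setequal(calls$tip_label, c("inv", "af1", "af2"))
  expect_true(calls$flagged[calls$tip_label == "inv"])
  expect_equal(calls$source_region[calls$tip_label == "inv"], "Asia")
  expect_false(any(calls$flagged[calls$tip_label %in% c("af1", "af2")]))
  # the two old-clade tips share one (unflagged) clade assessment
  expect_equal(length(unique(calls$clade_node[calls$tip_label %in%
                                                c("af1", "af2")])), 1)
})

test_that("invasion calls validate their inputs", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  fit <- fit_at(cherry, c(A = "x", B = "y"), 0.3, c("x", "y"))
  anc <- marginal_ancestral_states(fit)
  expect_error(call_invasions(fit, anc, "z", 0.9), "not in the state set")
  expect_error(call_invasions(fit, anc, "x", 0.4), "threshold")
  expect_error(call_invasions(fit, anc, "x", 1.2), "threshold")
})
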