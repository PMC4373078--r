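test_that("newick round-trips preserve topology, labels and branch lengths", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tmp)
  tree <- read_newick(tmp)
  expect_equal(length(tree$tip.label), 3)
  expect_equal(tree$Nnode, 2)
  tmp2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tmp2)
  tree2 <- read_newick(tmp2)
  expect_true(ape::all.equal.phylo(tree2, tree, use.edge.length = TRUE))
  expect_equal(sort(tree2$edge.length), sort(tree$edge.length))
  expect_setequal(tree2$tip.label, tree$tip.label)
})

test_that("malformed or incomplete trees are rejected", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C);", tmp)   # missing a branch length
  expect_error(read_newick(tmp), "branch length")
  writeLines("((A:1,B:1,C:1):1,D:1);", tmp)  # polytomies are fine
  expect_s3_class(read_newick(tmp), "phylo")
  unrooted <- ape::unroot(ape::rtree(5))
  tmp3 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(unrooted, tmp3)
  expect_error(read_newick(tmp3), "rooted")
})

test_that("boundary likelihoods have their closed-form values", {
  # two identical tips at rate zero: only the root prior mass remains
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  ll <- mk_loglik(cherry, c(A = "x", B = "x"), q = 0,
                  states = c("x", "y"))
  expect_equal(ll, -log(2), tolerance = 1e-12)
  # two different tips at rate zero: impossible data
  expect_equal(mk_loglik(cherry, c(A = "x", B = "y"), q = 0), -Inf)
})

test_that("likelihood is invariant under state relabeling", {
  case <- random_mk_case(21)
  states <- LETTERS[seq_len(case$k)]
  reg <- setNames(states[case$tip_state], case$tree$tip.label)
  perm <- rev(states)
  reg2 <- setNames(perm[case$tip_state], case$tree$tip.label)
  expect_equal(mk_loglik(case$tree, reg, case$q, states = states),
               mk_loglik(case$tree, reg2, case$q, states = states),
               tolerance = 1e-12)
})

test_that("pruning likelihood equals enumeration on random small trees", {
  for (seed in 1:25) {
    case <- random_mk_case(seed)
    states <- LETTERS[seq_len(case$k)]
    reg <- setNames(states[case$tip_state], case$tree$tip.label)
    ll <- mk_loglik(case$tree, reg, case$q, states = states)
    expect_equal(ll, log(enum_mk_lik(case$tree, case$tip_state, case$q,
                                     case$k)),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is continuous in the rate", {
  case <- random_mk_case(31)
  states <- LETTERS[seq_len(case$k)]
  reg <- setNames(states[case$tip_state], case$tree$tip.label)
  eps <- 1e-6
  expect_lt(abs(mk_loglik(case$tree, reg, case$q + eps, states = states) -
                  mk_loglik(case$tree, reg, case$q, states = states)),
            1e-4)
})

test_that("rate fitting finds a local optimum and handles boundaries", {
  tree <- simulate_yule_tree(80, 2, seed = 51)
  sim <- simulate_mk_states(tree, 0.5, c("A", "B", "C"), seed = 52)
  fit <- fit_mk(tree, sim$regions)
  ll <- function(q) mk_loglik(tree, sim$regions, q,
                              states = fit$states)
  expect_gte(fit$log_likelihood, ll(fit$q / 2) - 1e-9)
  expect_gte(fit$log_likelihood, ll(fit$q * 2) - 1e-9)
  expect_equal(fit$log_likelihood, ll(fit$q), tolerance = 1e-10)
  # monomorphic data: boundary fit with a warning, reconstruction defined
  mono <- setNames(rep("A", 80), tree$tip.label)
  expect_warning(bfit <- fit_mk(tree, mono, states = c("A", "B")),
                 "monomorphic")
  expect_equal(bfit$q, 1e-8 / max(ape::node.depth.edgelength(tree)))
  anc <- marginal_ancestral_states(bfit)
  expect_gt(min(anc[, "A"]), 0.999)
})

test_that("rate recovery: median estimate near truth across replicates", {
  # scaled-down version of the parameter-recovery experiment
  qs <- vapply(1:12, function(r) {
    tree <- simulate_yule_tree(150, 1, seed = 600 + r)
    sim <- simulate_mk_states(tree, 0.5, c("A", "B", "C"), seed = 700 + r)
    suppressWarnings(fit_mk(tree, sim$regions)$q)
  }, numeric(1))
  expect_gt(median(qs), 0.35)
  expect_lt(median(qs), 0.65)
})

test_that("errors: uncoded tips and negative rates", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(mk_loglik(tree, c(A = "x", B = "x"), q = 1), "uncoded tip")
  expect_error(mk_loglik(tree, c(A = "x", B = "x", C = "y"), q = -1),
               "non-negative")
})
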