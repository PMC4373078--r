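#' @title Equal-rates Mk likelihood of geographic regions on a tree
#'
#' @description
#' Computes the log-likelihood of tip region data under the k-state
#' equal-rates Mk model: a continuous-time Markov chain whose rate matrix
#' has every off-diagonal entry equal to `q` (diagonal `-(k-1)q`). The
#' transition probabilities have the closed form
#' \deqn{P_{ss}(t) = 1/k + (1 - 1/k)\,e^{-kqt}, \qquad
#'       P_{sr}(t) = 1/k - (1/k)\,e^{-kqt} \ (s \ne r),}
#' and the tree likelihood is evaluated with Felsenstein's pruning
#' algorithm (postorder conditional likelihoods with per-node rescaling),
#' weighting root states by `root_prior`. Polytomies and zero-length
#' branches (identity transition) are handled natively.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param regions Tip coding: a data frame with columns `tip_label` and
#'   `region`, or a named character vector `tip_label -> region`.
#' @param q The single off-diagonal transition rate (>= 0).
#' @param states Optional ordered state set; defaults to the sorted unique
#'   regions. Must cover every coded region.
#' @param root_prior Probability vector over `states` at the root
#'   (default uniform, which equals the ER stationary distribution).
#' @return The log-likelihood (a scalar <= 0 for discrete data).
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' reg <- c(A = "Africa", B = "Africa", C = "Asia", D = "Asia")
#' mk_loglik(tree, reg, q = 0.2)
#' @export
mk_loglik <- function(tree, regions, q, states = NULL, root_prior = NULL) {
  cd <- region_coding(tree, regions, states)
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0) {
    abort("q must be a single non-negative rate")
  }
  pr <- check_root_prior(root_prior, length(cd$states))
  pruning_pass(tree, cd, q, pr)$loglik
}

# Normalize region input, check completeness, build tip state indices.
region_coding <- function(tree, regions, states = NULL) {
  if (is.data.frame(regions)) {
    assignment <- setNames(as.character(regions$region), regions$tip_label)
  } else {
    assignment <- regions
  }
  missing_tips <- setdiff(tree$tip.label, names(assignment))
  if (length(missing_tips) > 0) {
    abort(paste0("uncoded tip(s): ", paste(missing_tips, collapse = ", ")))
  }
  assignment <- assignment[tree$tip.label]
  if (is.null(states)) states <- sort(unique(unname(assignment)))
  if (!all(assignment %in% states)) {
    abort("tip regions outside the declared state set")
  }
  list(states = states, assignment = assignment,
       tip_state = match(assignment, states))
}

check_root_prior <- function(root_prior, k) {
  if (is.null(root_prior)) return(rep(1 / k, k))
  if (length(root_prior) != k || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8) {
    abort("root_prior must be a probability vector over the states")
  }
  root_prior
}

# ER transition probability matrix for branch length t.
er_pmatrix <- function(q, t, k) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

# Postorder pruning pass. Returns per-node conditional likelihoods (scaled),
# per-node log scale factors, and the total log-likelihood.
pruning_pass <- function(tree, cd, q, root_prior) {
  k <- length(cd$states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- matrix(1, ntip + nnode, k)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), cd$tip_state)] <- 1
  logscale <- numeric(ntip + nnode)

  tr <- ape::reorder.phylo(tree, "postorder")
  for (ei in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[ei, 1]
    child <- tr$edge[ei, 2]
    P <- er_pmatrix(q, tr$edge.length[ei], k)
    L[parent, ] <- L[parent, ] * as.vector(P %*% L[child, ])
    logscale[parent] <- logscale[parent] + logscale[child]
    mx <- max(L[parent, ])
    if (mx > 0 && (mx < 1e-100 || mx > 1e100)) {
      L[parent, ] <- L[parent, ] / mx
      logscale[parent] <- logscale[parent] + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- sum(root_prior * L[root, ])
  list(L = L, logscale = logscale,
       loglik = if (lik <= 0) -Inf else log(lik) + logscale[root])
}

#' Fit the equal-rates Mk model by maximum likelihood
#'
#' Estimates the single transition rate `q` by bounded scalar optimization
#' of [mk_loglik()] on the log-rate scale, with bounds
#' \eqn{[10^{-8}, 10^{3}]} divided by the tree height so the search covers
#' effectively-static through effectively-randomized regimes on any time
#' scale. Monomorphic tip data carry no evidence of change and return a
#' boundary fit at the lower bound with a warning.
#'
#' @inheritParams mk_loglik
#' @return An object of class `mk_fit`: list with `q`, `log_likelihood`,
#'   `k`, `states`, `root_prior`, `tree` and the tip `assignment`.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fit <- fit_mk(tree, c(A = "Africa", B = "Africa", C = "Asia", D = "Asia"))
#' glance(fit)
#' @export
fit_mk <- function(tree, regions, states = NULL, root_prior = NULL) {
  validate_tree(tree)
  cd <- region_coding(tree, regions, states)
  k <- length(cd$states)
  pr <- check_root_prior(root_prior, k)
  h <- tree_height(tree)
  lower <- 1e-8 / h
  upper <- 1e3 / h
  if (length(unique(cd$assignment)) == 1 || k == 1) {
    warn("monomorphic tip data: no evidence of change, returning boundary fit")
    q_hat <- lower
    ll <- pruning_pass(tree, cd, q_hat, pr)$loglik
  } else {
    negll <- function(lq) -pruning_pass(tree, cd, exp(lq), pr)$loglik
    opt <- optimize(negll, interval = c(log(lower), log(upper)), tol = 1e-8)
    q_hat <- exp(opt$minimum)
    ll <- -opt$objective
  }
  structure(list(q = q_hat, log_likelihood = ll, k = k, states = cd$states,
                 root_prior = pr, tree = tree, assignment = cd$assignment),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf(paste0("Equal-rates Mk fit: %d states (%s)\n",
                     "q = %.6g, log-likelihood = %.4f\n"),
              x$k, paste(x$states, collapse = ", "),
              x$q, x$log_likelihood))
  invisible(x)
}

#' @describeIn fit_mk Parameter estimate as a one-row tibble.
#' @param x,object An `mk_fit`.
#' @param ... Unused.
#' @method tidy mk_fit
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = "q", estimate = x$q)
}

#' @describeIn fit_mk One-row model summary.
#' @method glance mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(q = x$q, log_likelihood = x$log_likelihood, k = x$k,
                 n_tips = length(x$tree$tip.label))
}
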