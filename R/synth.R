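#' Simulate a Yule (pure-birth) tree
#'
#' Forward-simulates a constant-rate pure-birth tree, the speciation
#' process assumed for the empirical phylogeny; branch lengths are in units
#' of `1 / birth_rate`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (default 1).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with tip labels `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) abort("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Simulate region evolution on a tree, optionally planting an invasion
#'
#' Evolves a discrete region character along the tree under the equal-rates
#' Mk model: the root state is drawn uniformly, and state changes occur
#' along each branch as a Poisson process with total rate
#' `(k - 1) * q_true`, each change picking one of the other states
#' uniformly. Optionally plants a "camouflaged invasion": one clade of the
#' requested size is relabeled to the focal region at the tips while its
#' stem and internal nodes keep the source state — emulating a recently
#' introduced lineage whose occurrence (focal region) contradicts its
#' ancestry (source region).
#'
#' @param tree An [ape::phylo] tree.
#' @param q_true True transition rate (>= 0).
#' @param states Character vector of region labels (>= 2).
#' @param seed Integer seed.
#' @param planted_invasion Optional list with `clade_size` (number of tips),
#'   `focal_region` and `source_region`. A clade of exactly `clade_size`
#'   tips whose simulated state is `source_region` is sought; its tips are
#'   relabeled to `focal_region`.
#' @param root_state Optional fixed root state; by default the root is
#'   drawn uniformly. The camouflaged-invader experiments fix the root at
#'   the source region, emulating an introduction into a phylogeny
#'   dominated by source-region lineages.
#' @return A list with `regions` (tibble `tip_label`, `region`),
#'   `node_states` (true states, all nodes in `ape` numbering) and `truth`
#'   (tibble `tip_label`, `planted` flag; `planted_node` attribute gives
#'   the clade's root node, `NA` when no clade of the requested size and
#'   source state exists).
#' @export
simulate_mk_states <- function(tree, q_true, states, seed = NULL,
                               planted_invasion = NULL, root_state = NULL) {
  if (q_true < 0) abort("q_true must be >= 0")
  k <- length(states)
  if (k < 2) abort("need at least 2 states")
  if (!is.null(root_state) && !root_state %in% states) {
    abort("root_state must be in the state set")
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  with_seed(seed, {
    node_state <- integer(ntip + nnode)
    root <- ntip + 1L
    node_state[root] <- if (is.null(root_state)) {
      sample.int(k, 1)
    } else {
      match(root_state, states)
    }
    tr <- ape::reorder.phylo(tree, "postorder")
    ord <- rev(seq_len(nrow(tr$edge)))  # preorder
    for (ei in ord) {
      parent <- tr$edge[ei, 1]
      child <- tr$edge[ei, 2]
      s <- node_state[parent]
      n_changes <- stats::rpois(1, (k - 1) * q_true * tr$edge.length[ei])
      for (ch in seq_len(n_changes)) {
        s <- sample(setdiff(seq_len(k), s), 1)
      }
      node_state[child] <- s
    }

    planted_node <- NA_integer_
    planted <- rep(FALSE, ntip)
    if (!is.null(planted_invasion)) {
      pi_ <- planted_invasion
      focal_i <- match(pi_$focal_region, states)
      source_i <- match(pi_$source_region, states)
      if (is.na(focal_i) || is.na(source_i)) {
        abort("planted_invasion regions must be in the state set")
      }
      # candidate clades: internal nodes with exactly clade_size descendant
      # tips, all (incl. the node) in the source state; if none exists for
      # the requested source, fall back to any shared non-focal state
      find_cand <- function(src) {
        cand <- integer(0)
        for (v in root:(ntip + nnode)) {
          tips <- tip_descendants(tree, v)
          if (length(tips) == pi_$clade_size &&
              node_state[v] == src &&
              all(node_state[tips] == src)) {
            cand <- c(cand, v)
          }
        }
        cand
      }
      cand <- find_cand(source_i)
      if (length(cand) == 0) {
        for (src in setdiff(seq_len(k), c(focal_i, source_i))) {
          cand <- find_cand(src)
          if (length(cand) > 0) break
        }
      }
      if (length(cand) > 0) {
        planted_node <- cand[sample.int(length(cand), 1)]
        tips <- tip_descendants(tree, planted_node)
        node_state[tips] <- focal_i
        planted[tips] <- TRUE
      }
    }

    regions <- tibble::tibble(tip_label = tree$tip.label,
                              region = states[node_state[seq_len(ntip)]])
    truth <- tibble::tibble(tip_label = tree$tip.label, planted = planted)
    attr(truth, "planted_node") <- planted_node
    list(regions = regions, node_states = states[node_state], truth = truth)
  })
}

tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(v)]]
    if (is.null(kids)) out <- c(out, v) else stack <- c(stack, kids)
  }
  out
}

#' Simulate a clonal morph character matrix
#'
#' Emulates shell scoring of predominantly parthenogenetic snail
#' populations: each morph (clonal lineage) gets a centroid scored
#' uniformly over the valid states of each character (respecting the
#' inapplicability rules), and each specimen perturbs each applicable
#' character away from the centroid with probability `plasticity`, moving
#' to an adjacent valid state (an ordinal random walk step, reflecting the
#' graded variation of real shell traits). A perturbed score is recorded
#' as a borderline two-state cell with probability `border_prob`,
#' mimicking disagreement between independent scorers. `plasticity = 0`
#' reproduces tight clonal morphs; large values mimic ecophenotypically
#' plastic populations.
#'
#' @param n_morphs Number of morphs.
#' @param specimens_per_morph Specimens scored per morph.
#' @param plasticity Per-character perturbation probability in \[0, 1\].
#' @param seed Integer seed.
#' @param border_prob Probability that a perturbed score is recorded as a
#'   two-state borderline cell (default 0.2).
#' @param definitions Character definitions (default
#'   [canonical_character_set()]).
#' @return A validated `character_matrix` tibble; morphs are labeled
#'   `M01, M02, ...` and alternate `native`/`invasive` groups.
#' @export
simulate_character_matrix <- function(n_morphs, specimens_per_morph,
                                      plasticity, seed = NULL,
                                      border_prob = 0.2,
                                      definitions = canonical_character_set()) {
  if (plasticity < 0 || plasticity > 1) abort("plasticity must be in [0, 1]")
  if (n_morphs < 1 || specimens_per_morph < 1) abort("counts must be positive")
  codes <- definitions$code
  with_seed(seed, {
    rows <- list()
    for (m in seq_len(n_morphs)) {
      morph <- sprintf("M%02d", m)
      centroid <- draw_centroid(definitions)
      for (s in seq_len(specimens_per_morph)) {
        cells <- centroid
        for (code in codes) {
          if (is.na(cells[[code]])) next
          if (runif(1) < plasticity) {
            def <- definitions[definitions$code == code, ]
            cur <- as.integer(cells[[code]])
            nb <- intersect(cur + c(-1L, 1L), def$states[[1]])
            if (length(nb) == 0) next
            new <- nb[sample.int(length(nb), 1)]
            cells[[code]] <- if (runif(1) < border_prob) {
              paste(sort(c(cur, new)), collapse = ",")
            } else {
              as.character(new)
            }
          }
        }
        cells <- enforce_na_rules(cells, definitions, redraw = TRUE)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          specimen_id = sprintf("%s-%02d", morph, s),
          population_code = morph,
          group = if (m %% 2 == 0) "invasive" else "native",
          unbleached = FALSE, !!!cells)
      }
    }
    as_character_matrix(dplyr::bind_rows(rows), definitions = definitions)
  })
}

# draw a single-state centroid per character, honouring na rules
draw_centroid <- function(definitions) {
  cells <- setNames(vector("list", nrow(definitions)), definitions$code)
  for (i in seq_len(nrow(definitions))) {
    st <- definitions$states[[i]]
    cells[[definitions$code[i]]] <- as.character(st[sample.int(length(st), 1)])
  }
  enforce_na_rules(cells, definitions, redraw = TRUE)
}

# make dependent characters consistent with their controllers: inapplicable
# cells become NA; cells that became applicable but are NA get redrawn
enforce_na_rules <- function(cells, definitions, redraw = FALSE) {
  for (i in seq_len(nrow(definitions))) {
    ctrl <- definitions$na_code[i]
    if (is.na(ctrl)) next
    code <- definitions$code[i]
    ctrl_states <- as.integer(strsplit(cells[[ctrl]], ",")[[1]])
    inapplicable <- all(ctrl_states %in% definitions$na_states[[i]])
    if (inapplicable) {
      cells[[code]] <- NA_character_
    } else if (is.na(cells[[code]]) && redraw) {
      st <- definitions$states[[i]]
      cells[[code]] <- as.character(st[sample.int(length(st), 1)])
    }
  }
  cells
}

#' Simulate a population grid with urban hotspots
#'
#' Generates a heavy-tailed population raster emulating a gridded census
#' product: lognormal background counts plus Gaussian-kernel population
#' surges around randomly placed hotspot centres, with a border band
#' masked out as a stand-in for a study-region polygon.
#'
#' @param nrows,ncols Grid dimensions.
#' @param n_hotspots Number of urban hotspots (default 5).
#' @param hotspot_intensity Peak population added at a hotspot centre
#'   (default 5e4).
#' @param hotspot_sd Kernel standard deviation in cells (default 2).
#' @param meanlog,sdlog Lognormal background parameters (defaults 4.8 and
#'   2, putting roughly 8% of cells above 100 people per km^2 at the
#'   default 21 km^2 cell area).
#' @param border Width of the masked-out border band in cells (default 1).
#' @param cell_area Cell area in km^2 (default 21).
#' @param seed Integer seed.
#' @return A [population_grid].
#' @export
simulate_population_grid <- function(nrows, ncols, n_hotspots = 5,
                                     hotspot_intensity = 5e4, hotspot_sd = 2,
                                     meanlog = 4.8, sdlog = 2, border = 1,
                                     cell_area = 21, seed = NULL) {
  with_seed(seed, {
    vals <- matrix(rlnorm(nrows * ncols, meanlog, sdlog), nrows, ncols)
    if (n_hotspots > 0) {
      centers <- cbind(runif(n_hotspots, 1, nrows), runif(n_hotspots, 1, ncols))
      rr <- row(vals); cc <- col(vals)
      for (h in seq_len(n_hotspots)) {
        d2 <- (rr - centers[h, 1])^2 + (cc - centers[h, 2])^2
        vals <- vals + hotspot_intensity * exp(-d2 / (2 * hotspot_sd^2))
      }
    }
    vals <- round(vals, 2)
    mask <- matrix(TRUE, nrows, ncols)
    if (border > 0) {
      mask[c(seq_len(border), nrows - seq_len(border) + 1), ] <- FALSE
      mask[, c(seq_len(border), ncols - seq_len(border) + 1)] <- FALSE
    }
    vals[!mask] <- NA_real_
    population_grid(vals, mask, cell_area = cell_area)
  })
}

#' Place invasion sites on a grid with density bias
#'
#' Samples `k` distinct masked cells with probability proportional to
#' `(count + 1)^beta`: `beta = 0` gives uniform placement, larger values
#' concentrate invasions in populous cells (the +1 keeps empty cells
#' reachable at any finite bias).
#'
#' @param g A [population_grid].
#' @param k Number of sites.
#' @param beta Bias exponent (>= 0).
#' @param seed Integer seed.
#' @return A sites tibble (`locality`, `row`, `col`).
#' @export
place_invasions <- function(g, k, beta = 0, seed = NULL) {
  stopifnot(inherits(g, "population_grid"))
  if (beta < 0) abort("beta must be >= 0")
  idx <- which(g$mask)
  if (k > length(idx)) abort("more sites than masked cells")
  w <- (g$values[idx] + 1)^beta
  chosen <- with_seed(seed, sample(idx, k, prob = w))
  tibble::tibble(locality = sprintf("site%02d", seq_len(k)),
                 row = ((chosen - 1) %% nrow(g$values)) + 1,
                 col = ((chosen - 1) %/% nrow(g$values)) + 1)
}
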