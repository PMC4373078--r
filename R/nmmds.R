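#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Embeds a dissimilarity matrix in `dims` dimensions so that the rank order
#' of configuration distances matches the rank order of the input
#' dissimilarities as closely as possible. Misfit is measured by Kruskal's
#' stress-1,
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j} (d_{ij} - \hat d_{ij})^2 /
#'   \sum_{i<j} d_{ij}^2},}
#' where \eqn{d_{ij}} are configuration distances and \eqn{\hat d_{ij}} the
#' disparities obtained by least-squares monotone regression
#' (pool-adjacent-violators) of the configuration distances on the
#' dissimilarity order. Ties in the dissimilarities are treated with
#' Kruskal's primary approach: tied dissimilarities impose no order
#' constraint among themselves.
#'
#' The configuration is optimized by iterative majorization (the Guttman
#' transform), alternating monotone regression with a configuration update;
#' an iteration that fails to decrease stress terminates the start at the
#' previous configuration, so the stress trace is non-increasing. One start
#' is initialized from classical metric scaling (principal coordinates) and
#' the remaining `n_starts - 1` from seeded random configurations; the
#' lowest-stress solution is returned, centered, rotated to its principal
#' axes, with each axis' sign fixed so its largest-magnitude coordinate is
#' positive, and scaled so the root-mean-square configuration distance
#' equals the root-mean-square input dissimilarity (stress-1 itself is
#' scale-free).
#'
#' @param d A [stats::dist] or square symmetric matrix of dissimilarities.
#' @param dims Number of embedding dimensions (default 3).
#' @param n_starts Total number of starts (default 20: 1 metric + 19 random).
#' @param seed Integer seed controlling the random starts.
#' @param max_iter Maximum majorization iterations per start (default 500).
#' @param tol Convergence tolerance on the relative stress decrease
#'   (default 1e-7).
#' @return An object of class `nmmds`: a list with `points` (n x dims
#'   matrix), `stress` (stress-1 in \[0, 1\]), `stress_pct` (stress x 100),
#'   `dims`, `n_starts`, `seed`, `best_start`, `converged`, per-start final
#'   stresses `start_stress`, and the best start's `stress_trace`.
#' @examples
#' d <- melanoides_shell_scores() |> collapse_multistate() |> mixed_distance()
#' ord <- nmmds(d, dims = 3, n_starts = 5, seed = 1)
#' glance(ord)
#' @export
nmmds <- function(d, dims = 3, n_starts = 20, seed = NULL,
                  max_iter = 500, tol = 1e-7) {
  d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (dims >= n - 1) abort("dims must be smaller than n_specimens - 1")
  dv <- as.vector(d)
  if (anyNA(dv)) abort("dissimilarities contain NA")
  if (all(dv == 0)) abort("degenerate input: all dissimilarities are zero")

  # starting configurations: principal coordinates, then seeded random
  starts <- vector("list", n_starts)
  pcoa <- suppressWarnings(cmdscale(d, k = dims))
  if (ncol(pcoa) < dims) {
    pcoa <- cbind(pcoa, matrix(0, n, dims - ncol(pcoa)))
  }
  starts[[1]] <- pcoa
  if (n_starts > 1) {
    child <- derive_seeds(if (is.null(seed)) 0L else seed, n_starts - 1)
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- with_seed(child[s], matrix(rnorm(n * dims), n, dims))
    }
  }

  runs <- lapply(starts, nmmds_one_start, dv = dv, n = n,
                 max_iter = max_iter, tol = tol)
  stresses <- vapply(runs, function(r) r$stress, numeric(1))
  best <- which.min(stresses)
  res <- runs[[best]]
  if (!any(vapply(runs, function(r) r$converged, logical(1)))) {
    warn("no start converged within max_iter; returning best configuration")
  }

  # output convention: centered, principal axes, positive dominant sign;
  # stress-1 is scale-free, so fix the scale by matching the RMS
  # configuration distance to the RMS input dissimilarity
  X <- scale(res$X, center = TRUE, scale = FALSE)
  Dv <- as.vector(dist(X))
  X <- X * sqrt(sum(dv^2) / sum(Dv^2))
  X <- X %*% svd(X)$v
  for (a in seq_len(ncol(X))) {
    if (X[which.max(abs(X[, a])), a] < 0) X[, a] <- -X[, a]
  }
  dimnames(X) <- list(labels, paste0("axis", seq_len(dims)))

  structure(list(points = X, stress = res$stress,
                 stress_pct = 100 * res$stress, dims = dims,
                 n_starts = n_starts, seed = seed, best_start = best,
                 converged = res$converged, start_stress = stresses,
                 stress_trace = res$trace, diss = d),
            class = "nmmds")
}

# One majorization run from configuration X0; dv = dissimilarity vector.
nmmds_one_start <- function(X0, dv, n, max_iter, tol) {
  X <- X0
  Dv <- as.vector(dist(X))
  st <- kruskal_stress1(dv, Dv)
  trace <- st$stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Xn <- guttman_update(X, st$dhat, Dv, n)
    Dn <- as.vector(dist(Xn))
    stn <- kruskal_stress1(dv, Dn)
    if (!is.finite(stn$stress) || stn$stress > st$stress) {
      # stress can no longer decrease under this majorization: a plateau
      converged <- TRUE
      break
    }
    dec <- st$stress - stn$stress
    X <- Xn; Dv <- Dn; st <- stn
    trace <- c(trace, st$stress)
    if (dec < tol * max(st$stress, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  list(X = X, stress = st$stress, trace = trace, converged = converged)
}

# Kruskal stress-1 of configuration distances Dv against dissimilarities dv,
# with disparities from PAVA under the primary tie treatment (within blocks
# of tied dv, configuration distances are pre-sorted so ties are free).
kruskal_stress1 <- function(dv, Dv) {
  ord <- order(dv, Dv)
  dhat <- numeric(length(Dv))
  dhat[ord] <- isoreg(Dv[ord])$yf
  denom <- sum(Dv^2)
  stress <- if (denom == 0) Inf else sqrt(sum((Dv - dhat)^2) / denom)
  list(stress = stress, dhat = dhat)
}

# Guttman transform: X <- (1/n) B(X) X with B built from dhat/D ratios.
guttman_update <- function(X, dhat, Dv, n) {
  ratio <- ifelse(Dv > 0, dhat / Dv, 0)
  Rm <- matrix(0, n, n)
  Rm[lower.tri(Rm)] <- ratio
  Rm <- Rm + t(Rm)
  B <- -Rm
  diag(B) <- rowSums(Rm)
  (B %*% X) / n
}

#' Recompute Kruskal stress-1 from coordinates
#'
#' @param d The dissimilarities ([stats::dist] or square matrix).
#' @param coords A configuration matrix (rows in the same order as `d`).
#' @return Stress-1 on the \[0, 1\] scale.
#' @export
stress_from_coords <- function(d, coords) {
  dv <- as.vector(stats::as.dist(as.matrix(d)))
  Dv <- as.vector(dist(coords))
  kruskal_stress1(dv, Dv)$stress
}

#' @export
print.nmmds <- function(x, ...) {
  cat(sprintf(paste0("Non-metric MDS: %d points in %d dimensions\n",
                     "stress-1 x 100 = %.3f (best of %d starts%s)\n"),
              nrow(x$points), x$dims, x$stress_pct, x$n_starts,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @describeIn nmmds Per-specimen ordination scores as a tibble.
#' @param x,object An `nmmds` object.
#' @param ... Unused.
#' @method tidy nmmds
#' @export
tidy.nmmds <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(specimen_id = rownames(x$points)),
                   tibble::as_tibble(x$points))
}

#' @describeIn nmmds One-row model summary (stress, convergence, starts).
#' @method glance nmmds
#' @export
glance.nmmds <- function(x, ...) {
  tibble::tibble(n = nrow(x$points), dims = x$dims,
                 stress = x$stress, stress_pct = x$stress_pct,
                 n_starts = x$n_starts, best_start = x$best_start,
                 converged = x$converged)
}

#' @describeIn nmmds Scatterplot of two ordination axes, optionally coloured
#'   by a `groups` table (`specimen_id`, `group`).
#' @param axes Which two axes to plot (default `c(1, 2)`).
#' @param groups Optional tibble with `specimen_id` and `group` columns.
#' @method autoplot nmmds
#' @export
autoplot.nmmds <- function(object, axes = c(1, 2), groups = NULL, ...) {
  df <- tidy(object)
  ax <- paste0("axis", axes)
  if (!is.null(groups)) {
    df <- dplyr::left_join(df, tibble::as_tibble(groups)[c("specimen_id", "group")],
                           by = "specimen_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]]))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("nmMDS (stress-1 x 100 = %.2f)", object$stress_pct))
}
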