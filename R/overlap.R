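#' Quantify morphospace overlap between specimen groups
#'
#' Summarizes how groups of specimens (e.g. native vs. invasive morphs)
#' occupy an ordination space: per-group axis-aligned bounding boxes,
#' convex-hull volumes, per-group morphological disparity (mean distance to
#' the group centroid) and, for every pair of groups, the volume of the
#' intersection of their convex hulls as a fraction of the smaller hull.
#'
#' Hull and intersection volumes are Monte Carlo estimates: points are drawn
#' uniformly in the relevant bounding box and tested for hull membership
#' with [in_hull()] (exact supporting-hyperplane test). Estimates are
#' reproducible via `seed`.
#'
#' @param ord An [nmmds] result, or a numeric coordinate matrix with
#'   specimen rownames.
#' @param groups A tibble/data frame with `specimen_id` and `group` columns,
#'   or a named character vector `specimen_id -> group`.
#' @param n_mc Monte Carlo sample size per volume estimate (default 20000).
#' @param seed Integer seed for the Monte Carlo draws.
#' @return An object of class `overlap_report`: list with `groups` (tibble:
#'   `group`, `n`, `disparity`, per-axis box limits, `hull_volume`) and
#'   `pairs` (tibble: `group_a`, `group_b`, `intersection_volume`,
#'   `overlap_fraction`).
#' @export
group_overlap <- function(ord, groups, n_mc = 20000, seed = NULL) {
  X <- if (inherits(ord, "nmmds")) ord$points else as.matrix(ord)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (is.data.frame(groups)) {
    grp <- setNames(as.character(groups$group), groups$specimen_id)
  } else {
    grp <- groups
  }
  grp <- grp[rownames(X)]
  if (anyNA(grp)) abort("every specimen needs a group assignment")
  levels <- unique(grp)
  if (length(levels) < 2) abort("need at least 2 groups")
  sizes <- table(grp)
  if (sum(sizes >= 4) < 2) abort("need at least 2 groups with >= 4 members")

  dims <- ncol(X)
  seeds <- derive_seeds(if (is.null(seed)) 0L else seed,
                        length(levels) + choose(length(levels), 2))
  si <- 0L

  rows <- list()
  for (g in levels) {
    P <- X[grp == g, , drop = FALSE]
    centroid <- colMeans(P)
    disp <- mean(sqrt(rowSums(sweep(P, 2, centroid)^2)))
    lo <- apply(P, 2, min); hi <- apply(P, 2, max)
    si <- si + 1L
    vol <- if (nrow(P) < dims + 1) {
      warn(sprintf("group '%s' has %d points; convex hull skipped", g, nrow(P)))
      NA_real_
    } else {
      hull_volume_mc(P, n_mc, seeds[si])
    }
    rows[[g]] <- tibble::tibble(group = g, n = nrow(P), disparity = disp,
                                hull_volume = vol,
                                box_min = list(lo), box_max = list(hi))
  }
  gtab <- dplyr::bind_rows(rows)

  prs <- list()
  if (length(levels) >= 2) {
    for (i in seq_len(length(levels) - 1)) {
      for (j in seq(i + 1, length(levels))) {
        a <- levels[i]; b <- levels[j]
        si <- si + 1L
        prs[[length(prs) + 1L]] <- hull_pair_overlap(
          X[grp == a, , drop = FALSE], X[grp == b, , drop = FALSE],
          a, b, gtab, n_mc, seeds[si])
      }
    }
  }
  structure(list(groups = gtab, pairs = dplyr::bind_rows(prs),
                 n_mc = n_mc, seed = seed),
            class = "overlap_report")
}

hull_pair_overlap <- function(A, B, name_a, name_b, gtab, n_mc, seed) {
  out <- tibble::tibble(group_a = name_a, group_b = name_b,
                        intersection_volume = NA_real_,
                        overlap_fraction = NA_real_)
  va <- gtab$hull_volume[gtab$group == name_a]
  vb <- gtab$hull_volume[gtab$group == name_b]
  if (is.na(va) || is.na(vb)) return(out)
  if (nrow(A) == nrow(B) && isTRUE(all.equal(A[order(A[, 1]), , drop = FALSE],
                                             B[order(B[, 1]), , drop = FALSE],
                                             check.attributes = FALSE))) {
    out$intersection_volume <- min(va, vb)
    out$overlap_fraction <- 1
    return(out)
  }
  lo <- pmax(apply(A, 2, min), apply(B, 2, min))
  hi <- pmin(apply(A, 2, max), apply(B, 2, max))
  if (any(lo >= hi)) {  # bounding boxes disjoint: hulls cannot intersect
    out$intersection_volume <- 0
    out$overlap_fraction <- 0
    return(out)
  }
  pts <- with_seed(seed, matrix(runif(n_mc * ncol(A)), n_mc) %*%
                     diag(hi - lo, ncol(A)) + rep(lo, each = n_mc))
  inside <- in_hull(pts, A) & in_hull(pts, B)
  out$intersection_volume <- mean(inside) * prod(hi - lo)
  out$overlap_fraction <- out$intersection_volume / min(va, vb)
  out
}

# Monte Carlo convex-hull volume of point set P.
hull_volume_mc <- function(P, n_mc, seed) {
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  span <- hi - lo
  if (any(span == 0)) return(0)  # degenerate (flat) hull
  pts <- with_seed(seed, matrix(runif(n_mc * ncol(P)), n_mc) %*%
                     diag(span, ncol(P)) + rep(lo, each = n_mc))
  mean(in_hull(pts, P)) * prod(span)
}

#' Test points for convex-hull membership
#'
#' Determines for each query point whether it lies in the convex hull of a
#' small point set. Supporting hyperplanes are enumerated by brute force
#' (every subset of `d` vertices spans a candidate hyperplane; it supports
#' the hull when all vertices lie on one side), and membership is the
#' intersection of the resulting half-spaces. Exact up to floating-point
#' tolerance and robust to coplanar vertices; intended for hulls of at most
#' a few dozen vertices.
#'
#' @param pts Query points (matrix, one row per point).
#' @param vertices Points whose convex hull is tested against.
#' @param tol Relative tolerance on the half-space inequalities
#'   (default 1e-9 of the hull's coordinate scale).
#' @return Logical vector, one entry per query point.
#' @export
in_hull <- function(pts, vertices, tol = 1e-9) {
  V <- as.matrix(vertices)
  P <- as.matrix(pts)
  hs <- hull_halfspaces(V, tol)
  if (is.null(hs)) return(rep(FALSE, nrow(P)))  # degenerate hull: zero volume
  slack <- P %*% t(hs$normals) - rep(hs$offsets, each = nrow(P))
  rowSums(slack > hs$eps) == 0
}

# Enumerate supporting half-spaces {x : n.x <= b} of the convex hull of V.
# Returns NULL when V is rank-deficient (flat hull, volume zero).
hull_halfspaces <- function(V, tol = 1e-9) {
  d <- ncol(V)
  m <- nrow(V)
  scale <- max(abs(sweep(V, 2, colMeans(V)))) + 1e-300
  eps <- tol * scale
  if (m < d + 1 || qr(sweep(V, 2, colMeans(V)))$rank < d) return(NULL)
  combos <- utils::combn(m, d)
  normals <- list(); offsets <- numeric(0)
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    base <- V[idx[1], ]
    A <- sweep(V[idx[-1], , drop = FALSE], 2, base)
    nv <- null_vector(A)
    if (is.null(nv)) next  # affinely dependent subset
    b <- sum(nv * base)
    proj <- V %*% nv
    if (max(proj) <= b + eps) {
      normals[[length(normals) + 1L]] <- nv; offsets <- c(offsets, b)
    }
    if (min(proj) >= b - eps) {
      normals[[length(normals) + 1L]] <- -nv; offsets <- c(offsets, -b)
    }
  }
  if (length(normals) == 0) return(NULL)
  list(normals = do.call(rbind, normals), offsets = offsets, eps = eps)
}

# Unit vector orthogonal to the rows of A ((d-1) x d), or NULL if A is
# rank-deficient.
null_vector <- function(A) {
  d <- ncol(A)
  qr_a <- qr(t(A))
  if (qr_a$rank < d - 1) return(NULL)
  nv <- qr.Q(qr_a, complete = TRUE)[, d]
  nv / sqrt(sum(nv^2))
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Morphospace overlap report\n\nGroups:\n")
  print(dplyr::select(x$groups, -"box_min", -"box_max"))
  cat("\nPairwise hull overlap:\n")
  print(x$pairs)
  invisible(x)
}

#' @describeIn group_overlap Pairwise overlap table as a tibble.
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) x$pairs
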